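#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats predict
#' @importFrom Rcpp evalCpp
#' @useDynLib eitgest, .registration = TRUE
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
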