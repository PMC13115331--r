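#' Time-difference boundary voltages
#'
#' Subtracts a reference frame from a measurement frame, channel by channel.
#' Difference imaging against a rest reference cancels the (unknown) static
#' anatomy and instrument gain, leaving the gesture-evoked change that the
#' linearized model `dV = J dsigma` describes.
#'
#' @param frame,reference Numeric voltage vectors in canonical channel order
#'   (same length, same units).
#' @return Numeric vector `frame - reference`.
#' @export
difference_voltages <- function(frame, reference) {
  if (length(frame) != length(reference)) {
    stop("frame and reference must have the same number of channels")
  }
  as.numeric(frame) - as.numeric(reference)
}

#' Reference frame from the rest intervals of a session
#'
#' @param stream A frame tibble from [simulate_session()].
#' @param policy `"mean_of_rest_frames"` (default): channel-wise mean over
#'   all frames whose phase is an inter-instruction rest interval;
#'   `"first_frame"`: the first frame of the stream.
#' @return Numeric vector, one value per channel.
#' @export
reference_frame <- function(stream, policy = c("mean_of_rest_frames",
                                               "first_frame")) {
  policy <- match.arg(policy)
  v <- frame_matrix(stream)
  if (policy == "first_frame") return(v[1, ])
  rest <- stream$phase == "interval"
  if (!any(rest)) stop("stream contains no rest-interval frames")
  colMeans(v[rest, , drop = FALSE])
}

#' Tikhonov-regularized difference image
#'
#' Reconstructs the per-element conductivity change from a boundary-voltage
#' difference by penalized least squares: the minimizer of
#' `||J dsigma - dV||^2 + alpha ||dsigma||^2`, computed by solving the
#' regularized normal equations `(J'J + alpha I) dsigma = J' dV` with a
#' Cholesky factorization (never by explicit inversion). The regularization
#' parameter stabilizes the severely under-determined inverse problem (208
#' equations, one unknown per mesh element).
#'
#' @param jacobian An `eit_jacobian` from [compute_jacobian()], or a plain
#'   numeric matrix.
#' @param dv Voltage-difference vector (one value per channel, same units as
#'   the Jacobian).
#' @param alpha Regularization parameter (>= 0). Default `NULL` uses
#'   `0.01 * lambda_max(J'J)`, a standard relative choice that adapts to the
#'   scale of the sensitivity matrix.
#' @param mesh Optional `eit_mesh` to attach for plotting; taken from the
#'   call site, not stored in the Jacobian.
#' @return An object of class `eit_recon`: list with `delta_sigma`
#'   (n_elements), `alpha`, and optionally `mesh`.
#' @examples
#' mesh <- build_disk_mesh(3)
#' J <- compute_jacobian(mesh, rep(1, nrow(mesh$elements)))
#' img <- tikhonov_reconstruct(J, rnorm(208) * 1e-6, mesh = mesh)
#' length(img$delta_sigma)
#' @export
tikhonov_reconstruct <- function(jacobian, dv, alpha = NULL, mesh = NULL) {
  J <- if (inherits(jacobian, "eit_jacobian")) jacobian$J else jacobian
  if (length(dv) != nrow(J)) {
    stop("dv must have one entry per Jacobian row (channel)")
  }
  if (!is.null(alpha) && alpha < 0) stop("alpha must be >= 0")
  m <- ncol(J)
  if (is.null(alpha)) {
    # nonzero eigenvalues of J'J equal those of the small Gram matrix JJ'
    lam <- eigen(J %*% t(J), symmetric = TRUE, only.values = TRUE)$values
    alpha <- 0.01 * max(lam)
  }
  A <- crossprod(J)
  diag(A) <- diag(A) + alpha
  rhs <- crossprod(J, dv)
  ch <- tryCatch(chol(A), error = function(e) {
    stop("regularized normal equations are numerically singular; ",
         "alpha = ", format(alpha), " is too small for this Jacobian")
  })
  ds <- backsolve(ch, forwardsolve(t(ch), rhs))
  structure(list(delta_sigma = as.numeric(ds), alpha = alpha, mesh = mesh),
            class = "eit_recon")
}

#' @export
print.eit_recon <- function(x, ...) {
  cat("<eit_recon> ", length(x$delta_sigma), " elements, alpha = ",
      format(x$alpha, digits = 4), ", |dsigma| range [",
      format(min(x$delta_sigma), digits = 3), ", ",
      format(max(x$delta_sigma), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Tidy a reconstructed image into one row per element
#'
#' @param x An `eit_recon`.
#' @param ... Unused.
#' @return A tibble with element index, centroid coordinates (when a mesh is
#'   attached) and `delta_sigma`.
#' @method tidy eit_recon
#' @export
tidy.eit_recon <- function(x, ...) {
  out <- tibble::tibble(element = seq_along(x$delta_sigma),
                        delta_sigma = x$delta_sigma)
  if (!is.null(x$mesh)) {
    out$x <- x$mesh$centroids[, 1]
    out$y <- x$mesh$centroids[, 2]
  }
  out
}

#' Plot a reconstructed conductivity-change image
#'
#' Renders the element-wise conductivity change on the mesh as filled
#' triangles with a diverging palette centred at zero.
#'
#' @param object An `eit_recon` with a mesh attached.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eit_recon
#' @export
autoplot.eit_recon <- function(object, ...) {
  if (is.null(object$mesh)) stop("attach a mesh to plot a reconstruction")
  mesh <- object$mesh
  tri <- mesh$elements
  df <- tibble::tibble(
    x = as.numeric(t(cbind(mesh$nodes[tri[, 1], 1], mesh$nodes[tri[, 2], 1],
                           mesh$nodes[tri[, 3], 1]))),
    y = as.numeric(t(cbind(mesh$nodes[tri[, 1], 2], mesh$nodes[tri[, 2], 2],
                           mesh$nodes[tri[, 3], 2]))),
    element = rep(seq_len(nrow(tri)), each = 3),
    delta_sigma = rep(object$delta_sigma, each = 3)
  )
  lim <- max(abs(object$delta_sigma))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$element,
                                   fill = .data$delta_sigma)) +
    ggplot2::geom_polygon(colour = NA) +
    ggplot2::scale_fill_gradient2(limits = c(-lim, lim),
                                  name = expression(Delta * sigma)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
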