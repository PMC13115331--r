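#' @importFrom Matrix sparseMatrix Cholesky solve t
NULL

# Assemble the P1 finite-element stiffness matrix for -div(sigma grad u) = 0.
# Uses the cached triplet pattern; duplicate (i, j) entries are summed by
# sparseMatrix().
fem_matrix <- function(mesh, sigma) {
  if (length(sigma) != nrow(mesh$elements)) {
    stop("sigma must have one value per mesh element")
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("conductivity must be finite and strictly positive")
  }
  a <- mesh$assembly
  Matrix::sparseMatrix(i = a$i, j = a$j, x = a$k * sigma[a$elem],
                       dims = rep(nrow(mesh$nodes), 2))
}

# Solve the 16 drive fields u_k for unit current (1 A) injected through each
# adjacent electrode pair (k, k+1). The pure-Neumann system is grounded at
# node 1 (the disk centre, never an electrode node). Returns an
# n_nodes x n_electrodes dense matrix of nodal potentials.
solve_pair_fields <- function(mesh, sigma, factor = NULL) {
  n <- nrow(mesh$nodes)
  ne <- mesh$n_electrodes
  A <- fem_matrix(mesh, sigma)
  Ar <- A[-1, -1]
  ch <- if (is.null(factor)) Matrix::Cholesky(Ar, LDL = FALSE) else
    Matrix::.updateCHMfactor(factor, Ar, mult = 0)
  B <- matrix(0, n, ne)
  for (k in seq_len(ne)) {
    src <- mesh$electrodes[[k]]
    snk <- mesh$electrodes[[if (k == ne) 1L else k + 1L]]
    B[src, k] <- B[src, k] + 1 / length(src)
    B[snk, k] <- B[snk, k] - 1 / length(snk)
  }
  X <- matrix(0, n, ne)
  X[-1, ] <- as.matrix(Matrix::solve(ch, B[-1, , drop = FALSE], system = "A"))
  attr(X, "factor") <- ch
  X
}

#' Solve the EIT forward problem on a mesh
#'
#' Assembles the finite-element system for the conductivity field, solves the
#' potential field for every adjacent drive pair, and extracts the 208
#' differential boundary voltages in canonical channel order (see
#' [adjacent_protocol()]). Electrode potentials are node-set means (gap
#' electrode model); voltages scale linearly with the drive current and
#' inversely with a global conductivity scaling.
#'
#' @param mesh An `eit_mesh`.
#' @param sigma Per-element conductivity (S/m), strictly positive.
#' @param protocol An `eit_protocol`.
#' @return Numeric vector of boundary voltages in volts, one per channel,
#'   canonical order.
#' @examples
#' mesh <- build_disk_mesh(4)
#' v <- solve_forward(mesh, rep(1, nrow(mesh$elements)), adjacent_protocol())
#' length(v) # 208
#' @export
solve_forward <- function(mesh, sigma, protocol = adjacent_protocol()) {
  if (protocol$n_electrodes != mesh$n_electrodes) {
    stop("protocol and mesh disagree on electrode count")
  }
  X <- solve_pair_fields(mesh, sigma)
  el_pot <- electrode_potentials(mesh, X)    # n_electrodes x n_drives
  chs <- protocol$channels
  I_amp <- protocol$current_mA * 1e-3
  v <- I_amp * (el_pot[cbind(chs$mpos + 1L, chs$drive + 1L)] -
                  el_pot[cbind(chs$mneg + 1L, chs$drive + 1L)])
  as.numeric(v)
}

# Mean potential over each electrode's node set, for each drive field.
electrode_potentials <- function(mesh, X) {
  t(vapply(mesh$electrodes,
           function(nodes) colMeans(X[nodes, , drop = FALSE]),
           numeric(ncol(X))))
}

#' Sensitivity (Jacobian) matrix of the forward map
#'
#' Computes the 208 x n_elements linearization `J` of the boundary-voltage
#' map around a reference conductivity, so that small conductivity changes
#' satisfy `dV = J dsigma`. Uses the adjoint-field identity: the sensitivity
#' of channel (drive d, measurement m) to element e is
#' `-I_drive * area_e * grad(u_d) . grad(u_m)`, where `u_d`, `u_m` are the
#' unit-current fields of the drive and measurement electrode pairs. Since
#' both drives and measurements use adjacent pairs, the 16 pair fields serve
#' both roles.
#'
#' @inheritParams solve_forward
#' @param sigma_ref Reference per-element conductivity at which to linearize.
#' @return An object of class `eit_jacobian`: list with `J` (208 x
#'   n_elements, volts per unit conductivity change), `sigma_ref`, and the
#'   protocol used.
#' @examples
#' mesh <- build_disk_mesh(3)
#' J <- compute_jacobian(mesh, rep(1, nrow(mesh$elements)))
#' dim(J$J) # 208 x 144
#' @export
compute_jacobian <- function(mesh, sigma_ref, protocol = adjacent_protocol()) {
  if (protocol$n_electrodes != mesh$n_electrodes) {
    stop("protocol and mesh disagree on electrode count")
  }
  X <- solve_pair_fields(mesh, sigma_ref)
  tri <- mesh$elements
  m <- nrow(tri)
  ne <- mesh$n_electrodes
  gx <- matrix(0, m, ne)
  gy <- matrix(0, m, ne)
  for (k in seq_len(ne)) {
    uv <- matrix(X[tri, k], ncol = 3)
    gx[, k] <- rowSums(uv * mesh$grad_b)
    gy[, k] <- rowSums(uv * mesh$grad_c)
  }
  chs <- protocol$channels
  I_amp <- protocol$current_mA * 1e-3
  J <- matrix(0, nrow(chs), m)
  for (r in seq_len(nrow(chs))) {
    d <- chs$drive[r] + 1L
    mp <- chs$mpos[r] + 1L   # measurement pair (mpos, mpos+1) = pair field mpos
    J[r, ] <- -I_amp * mesh$areas *
      (gx[, d] * gx[, mp] + gy[, d] * gy[, mp])
  }
  structure(list(J = J, sigma_ref = sigma_ref, protocol = protocol),
            class = "eit_jacobian")
}

#' @export
print.eit_jacobian <- function(x, ...) {
  cat("<eit_jacobian> ", nrow(x$J), " channels x ", ncol(x$J),
      " elements\n", sep = "")
  invisible(x)
}
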