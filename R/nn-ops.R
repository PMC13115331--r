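# Low-level tensor primitives for the sequence classifiers.
#
# Batched feature maps are stored as a matrix `X` of shape
# (channels) x (H * W * batch): one column per spatial position, spatial
# index fastest (column-major within a sample), samples concatenated. All
# spatial rearrangements (padding, dilated-convolution taps, fold/unfold)
# are precomputed global column-index vectors, cached per geometry, so the
# arithmetic reduces to BLAS matrix products and indexed gathers/scatters.

.nn_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  if (is.null(.nn_cache[[key]])) .nn_cache[[key]] <- make()
  .nn_cache[[key]]
}

# 3x3 (optionally dilated) convolution with "same" zero padding. Weights are
# stored as an array (Cout, Cin, 9) whose flattening (Cout, 9 * Cin) matches
# the row order of the compiled im2col (tap-major, channel-minor), so the
# convolution is a single GEMM against the im2col matrix.
conv2d_fwd <- function(X, Wt, b, H, W, B, dilation = 1L) {
  Cout <- dim(Wt)[1]
  Xcol <- im2col_3x3(X, H, W, B, as.integer(dilation))
  Y <- matrix(Wt, nrow = Cout) %*% Xcol + b
  list(Y = Y, Xcol = Xcol)
}

conv2d_bwd <- function(G, Wt, Xcol, H, W, B, dilation = 1L) {
  Cout <- dim(Wt)[1]; Cin <- dim(Wt)[2]
  gW <- array(tcrossprod(G, Xcol), dim = dim(Wt))
  gXcol <- crossprod(matrix(Wt, nrow = Cout), G)
  gX <- col2im_3x3(gXcol, H, W, B, as.integer(dilation), Cin)
  list(gX = gX, gW = gW, gb = rowSums(G))
}

# 1x1 convolution is a plain channel-mixing product
conv1x1_fwd <- function(X, Wt, b) list(Y = Wt %*% X + b)
conv1x1_bwd <- function(G, Wt, X) {
  list(gX = crossprod(Wt, G), gW = tcrossprod(G, X), gb = rowSums(G))
}

# fold: non-overlapping 2x2 blocks become 4 channels at half resolution.
# Block-position order (within the 2x2 window): (0,0), (1,0), (0,1), (1,1)
# in (row, col) offsets. Pure bijective rearrangement, no arithmetic.
fold_idx <- function(H, W, B) {
  key <- paste("fold", H, W, B, sep = "_")
  cache_get(key, function() {
    h2 <- H %/% 2L; w2 <- W %/% 2L
    lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(o) {
      rows <- 2L * seq_len(h2) - 1L + o[1]
      cols <- 2L * seq_len(w2) - 1L + o[2]
      one <- as.vector(outer(rows, (cols - 1L) * H, `+`))
      as.vector(outer(one, (seq_len(B) - 1L) * H * W, `+`))
    })
  })
}

fold_op <- function(X, H, W, B) {
  if (H %% 2L != 0L || W %% 2L != 0L) {
    stop("fold requires even spatial dimensions")
  }
  C <- nrow(X)
  idx <- fold_idx(H, W, B)
  Y <- matrix(0, 4L * C, (H %/% 2L) * (W %/% 2L) * B)
  for (q in 1:4) Y[(q - 1L) * C + seq_len(C), ] <- X[, idx[[q]], drop = FALSE]
  Y
}

unfold_op <- function(Y, H, W, B) {
  # H, W are the *output* (restored) spatial dimensions
  C4 <- nrow(Y)
  if (C4 %% 4L != 0L) stop("unfold requires a channel count divisible by 4")
  C <- C4 %/% 4L
  idx <- fold_idx(H, W, B)
  X <- matrix(0, C, H * W * B)
  for (q in 1:4) X[, idx[[q]]] <- Y[(q - 1L) * C + seq_len(C), , drop = FALSE]
  X
}

# bilinear 2x upsampling operator (16x16 -> 32x32), built once as a sparse
# matrix; output pixel centres sit at half-integer offsets of input centres
upsample_matrix <- function(H, W) {
  key <- paste("ups", H, W, sep = "_")
  cache_get(key, function() {
    Ho <- 2L * H; Wo <- 2L * W
    trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
    for (oc in seq_len(Wo)) {
      for (orr in seq_len(Ho)) {
        # input coordinate of this output pixel centre
        yi <- (orr - 0.5) / 2 + 0.5; xi <- (oc - 0.5) / 2 + 0.5
        y0 <- floor(yi); x0 <- floor(xi)
        fy <- yi - y0; fx <- xi - x0
        out <- (oc - 1L) * Ho + orr
        for (pt in list(c(y0, x0, (1 - fy) * (1 - fx)),
                        c(y0 + 1, x0, fy * (1 - fx)),
                        c(y0, x0 + 1, (1 - fy) * fx),
                        c(y0 + 1, x0 + 1, fy * fx))) {
          yy <- min(max(pt[1], 1), H); xx <- min(max(pt[2], 1), W)
          if (pt[3] > 0) {
            trip_i <- c(trip_i, out)
            trip_j <- c(trip_j, (xx - 1L) * H + yy)
            trip_x <- c(trip_x, pt[3])
          }
        }
      }
    }
    U <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                              dims = c(Ho * Wo, H * W))
    list(U = U, Ut = Matrix::t(U))
  })
}

# global average pooling over space and its adjoint (compiled)
gap_fwd <- function(X, HW, B) gap_pool(X, as.integer(HW), as.integer(B))
gap_bwd <- function(G, HW, B) gap_unpool(G, as.integer(HW), as.integer(B))

# in-place on freshly allocated matrices only
activations_relu <- function(X) relu_inplace(X)

# numerically stable softmax over rows (classes) per column (sample)
softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

# mean cross-entropy of one-hot targets; Y is the class-index vector
cross_entropy <- function(P, y_idx) {
  p <- P[cbind(y_idx, seq_len(ncol(P)))]
  -mean(log(pmax(p, 1e-12)))
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

glorot_conv <- function(cout, cin, taps) {
  s <- sqrt(6 / (cin * taps + cout * taps))
  array(stats::runif(cout * cin * taps, -s, s), dim = c(cout, cin, taps))
}

# Adam optimizer state; the update itself runs in compiled code
# (adam_update), in place over these lists
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

n_params <- function(params) sum(vapply(params, length, integer(1)))
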