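# The two sequence classifiers: FASPP-GRU (fold / atrous spatial pyramid
# pooling / GRU) and the CNN-LSTM baseline. Both consume windows of 11
# frames x 208 channels, reshape each frame into the padded 16 x 16 grid,
# encode frames spatially, and classify the window from the final recurrent
# state. Forward and backward passes are written out explicitly against the
# primitives in nn-ops.R.

#' Canonical gesture classes
#'
#' The nine instructed gestures, in canonical order.
#' @return Character vector of length 9.
#' @export
gesture_classes <- function() {
  c("pointer", "power", "pronation", "supination", "thumb",
    "tripod", "victory", "open", "rest")
}

#' Configuration of the FASPP-GRU classifier
#'
#' Defaults instantiate the reference architecture: per frame, the 16 x 16
#' measurement grid is bilinearly upsampled to 32 x 32, folded 2 x 2 into a
#' 16 x 16 x 4 map, passed through parallel atrous 3 x 3 convolutions at
#' dilations 1, 2 and 4 plus a 1 x 1 branch, projected, unfolded back to
#' measurement space, pooled over a 4 x 4 grid of regions and embedded;
#' a single-layer GRU reads
#' the 11 frame embeddings and an MLP head emits 9-class probabilities.
#' The default widths give 649,885 trainable parameters (0.65M).
#'
#' @param aspp_channels Channels per ASPP branch.
#' @param proj_channels Channels after the concat projection (must be
#'   divisible by 4 for the unfold).
#' @param embed_dim GRU input dimension.
#' @param gru_hidden GRU hidden-state size.
#' @param mlp_hidden MLP head width.
#' @param n_classes Number of gesture classes.
#' @param window Frames per sequence.
#' @param lr Adam learning rate (5e-5).
#' @param batch_size,max_epochs,patience Training-loop controls; training
#'   stops at `max_epochs` or after `patience` epochs without validation
#'   loss improvement.
#' @param standardize Standardize each channel with training-set statistics
#'   before encoding (default TRUE); `FALSE` feeds raw voltages.
#' @return A config list of class `faspp_gru_config`.
#' @export
faspp_gru_config <- function(aspp_channels = 8L, proj_channels = 32L,
                             embed_dim = 128L, gru_hidden = 160L,
                             mlp_hidden = 2898L, n_classes = 9L,
                             window = 11L, lr = 5e-5, batch_size = 64L,
                             max_epochs = 60L, patience = 8L,
                             standardize = TRUE) {
  stopifnot(proj_channels %% 4L == 0L)
  structure(list(arch = "faspp_gru", aspp_dilations = c(1L, 2L, 4L),
                 aspp_channels = aspp_channels,
                 proj_channels = proj_channels, embed_dim = embed_dim,
                 gru_hidden = gru_hidden, mlp_hidden = mlp_hidden,
                 n_classes = n_classes, window = window, lr = lr,
                 batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, standardize = standardize),
            class = c("faspp_gru_config", "eit_nn_config"))
}

#' Configuration of the CNN-LSTM baseline
#'
#' Per-frame two-layer convolutional encoder on the 16 x 16 grids, LSTM over
#' the 11 frame embeddings, MLP head. Default widths give 880,015 trainable
#' parameters (0.88M).
#'
#' @param conv_channels Widths of the two 3 x 3 convolution layers.
#' @param embed_dim LSTM input dimension.
#' @param lstm_hidden LSTM hidden size.
#' @inheritParams faspp_gru_config
#' @return A config list of class `cnn_lstm_config`.
#' @export
cnn_lstm_config <- function(conv_channels = c(8L, 16L), embed_dim = 128L,
                            lstm_hidden = 192L, mlp_hidden = 2967L,
                            n_classes = 9L, window = 11L, lr = 5e-5,
                            batch_size = 64L, max_epochs = 60L,
                            patience = 8L, standardize = TRUE) {
  structure(list(arch = "cnn_lstm", conv_channels = conv_channels,
                 embed_dim = embed_dim, lstm_hidden = lstm_hidden,
                 mlp_hidden = mlp_hidden, n_classes = n_classes,
                 window = window, lr = lr, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience,
                 standardize = standardize),
            class = c("cnn_lstm_config", "eit_nn_config"))
}

# mapping from the 256 grid positions (column-major 16 x 16) to the 208
# canonical channels; pad positions are 0
grid_gather <- function() {
  cache_get("grid_gather", function() {
    pos <- integer(256)
    for (d in 1:16) for (m in 1:13) pos[(m - 1L) * 16L + d] <- (d - 1L) * 13L + m
    list(grid_rows = which(pos > 0L), channels = pos[pos > 0L])
  })
}

# stack raw mV windows (win x 208 x B) into frame columns (208, win*B),
# frame index fastest. With a scaler (list of per-channel mu/sd fitted on
# training data) channels are standardized; otherwise mV are converted to
# volts.
frames_from_windows <- function(X, scaler = NULL) {
  win <- dim(X)[1]; B <- dim(X)[3]
  V <- matrix(aperm(X, c(2L, 1L, 3L)), nrow = dim(X)[2])
  V <- if (is.null(scaler)) V * 1e-3 else (V - scaler$mu) / scaler$sd
  g <- grid_gather()
  F256 <- matrix(0, 256L, win * B)
  F256[g$grid_rows, ] <- V[g$channels, , drop = FALSE]
  F256
}

# per-channel standardization statistics over all frames of a window set
fit_scaler <- function(X) {
  V <- matrix(aperm(X, c(2L, 1L, 3L)), nrow = dim(X)[2])
  list(mu = rowMeans(V), sd = pmax(apply(V, 1, stats::sd), 1e-8))
}

init_params <- function(cfg) {
  if (cfg$arch == "faspp_gru") {
    c0 <- cfg$aspp_channels; p <- cfg$proj_channels
    d <- cfg$embed_dim; h <- cfg$gru_hidden; m <- cfg$mlp_hidden
    params <- list(
      W_b0 = glorot(c0, 4L), b_b0 = numeric(c0),
      W_d1 = glorot_conv(c0, 4L, 9L), b_d1 = numeric(c0),
      W_d2 = glorot_conv(c0, 4L, 9L), b_d2 = numeric(c0),
      W_d4 = glorot_conv(c0, 4L, 9L), b_d4 = numeric(c0),
      W_proj = glorot(p, 4L * c0), b_proj = numeric(p),
      W_emb = glorot(d, 16L * (p %/% 4L)), b_emb = numeric(d),
      W_z = glorot(h, d), U_z = glorot(h, h), b_z = numeric(h),
      W_r = glorot(h, d), U_r = glorot(h, h), b_r = numeric(h),
      W_n = glorot(h, d), U_n = glorot(h, h), b_n = numeric(h),
      W_m1 = glorot(m, h), b_m1 = numeric(m),
      W_out = glorot(cfg$n_classes, m), b_out = numeric(cfg$n_classes)
    )
  } else {
    c1 <- cfg$conv_channels[1]; c2 <- cfg$conv_channels[2]
    d <- cfg$embed_dim; h <- cfg$lstm_hidden; m <- cfg$mlp_hidden
    params <- list(
      W_c1 = glorot_conv(c1, 1L, 9L), b_c1 = numeric(c1),
      W_c2 = glorot_conv(c2, c1, 9L), b_c2 = numeric(c2),
      W_emb = glorot(d, 16L * c2), b_emb = numeric(d),
      W_i = glorot(h, d), U_i = glorot(h, h), b_i = numeric(h),
      W_f = glorot(h, d), U_f = glorot(h, h), b_f = rep(1, h),
      W_o = glorot(h, d), U_o = glorot(h, h), b_o = numeric(h),
      W_g = glorot(h, d), U_g = glorot(h, h), b_g = numeric(h),
      W_m1 = glorot(m, h), b_m1 = numeric(m),
      W_out = glorot(cfg$n_classes, m), b_out = numeric(cfg$n_classes)
    )
  }
  params
}

#' Instantiate an untrained sequence classifier
#'
#' @param cfg A `faspp_gru_config()` or `cnn_lstm_config()`.
#' @param seed Integer seed for weight initialization (Glorot uniform).
#' @return An object of class `eit_nn`.
#' @examples
#' m <- nn_init(faspp_gru_config(), seed = 1)
#' sum(lengths(m$params)) # 649885
#' @export
nn_init <- function(cfg, seed = 1L) {
  params <- withr::with_seed(seed, init_params(cfg))
  structure(list(arch = cfg$arch, cfg = cfg, params = params,
                 classes = gesture_classes()[seq_len(cfg$n_classes)],
                 curves = NULL, seed = seed),
            class = "eit_nn")
}

#' @export
print.eit_nn <- function(x, ...) {
  cat("<eit_nn> ", x$arch, ", ", format(n_params(x$params), big.mark = ","),
      " parameters, ", if (is.null(x$curves)) "untrained" else
        paste0("trained ", max(x$curves$epoch), " epochs"), "\n", sep = "")
  invisible(x)
}

# ---- input preparation ----------------------------------------------------

# The stages before the first trainable layer carry no parameters (grid
# reshape; for FASPP also bilinear upsample and fold), so they are computed
# once per dataset and sliced per batch.
nn_prepare <- function(arch, X, scaler = NULL) {
  win <- dim(X)[1]; Bw <- dim(X)[3]
  F256 <- frames_from_windows(X, scaler)
  M <- if (arch == "faspp_gru") {
    U <- upsample_matrix(16L, 16L)
    fold_op(matrix(as.numeric(U$U %*% F256), nrow = 1L), 32L, 32L, win * Bw)
  } else {
    matrix(as.numeric(F256), nrow = 1L)
  }
  list(M = M, win = win, Bw = Bw)
}

# per-window blocks of the prepared matrix are contiguous
nn_slice <- function(inp, idx) {
  blk <- 256L * inp$win
  cols <- as.vector(outer(seq_len(blk), (idx - 1L) * blk, `+`))
  list(M = inp$M[, cols, drop = FALSE], win = inp$win, Bw = length(idx))
}

# ---- FASPP-GRU forward/backward -------------------------------------------

faspp_forward <- function(params, inp, cfg, keep_cache = FALSE) {
  win <- inp$win; Bw <- inp$Bw; Bf <- win * Bw
  Xf <- inp$M                                            # (4, 256*Bf)
  cv0 <- conv1x1_fwd(Xf, params$W_b0, params$b_b0)
  cv1 <- conv2d_fwd(Xf, params$W_d1, params$b_d1, 16L, 16L, Bf, 1L)
  cv2 <- conv2d_fwd(Xf, params$W_d2, params$b_d2, 16L, 16L, Bf, 2L)
  cv4 <- conv2d_fwd(Xf, params$W_d4, params$b_d4, 16L, 16L, Bf, 4L)
  c0 <- cfg$aspp_channels
  A <- matrix(0, 4L * c0, ncol(Xf))
  A[seq_len(c0), ] <- cv0$Y
  A[c0 + seq_len(c0), ] <- cv1$Y
  A[2L * c0 + seq_len(c0), ] <- cv2$Y
  A[3L * c0 + seq_len(c0), ] <- cv4$Y
  A <- activations_relu(A)
  pj <- conv1x1_fwd(A, params$W_proj, params$b_proj)
  P <- activations_relu(pj$Y)                            # (p, 256*Bf)
  # Regional 4x4 average pooling of the restored measurement-space map.
  # Pooling commutes with the unfold permutation: pooling the folded
  # 16x16 map over 4x4 blocks and averaging the four fold channel groups
  # equals unfolding to (p/4, 32x32) and pooling 8x8 blocks, without
  # materializing the larger tensor.
  C4 <- cfg$proj_channels %/% 4L
  Gp4 <- array(block_pool(P, 16L, 16L, Bf, 4L, 4L),
               dim = c(C4, 4L, 16L, Bf))                 # [c, fold, blk, b]
  Gp <- matrix((Gp4[, 1, , ] + Gp4[, 2, , ] + Gp4[, 3, , ] +
                  Gp4[, 4, , ]) / 4, nrow = 16L * C4)    # (16 p/4, Bf)
  E <- activations_relu(params$W_emb %*% Gp + params$b_emb)  # (d, Bf)

  gr <- gru_forward_cpp(E, params$W_z, params$U_z, params$b_z,
                        params$W_r, params$U_r, params$b_r,
                        params$W_n, params$U_n, params$b_n,
                        win, Bw, keep_cache)
  h <- gr$H
  M1 <- activations_relu(params$W_m1 %*% h + params$b_m1)
  Z <- params$W_out %*% M1 + params$b_out
  probs <- softmax_cols(Z)
  cache <- if (keep_cache) {
    list(Xf = Xf, cv0 = cv0, cv1 = cv1, cv2 = cv2, cv4 = cv4, A = A, P = P,
         Gp = Gp, E = E, gru = gr, h = h, M1 = M1,
         win = win, Bw = Bw, Bf = Bf)
  }
  list(probs = probs, cache = cache)
}

faspp_backward <- function(params, cache, dZ, cfg) {
  win <- cache$win; Bw <- cache$Bw; Bf <- cache$Bf
  g <- list()
  g$W_out <- tcrossprod(dZ, cache$M1); g$b_out <- rowSums(dZ)
  dM1 <- relu_bwd_inplace(crossprod(params$W_out, dZ), cache$M1)
  g$W_m1 <- tcrossprod(dM1, cache$h); g$b_m1 <- rowSums(dM1)
  dh <- crossprod(params$W_m1, dM1)

  gb <- gru_backward_cpp(cache$E, cache$gru, params$U_z, params$U_r,
                         params$U_n, params$W_z, params$W_r, params$W_n,
                         dh, win, Bw)
  for (nm in c("W_z", "U_z", "b_z", "W_r", "U_r", "b_r",
               "W_n", "U_n", "b_n")) {
    g[[nm]] <- gb[[nm]]
  }
  dE <- relu_bwd_inplace(gb$dE, cache$E)
  g$W_emb <- tcrossprod(dE, cache$Gp); g$b_emb <- rowSums(dE)
  dGp <- crossprod(params$W_emb, dE)
  C4 <- cfg$proj_channels %/% 4L
  dGp3 <- array(dGp, dim = c(C4, 16L, Bf))
  dGp4 <- array(0, dim = c(C4, 4L, 16L, Bf))
  for (q in 1:4) dGp4[, q, , ] <- dGp3 / 4
  dP <- relu_bwd_inplace(
    block_unpool(matrix(dGp4, nrow = 16L * cfg$proj_channels, ncol = Bf),
                 16L, 16L, Bf, 4L, 4L),
    cache$P)
  pb <- conv1x1_bwd(dP, params$W_proj, cache$A)
  g$W_proj <- pb$gW; g$b_proj <- pb$gb
  dA <- relu_bwd_inplace(pb$gX, cache$A)
  c0 <- cfg$aspp_channels
  d0 <- dA[seq_len(c0), , drop = FALSE]
  d1 <- dA[c0 + seq_len(c0), , drop = FALSE]
  d2 <- dA[2L * c0 + seq_len(c0), , drop = FALSE]
  d4 <- dA[3L * c0 + seq_len(c0), , drop = FALSE]
  b0 <- conv1x1_bwd(d0, params$W_b0, cache$Xf)
  g$W_b0 <- b0$gW; g$b_b0 <- b0$gb
  for (spec in list(list(d1, "W_d1", "b_d1", cache$cv1, 1L),
                    list(d2, "W_d2", "b_d2", cache$cv2, 2L),
                    list(d4, "W_d4", "b_d4", cache$cv4, 4L))) {
    bb <- conv2d_bwd(spec[[1]], params[[spec[[2]]]], spec[[4]]$Xcol,
                     16L, 16L, Bf, spec[[5]])
    g[[spec[[2]]]] <- bb$gW; g[[spec[[3]]]] <- bb$gb
  }
  g
}

# ---- CNN-LSTM forward/backward --------------------------------------------

cnn_lstm_forward <- function(params, inp, cfg, keep_cache = FALSE) {
  win <- inp$win; Bw <- inp$Bw; Bf <- win * Bw
  X1 <- inp$M                                            # (1, 256*Bf)
  cv1 <- conv2d_fwd(X1, params$W_c1, params$b_c1, 16L, 16L, Bf, 1L)
  A1 <- activations_relu(cv1$Y)
  cv2 <- conv2d_fwd(A1, params$W_c2, params$b_c2, 16L, 16L, Bf, 1L)
  A2 <- activations_relu(cv2$Y)
  Gp <- block_pool(A2, 16L, 16L, Bf, 4L, 4L)   # regional 4x4 pooling
  E <- activations_relu(params$W_emb %*% Gp + params$b_emb)

  ls <- lstm_forward_cpp(E, params$W_i, params$U_i, params$b_i,
                         params$W_f, params$U_f, params$b_f,
                         params$W_o, params$U_o, params$b_o,
                         params$W_g, params$U_g, params$b_g,
                         win, Bw, keep_cache)
  h <- ls$H
  M1 <- activations_relu(params$W_m1 %*% h + params$b_m1)
  Z <- params$W_out %*% M1 + params$b_out
  probs <- softmax_cols(Z)
  cache <- if (keep_cache) {
    list(cv1 = cv1, A1 = A1, cv2 = cv2, A2 = A2, Gp = Gp, E = E,
         lstm = ls, h = h, M1 = M1, win = win, Bw = Bw, Bf = Bf)
  }
  list(probs = probs, cache = cache)
}

cnn_lstm_backward <- function(params, cache, dZ, cfg) {
  win <- cache$win; Bw <- cache$Bw; Bf <- cache$Bf
  g <- list()
  g$W_out <- tcrossprod(dZ, cache$M1); g$b_out <- rowSums(dZ)
  dM1 <- relu_bwd_inplace(crossprod(params$W_out, dZ), cache$M1)
  g$W_m1 <- tcrossprod(dM1, cache$h); g$b_m1 <- rowSums(dM1)
  dh <- crossprod(params$W_m1, dM1)

  lb <- lstm_backward_cpp(cache$E, cache$lstm, params$U_i, params$U_f,
                          params$U_o, params$U_g, params$W_i, params$W_f,
                          params$W_o, params$W_g, dh, win, Bw)
  for (nm in c("W_i", "U_i", "b_i", "W_f", "U_f", "b_f",
               "W_o", "U_o", "b_o", "W_g", "U_g", "b_g")) {
    g[[nm]] <- lb[[nm]]
  }
  dE <- relu_bwd_inplace(lb$dE, cache$E)
  g$W_emb <- tcrossprod(dE, cache$Gp); g$b_emb <- rowSums(dE)
  dGp <- crossprod(params$W_emb, dE)
  dA2 <- relu_bwd_inplace(block_unpool(dGp, 16L, 16L, Bf, 4L, 4L),
                          cache$A2)
  b2 <- conv2d_bwd(dA2, params$W_c2, cache$cv2$Xcol, 16L, 16L, Bf, 1L)
  g$W_c2 <- b2$gW; g$b_c2 <- b2$gb
  dA1 <- relu_bwd_inplace(b2$gX, cache$A1)
  b1 <- conv2d_bwd(dA1, params$W_c1, cache$cv1$Xcol, 16L, 16L, Bf, 1L)
  g$W_c1 <- b1$gW; g$b_c1 <- b1$gb
  g
}

nn_forward_prepared <- function(model, inp, keep_cache = FALSE) {
  if (model$arch == "faspp_gru") {
    faspp_forward(model$params, inp, model$cfg, keep_cache)
  } else {
    cnn_lstm_forward(model$params, inp, model$cfg, keep_cache)
  }
}

nn_forward <- function(model, X, keep_cache = FALSE) {
  nn_forward_prepared(model, nn_prepare(model$arch, X, model$scaler),
                      keep_cache)
}

nn_backward <- function(model, cache, dZ) {
  if (model$arch == "faspp_gru") {
    faspp_backward(model$params, cache, dZ, model$cfg)
  } else {
    cnn_lstm_backward(model$params, cache, dZ, model$cfg)
  }
}
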