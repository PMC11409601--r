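# The dual-domain architectures: ECG-DualNet (LSTM signal encoder + five
# conditional-batch-norm ResNet spectrogram blocks) and ECG-DualNet++
# (Transformer signal encoder + two ResNet and three axial-attention
# spectrogram blocks, all with CBN). The signal encoder consumes the padded
# signal as a sequence of non-overlapping frames; its latent vector
# conditions every spectrogram-encoder block through CBN, and a final fully
# connected layer with softmax produces the class probabilities.

# One CBN-ResNet spectrogram block: 3x3 stride-2 conv (the downsampling conv
# comes first, as in the standard residual formulation), CBN, ReLU, 3x3
# conv, CBN, plus a 1x1 stride-2 projection skip; halves both time and
# frequency resolution.
make_cbn_block <- function(ctx, name, c_in, c_out, latent) {
  conv1 <- nn_conv2d(ctx, paste0(name, ".conv1"), c_in, c_out, 3L, sh = 2L)
  cbn1 <- nn_cbn(ctx, paste0(name, ".cbn1"), c_out, latent)
  conv2 <- nn_conv2d(ctx, paste0(name, ".conv2"), c_out, c_out, 3L, sh = 1L)
  cbn2 <- nn_cbn(ctx, paste0(name, ".cbn2"), c_out, latent)
  skip <- nn_conv2d(ctx, paste0(name, ".skip"), c_in, c_out, 1L, sh = 2L,
                    ph = 0L)
  function(x, z, H, W, n, train) {
    c1 <- conv1(x, H, W, n)
    a <- ad_relu(cbn1(c1$y, z, c1$H * c1$W, train))
    c2 <- conv2(a, c1$H, c1$W, n)
    b <- cbn2(c2$y, z, c2$H * c2$W, train)
    s <- skip(x, H, W, n)
    list(y = ad_relu(ad_add(b, s$y)), H = c2$H, W = c2$W)
  }
}

build_dualnet <- function(config) {
  ctx <- nn_ctx()
  chans <- config$chans
  latent <- config$latent
  frame_len <- 32L
  n_classes <- config$n_classes

  lstm1 <- nn_lstm(ctx, "sig.lstm1", frame_len, latent)
  lstm2 <- if (config$lstm_layers >= 2L)
    nn_lstm(ctx, "sig.lstm2", latent, latent) else NULL

  blocks <- vector("list", length(chans))
  c_in <- 1L
  for (i in seq_along(chans)) {
    blocks[[i]] <- make_cbn_block(ctx, sprintf("spec.b%d", i), c_in,
                                  chans[i], latent)
    c_in <- chans[i]
  }
  head <- nn_dense(ctx, "head.fc", chans[length(chans)], n_classes)

  encode_signal <- function(frames, n) {
    if (is.null(lstm2)) lstm1(frames, n)
    else lstm2(lstm1(frames, n, return_sequence = TRUE), n)
  }
  encode_spec <- function(x, z, H, W, n, train) {
    for (blk in blocks) {
      out <- blk(x, z, H, W, n, train)
      x <- out$y; H <- out$H; W <- out$W
    }
    ad_t(ad_pool_cols(x, H * W)) # N x C
  }
  forward <- function(batch, train) {
    z <- encode_signal(batch$frames, batch$n)
    head(encode_spec(batch$spec, z, batch$H, batch$W, batch$n, train))
  }
  # direct access to the conditioned spectrogram encoder (raw matrices in)
  spec_encode <- function(spec, z, train = FALSE) {
    x <- ad_const(matrix(as.vector(spec), nrow = 1L))
    encode_spec(x, ad_const(as_mat(z)), nrow(spec), ncol(spec),
                nrow(as_mat(z)), train)$value
  }
  structure(list(family = "dualnet", size = config$size,
                 n_classes = n_classes, config = config, ctx = ctx,
                 forward = forward, spec_encode = spec_encode),
            class = c("afib_dualnet", "afib_nn", "afib_model"))
}

# Axial-attention block: CBN, multi-head attention along the time axis
# (one sequence per frequency row), residual; CBN, attention along the
# frequency axis (one sequence per time column), residual. Per-axis
# positional embeddings are added before attention.
make_axial_block <- function(ctx, name, C, latent, heads = 4L,
                             max_w = 1024L, max_h = 64L) {
  cbn_t <- nn_cbn(ctx, paste0(name, ".cbn_t"), C, latent)
  mha_t <- nn_mha(ctx, paste0(name, ".mha_t"), C, heads)
  pos_t <- nn_par(ctx, paste0(name, ".pos_t"),
                  matrix(stats::rnorm(max_w * C, 0, 0.02), max_w, C))
  cbn_f <- nn_cbn(ctx, paste0(name, ".cbn_f"), C, latent)
  mha_f <- nn_mha(ctx, paste0(name, ".mha_f"), C, heads)
  pos_f <- nn_par(ctx, paste0(name, ".pos_f"),
                  matrix(stats::rnorm(max_h * C, 0, 0.02), max_h, C))
  function(x, z, H, W, n, train) {
    # time axis: sequences of length W for each (image, frequency row)
    xn <- cbn_t(x, z, H * W, train)
    blocks <- vector("list", n * H)
    k <- 0L
    for (ni in seq_len(n)) {
      for (h in seq_len(H)) {
        k <- k + 1L
        cols <- (ni - 1L) * H * W + (seq_len(W) - 1L) * H + h
        s <- ad_add(ad_t(ad_slice_cols(xn, cols)),
                    ad_slice_rows(pos_t, seq_len(W)))
        blocks[[k]] <- ad_t(mha_t(s)) # C x W
      }
    }
    comp <- ad_cbind(blocks) # column order (image, row h, w)
    o <- seq_len(n * H * W)
    hh <- (o - 1L) %% H + 1L
    ww <- ((o - 1L) %/% H) %% W + 1L
    nn <- (o - 1L) %/% (H * W) + 1L
    perm <- ((nn - 1L) * H + (hh - 1L)) * W + ww
    x <- ad_add(x, ad_slice_cols(comp, perm))
    # frequency axis: sequences of length H for each (image, time column)
    xn2 <- cbn_f(x, z, H * W, train)
    blocks2 <- vector("list", n * W)
    k <- 0L
    for (ni in seq_len(n)) {
      for (w in seq_len(W)) {
        k <- k + 1L
        cols <- (ni - 1L) * H * W + (w - 1L) * H + seq_len(H)
        s <- ad_add(ad_t(ad_slice_cols(xn2, cols)),
                    ad_slice_rows(pos_f, seq_len(H)))
        blocks2[[k]] <- ad_t(mha_f(s)) # C x H
      }
    }
    x <- ad_add(x, ad_cbind(blocks2)) # (image, w, h) = native order
    list(y = x, H = H, W = W)
  }
}

build_dualnet_pp <- function(config) {
  ctx <- nn_ctx()
  d <- config$d_model
  latent <- config$latent
  res_ch <- config$res_ch
  frame_len <- 32L
  n_classes <- config$n_classes
  max_t <- 600L

  embed <- nn_dense(ctx, "sig.embed", frame_len, d)
  pos <- nn_par(ctx, "sig.pos", matrix(stats::rnorm(max_t * d, 0, 0.02),
                                       max_t, d))
  enc <- lapply(seq_len(config$enc_layers), function(i)
    nn_transformer_layer(ctx, sprintf("sig.enc%d", i), d, config$heads))
  proj <- nn_dense(ctx, "sig.proj", d, latent)

  res_blocks <- list(
    make_cbn_block(ctx, "spec.b1", 1L, res_ch[1L], latent),
    make_cbn_block(ctx, "spec.b2", res_ch[1L], res_ch[2L], latent))
  C <- res_ch[2L]
  ax_blocks <- lapply(seq_len(3L), function(i)
    make_axial_block(ctx, sprintf("spec.ax%d", i), C, latent))
  head <- nn_dense(ctx, "head.fc", C, n_classes)

  encode_signal <- function(frames, n) {
    T <- length(frames)
    stopifnot(T <= max_t)
    pooled <- vector("list", n)
    pool_row <- ad_const(matrix(1 / T, 1L, T))
    for (i in seq_len(n)) {
      xi <- t(vapply(frames, function(f) f$value[i, ], numeric(frame_len)))
      e <- ad_add(embed(ad_const(xi)), ad_slice_rows(pos, seq_len(T)))
      for (layer in enc) e <- layer(e)
      pooled[[i]] <- ad_matmul(pool_row, e) # mean over time: 1 x d
    }
    proj(ad_rbind(pooled))
  }
  encode_spec <- function(x, z, H, W, n, train) {
    for (blk in c(res_blocks, ax_blocks)) {
      out <- blk(x, z, H, W, n, train)
      x <- out$y; H <- out$H; W <- out$W
    }
    ad_t(ad_pool_cols(x, H * W))
  }
  forward <- function(batch, train) {
    z <- encode_signal(batch$frames, batch$n)
    head(encode_spec(batch$spec, z, batch$H, batch$W, batch$n, train))
  }
  spec_encode <- function(spec, z, train = FALSE) {
    x <- ad_const(matrix(as.vector(spec), nrow = 1L))
    encode_spec(x, ad_const(as_mat(z)), nrow(spec), ncol(spec),
                nrow(as_mat(z)), train)$value
  }
  structure(list(family = "dualnet_pp", size = config$size,
                 n_classes = n_classes, config = config, ctx = ctx,
                 forward = forward, spec_encode = spec_encode),
            class = c("afib_dualnet_pp", "afib_nn", "afib_model"))
}
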