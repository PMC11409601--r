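# Neural-network layer constructors on top of the autodiff engine.
#
# A "context" collects named parameters and normalization buffers so that a
# model can enumerate, checkpoint and selectively freeze them. Layers are
# closures over their parameter nodes; convolution layers cache im2col index
# matrices per input geometry.

nn_ctx <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$buffers <- list()
  e
}

nn_par <- function(ctx, name, value) {
  nd <- ad_param(value)
  ctx$params[[name]] <- nd
  nd
}

nn_buffer <- function(ctx, name, st) {
  ctx$buffers[[name]] <- st
  st
}

# Spatial layout convention: an activation with C channels over an H x W grid
# for a batch of N images is a C x (H*W*N) matrix. Within an image, spatial
# positions are column-major over (h, w): column s = (w-1)*H + h; images are
# stored as consecutive blocks of H*W columns.

# Precompute, for each kernel tap, the 0-based output/input column index
# pairs of the offset-decomposed convolution (zero padding positions are
# simply absent from the pair). Tap order matches the weight-column blocks:
# dh fastest, then dw.
conv_pair_idx <- function(H, W, N, kh, kw, sh, sw, ph, pw) {
  Ho <- (H + 2L * ph - kh) %/% sh + 1L
  Wo <- (W + 2L * pw - kw) %/% sw + 1L
  ho <- rep(seq_len(Ho), times = Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  img_out <- rep((seq_len(N) - 1L) * Ho * Wo, each = Ho * Wo)
  img_in <- rep((seq_len(N) - 1L) * H * W, each = Ho * Wo)
  pos <- rep(seq_len(Ho * Wo), times = N)
  pairs <- vector("list", kh * kw)
  k <- 0L
  for (dw in seq_len(kw)) {
    for (dh in seq_len(kh)) {
      k <- k + 1L
      h <- (ho - 1L) * sh + dh - ph
      w <- (wo - 1L) * sw + dw - pw
      valid <- h >= 1L & h <= H & w >= 1L & w <= W
      scol <- (w - 1L) * H + h
      v <- valid[pos]
      pairs[[k]] <- list(o = img_out[v] + pos[v] - 1L,
                         i = img_in[v] + scol[pos[v]] - 1L)
    }
  }
  list(pairs = pairs, Ho = Ho, Wo = Wo, outcols = Ho * Wo * N)
}

# 2-D convolution (kh x kw kernel, stride (sh, sw), "same"-style zero padding
# chosen by the caller). Returns list(y, H, W) with the output geometry.
nn_conv2d <- function(ctx, name, c_in, c_out, kh, kw = kh, sh = 1L, sw = sh,
                      ph = (kh - 1L) %/% 2L, pw = (kw - 1L) %/% 2L) {
  fan_in <- c_in * kh * kw
  W <- nn_par(ctx, paste0(name, ".W"),
              matrix(stats::rnorm(c_out * fan_in, 0, sqrt(2 / fan_in)), c_out, fan_in))
  b <- nn_par(ctx, paste0(name, ".b"), matrix(0, c_out, 1L))
  cache <- new.env(parent = emptyenv())
  function(x, H, Wsp, N) {
    key <- paste(H, Wsp, N, sep = "x")
    ii <- cache[[key]]
    if (is.null(ii)) {
      ii <- conv_pair_idx(H, Wsp, N, kh, kw, sh, sw, ph, pw)
      cache[[key]] <- ii
    }
    y <- ad_add_colvec(ad_conv(x, W, ii$pairs, c_in, ii$outcols), b)
    list(y = y, H = ii$Ho, W = ii$Wo)
  }
}

# 1-D convolution over length-L signals: a special case of conv2d with W = 1.
nn_conv1d <- function(ctx, name, c_in, c_out, k, stride = 1L,
                      pad = (k - 1L) %/% 2L) {
  f <- nn_conv2d(ctx, name, c_in, c_out, kh = k, kw = 1L, sh = stride, sw = 1L,
                 ph = pad, pw = 0L)
  function(x, L, N) {
    out <- f(x, L, 1L, N)
    list(y = out$y, L = out$H)
  }
}

nn_dense <- function(ctx, name, d_in, d_out, zero_init = FALSE) {
  W <- nn_par(ctx, paste0(name, ".W"),
              if (zero_init) matrix(0, d_in, d_out)
              else matrix(stats::rnorm(d_in * d_out, 0, sqrt(2 / d_in)), d_in, d_out))
  b <- nn_par(ctx, paste0(name, ".b"), matrix(0, 1L, d_out))
  function(x) ad_add_rowvec(ad_matmul(x, W), b)
}

# Batch normalization over channels (rows); statistics pooled over batch and
# spatial columns. Running statistics are tracked for inference.
nn_bn <- function(ctx, name, C, momentum = 0.1, eps = 1e-5) {
  gamma <- nn_par(ctx, paste0(name, ".gamma"), matrix(1, C, 1L))
  beta <- nn_par(ctx, paste0(name, ".beta"), matrix(0, C, 1L))
  st <- new.env(parent = emptyenv())
  st$rm <- matrix(0, C, 1L)
  st$rv <- matrix(1, C, 1L)
  nn_buffer(ctx, name, st)
  function(x, train) {
    if (train) {
      xn <- ad_norm_rows(x, eps)
      mu <- rowMeans(x$value)
      v <- rowMeans(x$value^2) - mu^2
      st$rm <- (1 - momentum) * st$rm + momentum * mu
      st$rv <- (1 - momentum) * st$rv + momentum * v
    } else {
      xn <- ad_mul_colvec(ad_add_colvec(x, ad_const(-st$rm)),
                          ad_const(1 / sqrt(st$rv + eps)))
    }
    ad_add_colvec(ad_mul_colvec(xn, gamma), beta)
  }
}

# Conditional batch normalization: per-channel scale and shift are affine
# functions of a per-image latent vector z (N x latent). The FiLM projection
# uses a small random init so the block starts near identity (gamma ~ 1,
# beta ~ 0) while the conditioning pathway is live from the first step.
nn_cbn <- function(ctx, name, C, latent_dim, momentum = 0.1, eps = 1e-5) {
  film_W <- nn_par(ctx, paste0(name, ".film.W"),
                   matrix(stats::rnorm(latent_dim * 2L * C, 0, 0.05 / sqrt(latent_dim)),
                          latent_dim, 2L * C))
  film_b <- nn_par(ctx, paste0(name, ".film.b"), matrix(0, 1L, 2L * C))
  film <- function(x) ad_add_rowvec(ad_matmul(x, film_W), film_b)
  st <- new.env(parent = emptyenv())
  st$rm <- matrix(0, C, 1L)
  st$rv <- matrix(1, C, 1L)
  nn_buffer(ctx, name, st)
  function(x, z, times, train) {
    n <- nrow(z$value)
    gb <- film(z)
    gamma <- ad_add(ad_slice_cols(gb, seq_len(C)), ad_const(matrix(1, n, C)))
    beta <- ad_slice_cols(gb, C + seq_len(C))
    if (train) {
      xn <- ad_norm_rows(x, eps)
      mu <- rowMeans(x$value)
      v <- rowMeans(x$value^2) - mu^2
      st$rm <- (1 - momentum) * st$rm + momentum * mu
      st$rv <- (1 - momentum) * st$rv + momentum * v
    } else {
      xn <- ad_mul_colvec(ad_add_colvec(x, ad_const(-st$rm)),
                          ad_const(1 / sqrt(st$rv + eps)))
    }
    ad_film(xn, ad_t(gamma), ad_t(beta), times)
  }
}

# LSTM over a list of per-step input matrices (each N x d_in); returns the
# final hidden state (N x d_hidden), or the full list of hidden states when
# return_sequence is TRUE. Forget-gate bias initialized to 1.
nn_lstm <- function(ctx, name, d_in, d_hidden) {
  d <- d_in + d_hidden
  W <- nn_par(ctx, paste0(name, ".W"),
              matrix(stats::runif(d * 4L * d_hidden, -sqrt(1 / d_hidden), sqrt(1 / d_hidden)),
                     d, 4L * d_hidden))
  b0 <- matrix(0, 1L, 4L * d_hidden)
  b0[1L, d_hidden + seq_len(d_hidden)] <- 1
  b <- nn_par(ctx, paste0(name, ".b"), b0)
  H <- d_hidden
  function(xs, N, return_sequence = FALSE) {
    h <- ad_const(matrix(0, N, H))
    cc <- ad_const(matrix(0, N, H))
    hs <- if (return_sequence) vector("list", length(xs)) else NULL
    for (k in seq_along(xs)) {
      a <- ad_add_rowvec(ad_matmul(ad_cbind(list(xs[[k]], h)), W), b)
      i <- ad_sigmoid(ad_slice_cols(a, seq_len(H)))
      f <- ad_sigmoid(ad_slice_cols(a, H + seq_len(H)))
      g <- ad_tanh(ad_slice_cols(a, 2L * H + seq_len(H)))
      o <- ad_sigmoid(ad_slice_cols(a, 3L * H + seq_len(H)))
      cc <- ad_add(ad_mul(f, cc), ad_mul(i, g))
      h <- ad_mul(o, ad_tanh(cc))
      if (return_sequence) hs[[k]] <- h
    }
    if (return_sequence) hs else h
  }
}

nn_layernorm <- function(ctx, name, d, eps = 1e-5) {
  gamma <- nn_par(ctx, paste0(name, ".gamma"), matrix(1, 1L, d))
  beta <- nn_par(ctx, paste0(name, ".beta"), matrix(0, 1L, d))
  function(x) ad_add_rowvec(ad_mul_rowvec(ad_norm_rows(x, eps), gamma), beta)
}

# Multi-head self-attention over one sequence (T x d in, T x d out).
nn_mha <- function(ctx, name, d, heads) {
  stopifnot(d %% heads == 0L)
  dh <- d %/% heads
  Wq <- nn_dense(ctx, paste0(name, ".q"), d, d)
  Wk <- nn_dense(ctx, paste0(name, ".k"), d, d)
  Wv <- nn_dense(ctx, paste0(name, ".v"), d, d)
  Wo <- nn_dense(ctx, paste0(name, ".o"), d, d)
  function(x) {
    q <- Wq(x); k <- Wk(x); v <- Wv(x)
    outs <- vector("list", heads)
    for (hh in seq_len(heads)) {
      cols <- (hh - 1L) * dh + seq_len(dh)
      qh <- ad_slice_cols(q, cols)
      kh <- ad_slice_cols(k, cols)
      vh <- ad_slice_cols(v, cols)
      att <- ad_softmax_rows(ad_scale(ad_matmul(qh, ad_t(kh)), 1 / sqrt(dh)))
      outs[[hh]] <- ad_matmul(att, vh)
    }
    Wo(ad_cbind(outs))
  }
}

# Transformer encoder layer (post-norm): MHA + residual + LN, FFN + residual + LN.
nn_transformer_layer <- function(ctx, name, d, heads, d_ff = 4L * d) {
  mha <- nn_mha(ctx, paste0(name, ".mha"), d, heads)
  ln1 <- nn_layernorm(ctx, paste0(name, ".ln1"), d)
  ff1 <- nn_dense(ctx, paste0(name, ".ff1"), d, d_ff)
  ff2 <- nn_dense(ctx, paste0(name, ".ff2"), d_ff, d)
  ln2 <- nn_layernorm(ctx, paste0(name, ".ln2"), d)
  function(x) {
    x <- ln1(ad_add(x, mha(x)))
    ln2(ad_add(x, ff2(ad_relu(ff1(x)))))
  }
}

## ---- parameter bookkeeping --------------------------------------------------

nn_param_count <- function(ctx, prefix = NULL) {
  nm <- names(ctx$params)
  if (!is.null(prefix)) nm <- nm[startsWith(nm, prefix)]
  sum(vapply(ctx$params[nm], function(p) length(p$value), numeric(1L)))
}

nn_state_get <- function(ctx) {
  list(params = lapply(ctx$params, function(p) p$value),
       buffers = lapply(ctx$buffers, function(st) list(rm = st$rm, rv = st$rv)))
}

nn_state_set <- function(ctx, state) {
  for (nm in names(state$params)) ctx$params[[nm]]$value <- state$params[[nm]]
  for (nm in names(state$buffers)) {
    ctx$buffers[[nm]]$rm <- state$buffers[[nm]]$rm
    ctx$buffers[[nm]]$rv <- state$buffers[[nm]]$rv
  }
  invisible(ctx)
}

nn_zero_grads <- function(ctx) {
  for (p in ctx$params) p$grad <- NULL
  invisible(NULL)
}
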