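# The reverse-mode engine: every operator's analytic gradient must agree
# with central finite differences, and forward values must be reproducible.

ad <- function(name) get(name, asNamespace("afibnet"))

test_that("dense/softmax-cross-entropy gradients match finite differences", {
  set.seed(42)
  W <- ad("ad_param")(matrix(rnorm(12), 4, 3))
  b <- ad("ad_param")(matrix(rnorm(3), 1, 3))
  X <- matrix(rnorm(20), 5, 4)
  y <- diag(3)[sample(1:3, 5, TRUE), ]
  errs <- grad_check(function() {
    ad("ad_wce_logits")(ad("ad_add_rowvec")(ad("ad_matmul")(ad("ad_const")(X), W), b),
                        y, c(1.5, 1, 0.5))
  }, list(W = W, b = b))
  expect_lt(max(errs), 1e-5)
})

test_that("normalization, pooling and activation gradients are exact", {
  set.seed(43)
  A <- ad("ad_param")(matrix(rnorm(24), 4, 6))
  g2 <- ad("ad_param")(matrix(rnorm(4), 4, 1))
  errs <- grad_check(function() {
    xn <- ad("ad_norm_rows")(A, 1e-5)
    o <- ad("ad_add_colvec")(ad("ad_mul_colvec")(ad("ad_tanh")(xn), g2), g2)
    pooled <- ad("ad_t")(ad("ad_pool_cols")(ad("ad_sigmoid")(o), 2L))
    ad("ad_wce_logits")(pooled, diag(4)[c(1, 2, 3), ], rep(1, 4))
  }, list(A = A, g2 = g2))
  expect_lt(max(errs), 1e-5)
})

test_that("attention-style softmax/matmul gradients are exact", {
  set.seed(44)
  Q <- ad("ad_param")(matrix(rnorm(8), 4, 2))
  V <- ad("ad_param")(matrix(rnorm(8), 4, 2))
  errs <- grad_check(function() {
    att <- ad("ad_softmax_rows")(ad("ad_scale")(ad("ad_matmul")(Q, ad("ad_t")(Q)), 0.7))
    ad("ad_wce_logits")(ad("ad_matmul")(att, V), diag(2)[c(1, 2, 1, 2), ], c(1, 2))
  }, list(Q = Q, V = V))
  expect_lt(max(errs), 1e-5)
})

test_that("FiLM modulation gradients are exact", {
  set.seed(45)
  X <- ad("ad_param")(matrix(rnorm(18), 3, 6))
  G <- ad("ad_param")(matrix(rnorm(6), 3, 2))
  B <- ad("ad_param")(matrix(rnorm(6), 3, 2))
  errs <- grad_check(function() {
    y <- ad("ad_film")(X, G, B, 3L)
    ad("ad_wce_logits")(ad("ad_t")(ad("ad_pool_cols")(y, 3L)),
                        diag(3)[c(2, 3), ], rep(1, 3))
  }, list(X = X, G = G, B = B))
  expect_lt(max(errs), 1e-5)
})

test_that("convolution matches a naive reference and its gradients check out", {
  set.seed(46)
  ctx <- ad("nn_ctx")()
  conv <- ad("nn_conv2d")(ctx, "c", 3L, 4L, 3L, sh = 2L)
  H <- 5L; Wsp <- 6L; N <- 2L
  X <- ad("ad_param")(matrix(rnorm(3 * H * Wsp * N), 3))

  naive_conv <- function(xa, Wm, bm, k, s) {
    cin <- nrow(xa); cout <- nrow(Wm); p <- (k - 1) %/% 2
    Ho <- (H + 2 * p - k) %/% s + 1
    Wo <- (Wsp + 2 * p - k) %/% s + 1
    y <- matrix(0, cout, Ho * Wo * N)
    for (n in 1:N) for (wo in 1:Wo) for (ho in 1:Ho) {
      acc <- bm
      for (dw in 1:k) for (dh in 1:k) {
        h <- (ho - 1) * s + dh - p
        w <- (wo - 1) * s + dw - p
        if (h >= 1 && h <= H && w >= 1 && w <= Wsp) {
          xi <- xa[, (n - 1) * H * Wsp + (w - 1) * H + h]
          blk <- ((dw - 1) * k + (dh - 1)) * cin
          acc <- acc + Wm[, blk + 1:cin, drop = FALSE] %*% xi
        }
      }
      y[, (n - 1) * Ho * Wo + (wo - 1) * Ho + ho] <- acc
    }
    y
  }
  out <- conv(X, H, Wsp, N)
  ref <- naive_conv(X$value, ctx$params$c.W$value, ctx$params$c.b$value, 3L, 2L)
  expect_lt(max(abs(out$y$value - ref)), 1e-10)

  errs <- grad_check(function() {
    o <- conv(X, H, Wsp, N)
    ad("ad_wce_logits")(ad("ad_t")(ad("ad_pool_cols")(o$y, o$H * o$W)),
                        diag(4)[c(1, 3), ], rep(1, 4))
  }, list(W = ctx$params$c.W, b = ctx$params$c.b, X = X))
  expect_lt(max(errs), 1e-5)
})

test_that("LSTM layer gradients flow through time", {
  set.seed(47)
  ctx <- ad("nn_ctx")()
  lstm <- ad("nn_lstm")(ctx, "l", 3L, 4L)
  xs <- lapply(1:5, function(t) ad("ad_const")(matrix(rnorm(6), 2, 3)))
  errs <- grad_check(function() {
    h <- lstm(xs, 2L)
    ad("ad_wce_logits")(h, diag(4)[c(1, 4), ], rep(1, 4))
  }, ctx$params)
  expect_lt(max(errs), 1e-5)
})
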