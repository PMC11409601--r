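# Loss, class weights, learning-rate schedule, optimizer behaviour, fitting
# mechanics, staged RCLSTM training and cross-validation.

test_that("weighted cross-entropy reproduces hand-evaluated cases", {
  # exact one-hot prediction: zero loss
  y <- diag(4)[c(1, 3), ]
  expect_equal(weighted_cross_entropy(y, y), 0, tolerance = 1e-12)
  # uniform prediction over C classes: log(C)
  u <- matrix(0.25, 3, 4)
  expect_equal(weighted_cross_entropy(u, diag(4)[c(1, 2, 4), ]), log(4),
               tolerance = 1e-12)
  # N = 2, C = 2, alpha = (2, 1)
  pred <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  truth <- rbind(c(1, 0), c(0, 1))
  expect_equal(weighted_cross_entropy(pred, truth, c(2, 1)),
               -0.5 * (2 * log(0.8) + 1 * log(0.6)), tolerance = 1e-12)
  expect_error(weighted_cross_entropy(pred, truth[1, , drop = FALSE]), "dim")
})

test_that("the packaged loss agrees with the fused training-path loss", {
  af <- asNamespace("afibnet")
  set.seed(8)
  for (i in 1:25) {
    n <- sample(1:16, 1)
    C <- sample(c(2L, 4L), 1)
    logits <- matrix(rnorm(n * C, sd = 3), n, C)
    probs <- exp(logits - apply(logits, 1, max))
    probs <- probs / rowSums(probs)
    y <- diag(C)[sample(seq_len(C), n, TRUE), , drop = FALSE]
    alpha <- runif(C, 0.2, 3)
    fused <- af$ad_wce_logits(af$ad_const(logits), y, alpha)$value[1, 1]
    expect_equal(weighted_cross_entropy(probs, y, alpha), fused,
                 tolerance = 1e-9)
  }
})

test_that("inverse-frequency class weights normalize to mean one", {
  expect_equal(class_weights(c(10, 10, 10)), rep(1, 3), ignore_attr = TRUE)
  expect_equal(class_weights(c(300, 100)), c(0.5, 1.5), ignore_attr = TRUE)
  w <- class_weights(c(50, 10, 5, 100))
  expect_equal(mean(w), 1)
  expect_true(all(diff(w[order(c(50, 10, 5, 100), decreasing = TRUE)]) >= 0))
})

test_that("the step-decay schedule has exactly three drops", {
  cfg <- train_config()
  expect_equal(lr_at(0, 1000, cfg), 1e-3)
  expect_equal(lr_at(600, 1000, cfg), 1e-5) # two decay points passed
  expect_equal(lr_at(990, 1000, cfg), 1e-6) # all three passed
  lrs <- vapply(0:999, lr_at, 0, total_steps = 1000, config = cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_identical(sum(diff(lrs) < 0), 3L)
  expect_error(lr_at(1000, 1000, cfg), "step")
})

test_that("fitting runs, records history and validates inputs", {
  recs <- fixture_records(c(NSR = 6, AFib = 6), seed = 14, duration_s = 5)
  pp <- preprocess_config(target_len = 1536L)
  m <- build_model(model_config("dualnet", "S", n_classes = 2L), seed = 2)
  f <- fit(m, recs[1:8], recs[9:12],
           config = train_config(epochs = 1L, batch_size = 4L, seed = 3),
           pp = pp)
  expect_s3_class(f, "afib_fit")
  expect_identical(nrow(tidy(f)), 1L)
  expect_true(is.finite(f$history$loss))
  expect_true(f$history$val_f1 >= 0 && f$history$val_f1 <= 1)
  expect_identical(glance(f)$epochs, 1L)
  expect_error(fit(m, list(), config = train_config(epochs = 1L)), "empty")
})

test_that("staged RCLSTM training freezes the branches in the final stage", {
  recs <- fixture_records(c(NSR = 4, AFib = 4), seed = 15, duration_s = 5)
  pp <- preprocess_config(target_len = 1536L)
  m <- build_model(model_config("rclstm", "S", n_classes = 2L), seed = 5)
  tc <- train_config(epochs = 1L, batch_size = 4L, seed = 6)
  before <- lapply(m$ctx$params, function(p) p$value)
  expect_warning(expect_warning(
    fit_rclstm_staged(m, recs, tc, pp = pp),
    "ResNet pretraining"), "beat pretraining")
  changed <- names(Filter(isTRUE, lapply(names(before), function(nm)
    !isTRUE(all.equal(before[[nm]], m$ctx$params[[nm]]$value))) |>
      stats::setNames(names(before))))
  expect_gt(length(changed), 0)
  expect_true(all(startsWith(changed, "fuse.")))
  # with pretraining data all three stages run and touch their components
  m2 <- build_model(model_config("rclstm", "S", n_classes = 2L), seed = 5)
  before2 <- lapply(m2$ctx$params, function(p) p$value)
  m2 <- fit_rclstm_staged(m2, recs, tc, pretrain_resnet = recs,
                          pretrain_beats = recs, pp = pp)
  hist <- attr(m2, "stage_history")
  expect_named(hist, c("resnet", "cnn", "clstm", "fusion"))
  expect_identical(nrow(hist$fusion), 1L) # final stage is a single epoch
  changed2 <- names(Filter(isTRUE, lapply(names(before2), function(nm)
    !isTRUE(all.equal(before2[[nm]], m2$ctx$params[[nm]]$value))) |>
      stats::setNames(names(before2))))
  expect_true(any(startsWith(changed2, "resnet.")))
  expect_true(any(startsWith(changed2, "clstm.")))
})

test_that("cross-validation folds are disjoint, stratified and averaged", {
  recs <- fixture_records(c(NSR = 20, AFib = 20), seed = 16, duration_s = 10)
  fit_fn <- function(tr, va) {
    bl <- build_model(model_config("baseline", threshold = 0.1))
    function(r) predict_dataset(bl, r)
  }
  cv <- cross_validate(recs, k = 4, fit_fn = fit_fn, seed = 4)
  expect_length(cv$per_fold, 4)
  expect_equal(cv$mean, mean(cv$per_fold))
  expect_identical(sort(unique(cv$folds)), 1:4)
  expect_identical(unname(lengths(split(seq_along(recs), cv$folds))),
                   rep(10L, 4))
  labs <- vapply(recs, function(r) r$label, "")
  per_fold_counts <- table(cv$folds, labs)
  expect_true(all(abs(per_fold_counts - 5) <= 1))
})
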