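# Model construction, the uniform prediction interface and the baseline.

short_pp <- preprocess_config(target_len = 1536L)

test_that("all families emit simplex probabilities, deterministically", {
  recs <- fixture_records(c(NSR = 2, AFib = 1), seed = 9, duration_s = 5)
  for (fam in c("dualnet", "dualnet_pp", "rclstm")) {
    m <- build_model(model_config(fam, "S", n_classes = 4L), seed = 3)
    pr <- predict_dataset(m, recs, short_pp)
    probs <- as.matrix(pr[, paste0("p_", afib_classes())])
    expect_true(all(probs >= 0))
    expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
    expect_identical(pr$record_id, vapply(recs, function(r) r$record_id, ""))
    expect_identical(predict_dataset(m, recs, short_pp), pr)
  }
})

test_that("gradients are finite for random inputs in every family", {
  af <- asNamespace("afibnet")
  recs <- fixture_records(c(NSR = 2, AFib = 2), seed = 10, duration_s = 5)
  y <- af$onehot(vapply(recs, function(r) r$label, ""), c("NSR", "AFib"))
  for (fam in c("dualnet", "dualnet_pp", "rclstm")) {
    m <- build_model(model_config(fam, "S", n_classes = 2L), seed = 4)
    pre <- lapply(recs, function(r)
      af$preprocess_record(r$signal, r$fs, short_pp, fam))
    batch <- af$make_batch(pre, fam, short_pp)
    af$ad_tape_begin()
    loss <- af$ad_wce_logits(m$forward(batch, TRUE), y, c(1, 1))
    af$ad_backward(loss)
    af$ad_tape_end()
    grads <- Filter(Negate(is.null), lapply(m$ctx$params, function(p) p$grad))
    expect_gt(length(grads), 0)
    expect_true(all(vapply(grads, function(g) all(is.finite(g)), TRUE)))
    af$nn_zero_grads(m$ctx)
  }
})

test_that("parameter counting matches hand arithmetic", {
  af <- asNamespace("afibnet")
  ctx <- af$nn_ctx()
  af$nn_dense(ctx, "lin", 4L, 3L)
  expect_identical(af$nn_param_count(ctx), 15) # 4*3 + 3
  m <- build_model(model_config("baseline"))
  expect_identical(count_parameters(m), 0)
})

test_that("count is invariant to running inference", {
  m <- build_model(model_config("dualnet", "S"), seed = 5)
  n0 <- count_parameters(m)
  invisible(predict_dataset(m, fixture_records(c(NSR = 1), seed = 11,
                                               duration_s = 5), short_pp))
  expect_identical(count_parameters(m), n0)
})

test_that("the RCLSTM handles records with zero detected beats", {
  m <- build_model(model_config("rclstm", "S", n_classes = 4L), seed = 6)
  flat <- ecg_record("flat", numeric(1500), fs = 300, label = "NSR")
  pr <- predict_dataset(m, list(flat), short_pp)
  probs <- as.matrix(pr[, paste0("p_", afib_classes())])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
})

test_that("beat counts do not change the output dimensionality", {
  m <- build_model(model_config("rclstm", "S", n_classes = 4L), seed = 6)
  short <- fixture_records(c(NSR = 1), seed = 12, duration_s = 5)[[1]]
  long <- fixture_records(c(AFib = 1), seed = 13, duration_s = 30)[[1]]
  pr <- predict_dataset(m, list(short, long), preprocess_config(target_len = 3000L))
  expect_identical(nrow(pr), 2L)
  expect_identical(ncol(pr), 6L)
})

test_that("the beat-interval baseline implements its decision rule", {
  reg <- fixture_clean_record("NSR", rr = 0.8, duration_s = 20)
  expect_identical(as.character(baseline_bbi(reg, 0.1)$label), "NSR")
  spec <- rhythm_spec("AFib", duration_s = 20, rr_mean_s = 0.8, rr_cv = 0.3,
                      noise_sigma = 0.05, seed = 21)
  irr <- synthesize_ecg(generate_rr_series(spec), spec)
  expect_identical(as.character(baseline_bbi(irr, 0.1)$label), "AFib")
  flat <- ecg_record("flat", numeric(3000), fs = 300)
  expect_identical(as.character(baseline_bbi(flat, 0.1)$label), "NSR")
  p <- baseline_bbi(reg, 0.1)
  expect_identical(p$p_NSR + p$p_AFib, 1) # one-hot
})

test_that("model configuration validates sizes and overrides", {
  expect_error(model_config("dualnet", size = "130M"), "unknown size")
  cfg <- model_config("dualnet", "S", latent = 64)
  expect_identical(cfg$latent, 64)
  expect_error(model_config("dualnet", n_classes = 3), "n_classes")
})
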