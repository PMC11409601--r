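# The challenge scoring harness.

tb <- function(ids, labels) tibble::tibble(record_id = ids, label = labels)

test_that("binary relabeling drops Other/Noisy truth and maps predictions", {
  ref <- tb(c("a", "b", "c", "d"), c("NSR", "AFib", "Other", "Noisy"))
  pred <- tb(c("a", "b", "c", "d"), c("NSR", "AFib", "NSR", "NSR"))
  pairs <- relabel_for_binary(pred, ref)
  expect_identical(pairs$record_id, c("a", "b"))
  expect_identical(as.character(pairs$pred), c("NSR", "AFib"))
  # a prediction of Other for AFib truth becomes a false negative (A -> N)
  pairs2 <- relabel_for_binary(tb("b", "Other"), ref)
  expect_identical(as.character(pairs2$ref), c("NSR", "AFib"))
  expect_identical(as.character(pairs2$pred), c("NSR", "NSR"))
  expect_equal(f1_binary(pairs2), 0)
  # empty prediction set scores every kept record as predicted NSR
  pairs3 <- relabel_for_binary(tb(character(), character()), ref)
  expect_identical(as.character(pairs3$pred), c("NSR", "NSR"))
  # unknown prediction ids are an error
  expect_error(relabel_for_binary(tb("zz", "NSR"), ref), "unknown record ids")
})

test_that("binary F1 matches hand-evaluated counts", {
  pairs <- tibble::tibble(
    ref = afibnet:::label_factor(c(rep("AFib", 10), rep("NSR", 10))),
    pred = afibnet:::label_factor(c(rep("AFib", 8), rep("NSR", 2),
                                    rep("AFib", 2), rep("NSR", 8))))
  expect_equal(f1_binary(pairs), 0.8) # TP 8, FP 2, FN 2
  perfect <- tibble::tibble(ref = pairs$ref, pred = pairs$ref)
  expect_equal(f1_binary(perfect), 1)
  allnsr <- tibble::tibble(ref = pairs$ref,
                           pred = afibnet:::label_factor(rep("NSR", 20)))
  expect_equal(f1_binary(allnsr), 0)
})

test_that("macro and CinC scores follow their analytic values", {
  ref <- rep(afib_classes(), each = 10)
  expect_equal(f1_macro(ref, ref), 1)
  expect_equal(f1_cinc(ref, ref), 1)
  expect_equal(f1_macro(rep("NSR", 40), ref), 0.1)
  expect_equal(f1_cinc(rep("NSR", 40), ref), 0.4 / 3)
  # record order invariance
  set.seed(5)
  pred <- sample(afib_classes(), 40, TRUE)
  o <- sample(40)
  expect_equal(f1_macro(pred, ref), f1_macro(pred[o], ref[o]))
  expect_equal(f1_cinc(pred, ref), f1_cinc(pred[o], ref[o]))
})

test_that("degenerate per-class F1 terms follow the documented rules", {
  # Noisy absent from truth and prediction: its term is 1
  ref <- c("NSR", "AFib", "Other")
  pred <- c("NSR", "AFib", "Other")
  expect_equal(f1_macro(pred, ref), 1)
  # class present in exactly one side contributes 0
  expect_equal(f1_macro(c("NSR", "NSR", "NSR"), c("NSR", "NSR", "Noisy")),
               (2 / 2.5 + 1 + 1 + 0) / 4)
})

test_that("score_submission produces a complete, bounded report", {
  td <- withr::local_tempdir()
  res <- generate_dataset(file.path(td, "d"), c(NSR = 3, AFib = 3), seed = 8,
                          duration_s = 5)
  ref_file <- file.path(td, "d", "REFERENCE.csv")
  pred_file <- file.path(td, "ans.csv")
  write_predictions(res$labels, pred_file)
  rep <- score_submission(pred_file, ref_file)
  expect_equal(rep$f1_binary, 1)
  expect_equal(rep$f1_macro, 1)
  expect_equal(rep$accuracy, 1)
  g <- glance(rep)
  expect_identical(nrow(g), 1L)
  # random predictions still give scores inside [0, 1]
  set.seed(9)
  scr <- res$labels
  scr$label <- sample(afib_classes(), nrow(scr), TRUE)
  write_predictions(scr, pred_file)
  rep2 <- score_submission(pred_file, ref_file)
  vals <- c(rep2$f1_binary, rep2$f1_macro, rep2$f1_cinc, rep2$accuracy,
            rep2$per_class_f1)
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("rank-based AUROC matches the pROC oracle; AP behaves", {
  skip_if_not_installed("pROC")
  af <- asNamespace("afibnet")
  set.seed(10)
  for (i in 1:20) {
    score <- rnorm(60)
    pos <- runif(60) < 0.4
    if (!any(pos) || all(pos)) next
    ours <- af$auc_roc(score, pos)
    ref <- as.numeric(pROC::auc(pROC::roc(pos, score, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  # perfect separation gives AP = 1; degenerate labels give NA
  expect_equal(af$auc_pr(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_true(is.na(af$auc_pr(1:3, rep(TRUE, 3))))
})

test_that("the submission store enforces the five-run quota", {
  td <- withr::local_tempdir()
  res <- generate_dataset(file.path(td, "d"), c(NSR = 2, AFib = 2), seed = 3,
                          duration_s = 5)
  pred <- file.path(td, "p.csv")
  write_predictions(res$labels, pred)
  rep <- score_submission(pred, file.path(td, "d", "REFERENCE.csv"))
  store <- file.path(td, "runs.json")
  for (i in 1:5) record_run(store, "alpha", "model-v1", rep)
  expect_error(record_run(store, "alpha", "model-v1", rep), "quota")
  expect_silent(record_run(store, "beta", "model-v2", rep))
  lb <- leaderboard(store)
  expect_identical(nrow(lb), 6L)
  expect_true(all(diff(lb$f1_binary) <= 0))
  # override flag admits a sixth run
  lb2 <- record_run(store, "alpha", "model-v1", rep, force = TRUE)
  expect_identical(sum(lb2$team == "alpha"), 6L)
})
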