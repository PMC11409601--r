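# The synthetic rhythm generator: RR statistics, beat morphology and the
# on-disk dataset dialect.

test_that("degenerate rr_cv gives perfectly regular intervals", {
  spec <- rhythm_spec("NSR", duration_s = 20, rr_mean_s = 0.8, rr_cv = 0,
                      seed = 1)
  rr <- generate_rr_series(spec)
  expect_true(all(rr == 0.8))
  expect_lte(sum(rr), 20)
})

test_that("lognormal RR jitter hits the requested coefficient of variation", {
  # ~10 000 intervals in one long series
  spec <- rhythm_spec("AFib", duration_s = 10000, fs = 1, rr_mean_s = 1.0,
                      rr_cv = 0.3, seed = 42)
  rr <- generate_rr_series(spec)
  expect_gt(length(rr), 5000)
  cv <- stats::sd(rr) / mean(rr)
  expect_gt(cv, 0.2)
  expect_lt(cv, 0.4)
  expect_true(all(rr > 0))
  expect_lte(sum(rr), 10000)
})

test_that("invalid rhythm specifications are rejected", {
  expect_error(rhythm_spec("NSR", duration_s = 10, rr_mean_s = 10), "rr_mean_s")
  expect_error(rhythm_spec("NSR", rr_cv = -1), "rr_cv")
  expect_error(rhythm_spec("Sinus"), "arg")
})

test_that("clean regular records have R-peaks at the prescribed spacing", {
  rec <- fixture_clean_record("NSR", rr = 1.0, duration_s = 30)
  det <- detect_r_peaks(rec$signal, rec$fs)
  expect_gte(length(det), 29 - 1)
  expect_lte(length(det), 31)
  spacing <- diff(det)
  expect_true(all(abs(spacing - 1.0 * rec$fs) <= 1))
  # detections line up with the generator's ground truth
  truth <- attr(rec, "r_peaks")
  expect_true(all(vapply(det, function(p) min(abs(truth - p)), 0) <= 1))
})

test_that("suppressing the P-wave empties the pre-R window", {
  amp_in_window <- function(rec) {
    rp <- attr(rec, "r_peaks")
    rp <- rp[rp > 0.3 * rec$fs]
    mean(vapply(rp, function(p) {
      w <- rec$signal[(p - round(0.2 * rec$fs)):(p - round(0.12 * rec$fs))]
      max(abs(w))
    }, 0))
  }
  nsr <- fixture_clean_record("NSR", rr = 0.8, duration_s = 10)
  af <- fixture_clean_record("AFib", rr = 0.8, duration_s = 10)
  expect_lt(amp_in_window(af), 0.5 * amp_in_window(nsr))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_records(c(NSR = 2, AFib = 2), seed = 5, duration_s = 5)
  b <- generate_records(c(NSR = 2, AFib = 2), seed = 5, duration_s = 5)
  expect_identical(lapply(a, unclass), lapply(b, unclass))
  c2 <- generate_records(c(NSR = 2, AFib = 2), seed = 6, duration_s = 5)
  expect_false(identical(a[[1]]$signal, c2[[1]]$signal))
})

test_that("on-disk datasets have exact per-class counts and reload cleanly", {
  td <- withr::local_tempdir()
  res <- generate_dataset(td, c(NSR = 5, AFib = 5, Other = 5, Noisy = 5),
                          seed = 2, duration_s = 5)
  expect_identical(unname(table(res$labels$label)[afib_classes()]),
                   table(factor(rep(afib_classes(), each = 5),
                                levels = afib_classes()))[afib_classes()] |> unname())
  recs <- read_dataset(td)
  expect_length(recs, 20)
  expect_true(all(vapply(recs, function(r) length(r$signal) == 1500, TRUE)))
  expect_identical(vapply(recs, function(r) r$label, ""),
                   as.character(res$labels$label))
})
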