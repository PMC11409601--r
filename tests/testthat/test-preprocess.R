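# Preprocessing: oversampling, filtering, standardization, spectrograms,
# padding, R-peak detection and beat segmentation.

test_that("oversampling balances exactly and preserves the original prefix", {
  mk <- function(cls, n) lapply(seq_len(n), function(i)
    ecg_record(paste0(cls, i), rnorm(10), label = cls))
  recs <- c(mk("NSR", 10), mk("AFib", 4), mk("Other", 2), mk("Noisy", 1))
  set.seed(1)
  out <- oversample_to_balance(recs)
  labs <- vapply(out, function(r) r$label, "")
  expect_true(all(table(labs) == 10))
  expect_identical(out[seq_along(recs)], recs)
  # copies are verbatim duplicates of existing records
  extra <- out[-seq_along(recs)]
  expect_true(all(vapply(extra, function(e)
    any(vapply(recs, function(r) identical(r, e), TRUE)), TRUE)))
  # balanced input is returned unchanged
  bal <- c(mk("NSR", 3), mk("AFib", 3))
  expect_identical(oversample_to_balance(bal), bal)
  expect_error(oversample_to_balance(list()), "no records")
})

test_that("the FIR bandpass attenuates out-of-band and passes in-band tones", {
  fs <- 300
  t <- (0:2999) / fs
  hum <- sin(2 * pi * 60 * t)
  mid <- sin(2 * pi * 10 * t)
  rms <- function(x) sqrt(mean(x^2))
  expect_lte(rms(fir_bandpass(hum, fs, 0.5, 40)), 0.05 * rms(hum))
  expect_gte(rms(fir_bandpass(mid, fs, 0.5, 40)), 0.90 * rms(mid))
  expect_identical(fir_bandpass(numeric(100) , fs, 0.5, 40), numeric(100))
  expect_length(fir_bandpass(rnorm(777), fs, 0.5, 40), 777)
  expect_error(fir_bandpass(rnorm(10), fs, 40, 0.5), "band")
  expect_error(fir_bandpass(rnorm(10), fs, 0.5, 200), "band")
})

test_that("standardization is exact, affine-invariant and idempotent", {
  y <- standardize(c(1, 2, 3))
  expect_lt(abs(mean(y)), 1e-9)
  expect_lt(abs(stats::sd(y) - 1), 1e-9)
  expect_identical(standardize(rep(2, 5)), numeric(5))
  expect_error(standardize(1), "length")
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(50)
    a <- runif(1, 0.1, 5)
    b <- rnorm(1)
    expect_equal(standardize(a * x + b), standardize(x), tolerance = 1e-9)
    expect_equal(standardize(-x), -standardize(x), tolerance = 1e-9)
    expect_equal(standardize(standardize(x)), standardize(x), tolerance = 1e-9)
  }
})

test_that("spectrogram geometry follows the frame-count formula", {
  s <- log_spectrogram(rnorm(18000))
  expect_identical(dim(unclass(s)), c(64L, 561L))
  expect_identical(ncol(log_spectrogram(rnorm(64))), 1L)
  set.seed(3)
  for (L in as.integer(c(64, 65, 95, 96, sample(64:20000, 25)))) {
    expect_identical(dim(unclass(log_spectrogram(rnorm(L)))),
                     c(64L, (L - 64L) %/% 32L + 1L))
  }
  expect_error(log_spectrogram(rnorm(63)), "window")
  # all-zero input gives log(eps) everywhere
  z <- log_spectrogram(numeric(128), eps = 1e-6)
  expect_true(all(abs(unclass(z) - log(1e-6)) < 1e-12))
})

test_that("padding and cropping land on the exact target", {
  expect_equal(pad_or_crop(1:10, 16), c(1:10, rep(0, 6)))
  expect_identical(pad_or_crop(1:20, 16), 3:18) # 0-based samples 2..17
  x <- rnorm(16)
  expect_identical(pad_or_crop(x, 16), x)
})

test_that("the Hamilton detector finds clean and moderately noisy beats", {
  rec <- fixture_clean_record("NSR", rr = 1.0, duration_s = 30)
  det <- detect_r_peaks(rec$signal, rec$fs)
  truth <- attr(rec, "r_peaks")
  tol <- 0.05 * rec$fs
  expect_gte(length(det), 28)
  expect_true(all(vapply(det, function(p) min(abs(truth - p)) <= tol, TRUE)))
  expect_identical(detect_r_peaks(numeric(3000), 300), integer(0))
  expect_true(all(diff(det) > 0))
})

test_that("beat segments are two seconds with boundary zero-padding", {
  fs <- 300
  x <- rnorm(3000)
  segs <- segment_beats(x, c(1L, 1500L, 2950L), fs)
  expect_length(segs, 3)
  expect_true(all(vapply(segs, function(s) length(s$values) == 2 * fs, TRUE)))
  # peak at sample 1: the first second (minus one sample) is zero padding
  expect_true(all(segs[[1]]$values[1:(fs - 1)] == 0))
  # mid-record peak equals the raw slice
  expect_identical(segs[[2]]$values, x[(1500 - fs):(1500 + fs - 1)])
  # end-of-record peak is right-padded
  expect_true(all(tail(segs[[3]]$values, (2950 + fs - 1) - 3000) == 0))
})
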