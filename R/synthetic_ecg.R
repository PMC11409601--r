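# Synthetic single-lead ECG generator.
#
# Records are rendered as sums of Gaussian bumps (P, Q, R, S, T) centered on
# beat positions drawn from a lognormal RR-interval model. The generator
# encodes exactly the physiology the classifiers exploit: sinus rhythm has
# regular RR intervals and P-waves; atrial fibrillation has irregular RR
# intervals, no P-waves and a low-amplitude 4-9 Hz fibrillatory oscillation;
# "other rhythm" is rendered as bigeminy-like alternating short/long RR with
# P-waves present; the noisy class drowns the waveform in Gaussian noise.

# Gaussian beat template: time offsets from the R-peak (s), widths (s, as the
# Gaussian s.d.), and amplitudes relative to a 1 mV R-peak. The P bump is
# centered 160 ms before R so it falls inside the conventional 120-200 ms
# pre-R window.
.beat_template <- list(
  wave = c("P", "Q", "R", "S", "T"),
  offset = c(-0.160, -0.035, 0.000, 0.035, 0.220),
  width = c(0.022, 0.012, 0.014, 0.012, 0.045),
  amp = c(0.15, -0.12, 1.00, -0.25, 0.35)
)

# Per-class default rhythm statistics. NSR uses a small RR coefficient of
# variation, AFib a large one; the noisy class uses noise at or above the
# QRS amplitude.
.class_defaults <- list(
  NSR = list(rr_mean_s = 0.85, rr_cv = 0.03, p_wave = TRUE, noise_sigma = 0.05),
  AFib = list(rr_mean_s = 0.75, rr_cv = 0.30, p_wave = FALSE, noise_sigma = 0.05),
  Other = list(rr_mean_s = 0.90, rr_cv = 0.05, p_wave = TRUE, noise_sigma = 0.05),
  Noisy = list(rr_mean_s = 0.85, rr_cv = 0.10, p_wave = TRUE, noise_sigma = 1.2)
)

#' Specify a synthetic rhythm
#'
#' @param cls Rhythm class, one of [afib_classes()].
#' @param duration_s Record duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param rr_mean_s Mean beat-to-beat (RR) interval in seconds.
#' @param rr_cv Coefficient of variation of the RR intervals (lognormal
#'   jitter around `rr_mean_s`; 0 gives a perfectly regular rhythm).
#' @param p_wave Render a P-wave before each QRS complex? When `FALSE` a
#'   4-9 Hz low-amplitude fibrillatory oscillation is added instead.
#' @param noise_sigma Additive Gaussian noise s.d. relative to the R-peak
#'   amplitude (1 mV).
#' @param seed Optional integer seed making the record reproducible.
#' @return A `rhythm_spec` list.
#' @export
rhythm_spec <- function(cls, duration_s = 30, fs = 300,
                        rr_mean_s = NULL, rr_cv = NULL, p_wave = NULL,
                        noise_sigma = NULL, seed = NULL) {
  cls <- match.arg(cls, afib_classes())
  d <- .class_defaults[[cls]]
  spec <- list(cls = cls, duration_s = duration_s, fs = fs,
               rr_mean_s = rr_mean_s %||% d$rr_mean_s,
               rr_cv = rr_cv %||% d$rr_cv,
               p_wave = p_wave %||% d$p_wave,
               noise_sigma = noise_sigma %||% d$noise_sigma,
               seed = seed)
  if (spec$rr_mean_s <= 0 || spec$rr_mean_s >= spec$duration_s)
    stop("rr_mean_s must lie in (0, duration_s)", call. = FALSE)
  if (spec$rr_cv < 0) stop("rr_cv must be >= 0", call. = FALSE)
  n <- spec$duration_s * spec$fs
  if (abs(n - round(n)) > 1e-9 || n < 1)
    stop("duration_s * fs must be a positive integer", call. = FALSE)
  structure(spec, class = "rhythm_spec")
}

#' Draw a beat-to-beat interval series
#'
#' RR intervals are drawn from a lognormal distribution parameterized so the
#' mean equals `rr_mean_s` and the coefficient of variation equals `rr_cv`
#' (`rr_cv = 0` degenerates to constant intervals). For the "Other" class a
#' bigeminy-like alternation multiplies successive intervals by 0.7 and 1.3.
#' Drawing stops before the cumulative sum exceeds the record duration.
#'
#' @param spec A [rhythm_spec()].
#' @return Numeric vector of positive RR intervals (s) whose cumulative sum
#'   stays below `duration_s`.
#' @export
generate_rr_series <- function(spec) {
  stopifnot(inherits(spec, "rhythm_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n_max <- ceiling(spec$duration_s / spec$rr_mean_s * 3) + 10L
  if (spec$rr_cv > 0) {
    sdlog <- sqrt(log1p(spec$rr_cv^2))
    meanlog <- log(spec$rr_mean_s) - sdlog^2 / 2
    rr <- stats::rlnorm(n_max, meanlog, sdlog)
  } else {
    rr <- rep(spec$rr_mean_s, n_max)
  }
  if (spec$cls == "Other") {
    rr <- rr * rep_len(c(0.7, 1.3), length(rr))
  }
  keep <- cumsum(rr) <= spec$duration_s - 0.5 * spec$rr_mean_s
  rr[keep]
}

#' Render a synthetic ECG record from an RR series
#'
#' @param rr RR-interval vector (s), e.g. from [generate_rr_series()].
#' @param spec The [rhythm_spec()] that produced it.
#' @param record_id Identifier for the resulting record.
#' @return An [ecg_record()] with the class label attached and the
#'   ground-truth R-peak sample indices stored in `attr(, "r_peaks")`.
#' @export
synthesize_ecg <- function(rr, spec, record_id = "synth") {
  stopifnot(inherits(spec, "rhythm_spec"))
  n <- as.integer(round(spec$duration_s * spec$fs))
  tt <- (seq_len(n) - 1L) / spec$fs
  x <- numeric(n)
  centers <- cumsum(rr)
  tpl <- .beat_template
  waves <- if (spec$p_wave) seq_along(tpl$wave) else which(tpl$wave != "P")
  for (ct in centers) {
    lo <- max(1L, floor((ct - 0.5) * spec$fs))
    hi <- min(n, ceiling((ct + 0.5) * spec$fs))
    if (lo > hi) next
    seg <- tt[lo:hi]
    for (w in waves) {
      x[lo:hi] <- x[lo:hi] +
        tpl$amp[w] * exp(-0.5 * ((seg - ct - tpl$offset[w]) / tpl$width[w])^2)
    }
  }
  if (!spec$p_wave) {
    f <- stats::runif(1L, 4, 9)
    phi <- stats::runif(1L, 0, 2 * pi)
    x <- x + 0.06 * sin(2 * pi * f * tt + phi)
  }
  if (spec$noise_sigma > 0) x <- x + stats::rnorm(n, 0, spec$noise_sigma)
  rec <- ecg_record(record_id, x, fs = spec$fs, label = spec$cls)
  attr(rec, "r_peaks") <- as.integer(round(centers * spec$fs)) + 1L
  rec
}

# One-call convenience: spec -> record (seed handling inside the spec).
synth_record <- function(cls, record_id = "synth", seed = NULL, ...) {
  spec <- rhythm_spec(cls, seed = seed, ...)
  if (!is.null(seed)) set.seed(seed)
  spec$seed <- NULL # RNG state already set; keep downstream draws sequential
  synthesize_ecg(generate_rr_series(spec), spec, record_id = record_id)
}

#' Generate a labeled set of synthetic records in memory
#'
#' Per-record mean heart rates are jittered within a physiological range so
#' records differ in rate as well as rhythm. Deterministic for a fixed seed.
#'
#' @param n_per_class Named integer vector of per-class record counts, e.g.
#'   `c(NSR = 5, AFib = 5)`; names must be rhythm classes.
#' @param seed Integer seed.
#' @param duration_s,fs Record duration (s) and sampling rate (Hz).
#' @return List of labeled [ecg_record()] objects with ids `S00001, ...`.
#' @export
generate_records <- function(n_per_class, seed = 1L, duration_s = 30, fs = 300) {
  stopifnot(!is.null(names(n_per_class)),
            all(names(n_per_class) %in% afib_classes()),
            all(n_per_class >= 0))
  set.seed(seed)
  rr_range <- list(NSR = c(0.70, 1.00), AFib = c(0.60, 0.90),
                   Other = c(0.80, 1.00), Noisy = c(0.70, 1.00))
  recs <- list()
  k <- 0L
  for (cls in names(n_per_class)) {
    for (i in seq_len(n_per_class[[cls]])) {
      k <- k + 1L
      rng <- rr_range[[cls]]
      spec <- rhythm_spec(cls, duration_s = duration_s, fs = fs,
                          rr_mean_s = stats::runif(1L, rng[1L], rng[2L]))
      recs[[k]] <- synthesize_ecg(generate_rr_series(spec), spec,
                                  record_id = sprintf("S%05d", k))
    }
  }
  recs
}

#' Generate a synthetic dataset on disk
#'
#' Writes format-valid `.mat`/`.hea` record pairs plus a `REFERENCE.csv`
#' label file, readable by [read_dataset()].
#'
#' @inheritParams generate_records
#' @param dir Output directory.
#' @return Invisibly, a list with `dir` and the label tibble.
#' @export
generate_dataset <- function(dir, n_per_class, seed = 1L, duration_s = 30,
                             fs = 300) {
  recs <- generate_records(n_per_class, seed = seed, duration_s = duration_s,
                           fs = fs)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (r in recs) write_record(r, dir)
  labels <- tibble::tibble(
    record_id = vapply(recs, function(r) r$record_id, ""),
    label = label_factor(vapply(recs, function(r) r$label, "")))
  write_predictions(labels, file.path(dir, "REFERENCE.csv"))
  invisible(list(dir = dir, labels = labels))
}
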