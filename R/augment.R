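# Stochastic data augmentation: ten operators, each applied independently
# with probability p_apply, in a fixed order so results are reproducible
# under a fixed RNG state. Default parameter ranges are chosen to preserve
# rhythm-class semantics (no operator turns regular RR statistics into
# AFib-like irregularity).

#' The ten augmentation operator names, in application order
#' @return Character vector of operator names.
#' @export
afib_augment_ops <- function() {
  c("dropping", "cutout", "resampling", "random_resampling", "scaling",
    "shifting", "sine", "noise", "window_warp", "bandpass")
}

#' Configure the augmentation pipeline
#'
#' @param p_apply Probability that each enabled operator fires (default 0.2).
#' @param drop_fraction Fraction of samples zeroed by `dropping`.
#' @param cutout_frac_range Range of the zeroed run length (fraction of L).
#' @param resample_range Uniform range of the global resampling factor
#'   (`resampling` changes the signal length by this factor).
#' @param elastic_sd S.d. of the smooth random time-warp offsets
#'   (`random_resampling`), in seconds.
#' @param scale_range Uniform range of the multiplicative `scaling` factor.
#' @param shift_max_frac Maximum circular `shifting`, as a fraction of L.
#' @param sine_amp_frac Maximum sine amplitude relative to the signal s.d.
#' @param sine_freq_range Sine frequency range (Hz).
#' @param noise_sigma_frac Maximum Gaussian noise s.d. relative to signal s.d.
#' @param warp_window_frac Length of the warped window (fraction of L).
#' @param warp_factor_range Stretch/compress factor range for `window_warp`.
#' @param band Bandpass edges (Hz) for the `bandpass` operator.
#' @param enabled_ops Subset of [afib_augment_ops()] that may fire.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(p_apply = 0.2,
                                drop_fraction = 0.05,
                                cutout_frac_range = c(0.02, 0.10),
                                resample_range = c(0.8, 1.2),
                                elastic_sd = 0.05,
                                scale_range = c(0.7, 1.3),
                                shift_max_frac = 0.25,
                                sine_amp_frac = 0.3,
                                sine_freq_range = c(0.1, 2),
                                noise_sigma_frac = 0.1,
                                warp_window_frac = 0.1,
                                warp_factor_range = c(0.5, 2),
                                band = c(0.5, 40),
                                enabled_ops = afib_augment_ops()) {
  stopifnot(p_apply >= 0, p_apply <= 1,
            diff(cutout_frac_range) >= 0, diff(resample_range) >= 0,
            diff(scale_range) >= 0, diff(sine_freq_range) >= 0,
            diff(warp_factor_range) >= 0, band[1] < band[2])
  bad <- setdiff(enabled_ops, afib_augment_ops())
  if (length(bad)) stop("unknown operators: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(p_apply = p_apply, drop_fraction = drop_fraction,
                 cutout_frac_range = cutout_frac_range,
                 resample_range = resample_range, elastic_sd = elastic_sd,
                 scale_range = scale_range, shift_max_frac = shift_max_frac,
                 sine_amp_frac = sine_amp_frac,
                 sine_freq_range = sine_freq_range,
                 noise_sigma_frac = noise_sigma_frac,
                 warp_window_frac = warp_window_frac,
                 warp_factor_range = warp_factor_range, band = band,
                 enabled_ops = enabled_ops),
            class = "augmentation_config")
}

#' Restrict the augmentation pipeline to a model family's profile
#'
#' The dual-domain networks use all ten operators; the RCLSTM family confines
#' augmentation to artificial noise, resampling and window warping.
#'
#' @param config An [augmentation_config()].
#' @param profile `"dualnet"` or `"rclstm"`.
#' @return The config with `enabled_ops` restricted.
#' @export
restrict_profile <- function(config, profile) {
  stopifnot(inherits(config, "augmentation_config"))
  profile <- match.arg(profile, c("dualnet", "rclstm"))
  config$enabled_ops <- if (profile == "rclstm") {
    intersect(afib_augment_ops(), c("noise", "resampling", "window_warp"))
  } else {
    afib_augment_ops()
  }
  config
}

# linear resampling of x to n_out samples over the same support
resample_lin <- function(x, n_out) {
  if (length(x) == 1L) return(rep(x, n_out))
  stats::approx(seq_along(x), x, n = n_out)$y
}

aug_dropping <- function(x, cfg) {
  k <- ceiling(cfg$drop_fraction * length(x))
  x[sample.int(length(x), k)] <- 0
  x
}

aug_cutout <- function(x, cfg) {
  L <- length(x)
  len <- max(1L, round(stats::runif(1L, cfg$cutout_frac_range[1L],
                                    cfg$cutout_frac_range[2L]) * L))
  start <- sample.int(L - len + 1L, 1L)
  x[start:(start + len - 1L)] <- 0
  x
}

aug_resampling <- function(x, cfg) {
  f <- stats::runif(1L, cfg$resample_range[1L], cfg$resample_range[2L])
  resample_lin(x, max(2L, round(length(x) * f)))
}

aug_random_resampling <- function(x, cfg, fs) {
  L <- length(x)
  # smooth offsets at ~1 s knots, interpolated, added to a uniform time grid;
  # the warp is kept monotone by bounding the offset slope
  nk <- max(4L, ceiling(L / fs))
  knots <- stats::rnorm(nk, 0, cfg$elastic_sd * fs)
  offs <- stats::spline(seq(1L, L, length.out = nk), knots, n = L)$y
  slope_cap <- 0.9
  doffs <- pmin(pmax(diff(offs), -slope_cap), slope_cap)
  offs <- c(offs[1L], offs[1L] + cumsum(doffs))
  pos <- pmin(pmax(seq_len(L) + offs, 1), L)
  stats::approx(seq_len(L), x, xout = pos)$y
}

aug_scaling <- function(x, cfg) {
  x * stats::runif(1L, cfg$scale_range[1L], cfg$scale_range[2L])
}

aug_shifting <- function(x, cfg) {
  L <- length(x)
  max_s <- max(1L, floor(cfg$shift_max_frac * L))
  s <- sample.int(2L * max_s + 1L, 1L) - max_s - 1L # in [-max_s, max_s]
  if (s == 0L) return(x)
  if (s > 0L) c(tail(x, s), head(x, L - s)) else c(tail(x, L + s), head(x, -s))
}

aug_sine <- function(x, cfg, fs) {
  amp <- stats::runif(1L, 0, cfg$sine_amp_frac * stats::sd(x))
  f <- stats::runif(1L, cfg$sine_freq_range[1L], cfg$sine_freq_range[2L])
  phi <- stats::runif(1L, 0, 2 * pi)
  x + amp * sin(2 * pi * f * (seq_along(x) - 1L) / fs + phi)
}

aug_noise <- function(x, cfg) {
  sig <- stats::runif(1L, 0, cfg$noise_sigma_frac * stats::sd(x))
  x + stats::rnorm(length(x), 0, sig)
}

aug_window_warp <- function(x, cfg) {
  L <- length(x)
  wlen <- max(2L, round(cfg$warp_window_frac * L))
  start <- sample.int(L - wlen + 1L, 1L)
  f <- stats::runif(1L, cfg$warp_factor_range[1L], cfg$warp_factor_range[2L])
  warped <- resample_lin(x[start:(start + wlen - 1L)], max(2L, round(wlen * f)))
  y <- c(head(x, start - 1L), warped, tail(x, L - start - wlen + 1L))
  # restore the original length: crop/pad at the end, untouched part first
  if (length(y) >= L) y[seq_len(L)] else c(y, numeric(L - length(y)))
}

aug_bandpass <- function(x, cfg, fs) {
  taps <- min(301L, 2L * (length(x) %/% 2L) - 1L)
  if (taps < 5L) return(x)
  fir_bandpass(x, fs, cfg$band[1L], cfg$band[2L], numtaps = taps)
}

#' Apply the stochastic augmentation pipeline to a signal
#'
#' Each enabled operator fires independently with probability `p_apply`, in
#' the fixed order of [afib_augment_ops()]. All operators preserve the signal
#' length except plain `resampling`, which scales it by the drawn factor.
#' Augmentation never alters stored labels (it operates on the raw signal
#' only).
#'
#' @param x Numeric signal (non-empty).
#' @param fs Sampling rate (Hz).
#' @param config An [augmentation_config()].
#' @return The augmented signal.
#' @export
augment <- function(x, fs, config = augmentation_config()) {
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  stopifnot(inherits(config, "augmentation_config"))
  for (op in afib_augment_ops()) {
    if (!op %in% config$enabled_ops) next
    if (stats::runif(1L) >= config$p_apply) next
    x <- switch(op,
                dropping = aug_dropping(x, config),
                cutout = aug_cutout(x, config),
                resampling = aug_resampling(x, config),
                random_resampling = aug_random_resampling(x, config, fs),
                scaling = aug_scaling(x, config),
                shifting = aug_shifting(x, config),
                sine = aug_sine(x, config, fs),
                noise = aug_noise(x, config),
                window_warp = aug_window_warp(x, config),
                bandpass = aug_bandpass(x, config, fs))
  }
  x
}
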