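# Preprocessing: minority-class oversampling, zero-phase FIR bandpass,
# standardization, log-spectrogram, fixed-length padding, Hamilton R-peak
# detection and beat segmentation.

#' Oversample records until class counts are balanced
#'
#' Minority-class recordings are copied (drawn uniformly with replacement)
#' and appended until every class present reaches the majority count. The
#' original list is preserved as a prefix; already balanced input is returned
#' unchanged. Copies are whole, verbatim recordings.
#'
#' @param records List of labeled [ecg_record()] objects.
#' @return The augmented list of records.
#' @export
oversample_to_balance <- function(records) {
  if (length(records) == 0L) stop("no records to oversample", call. = FALSE)
  labels <- vapply(records, function(r) r$label %||% NA_character_, "")
  if (anyNA(labels)) stop("all records must be labeled", call. = FALSE)
  counts <- table(labels)
  target <- max(counts)
  extra <- list()
  for (cls in names(counts)) {
    need <- target - counts[[cls]]
    if (need > 0L) {
      pool <- which(labels == cls)
      pick <- pool[sample.int(length(pool), need, replace = TRUE)]
      extra <- c(extra, records[pick])
    }
  }
  c(records, extra)
}

#' Zero-phase FIR bandpass filter
#'
#' A linear-phase FIR bandpass (windowed design via [signal::fir1()]) applied
#' with group-delay compensation, so the output is phase-aligned with the
#' input and has the same length.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param low_hz,high_hz Band edges; must satisfy `0 < low < high < fs/2`.
#' @param numtaps Odd number of filter taps.
#' @return Filtered signal, same length as `x`.
#' @export
fir_bandpass <- function(x, fs, low_hz = 0.5, high_hz = 40, numtaps = 301L) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("band must satisfy 0 < low < high < fs/2", call. = FALSE)
  if (numtaps %% 2L == 0L) stop("numtaps must be odd", call. = FALSE)
  b <- as.numeric(signal::fir1(numtaps - 1L, c(low_hz, high_hz) / (fs / 2),
                               type = "pass"))
  d <- (numtaps - 1L) %/% 2L
  y <- signal::filter(b, 1, c(x, numeric(d)))
  as.numeric(y[(d + 1L):(d + length(x))])
}

#' Standardize a signal to zero mean and unit variance
#'
#' A constant signal maps to all zeros (documented degenerate rule).
#'
#' @param x Numeric signal of length at least 2.
#' @return Standardized signal.
#' @export
standardize <- function(x) {
  if (length(x) < 2L) stop("signal must have length >= 2", call. = FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(numeric(length(x)))
  (x - mean(x)) / s
}

#' Log-magnitude spectrogram
#'
#' Short-time Fourier magnitudes with a periodic Hann window of length
#' `win = 64`, hop `32`, and exactly `64` one-sided frequency bins (the
#' transform length is `2 * 64 - 2 = 126`, i.e. the 64-sample window is
#' zero-padded so the one-sided bin count is exactly 64), followed by
#' `log(magnitude + eps)`. Frame count is `floor((L - win) / hop) + 1`.
#'
#' @param x Numeric signal of length at least `win`.
#' @param win,hop,nbins Window length, hop size and one-sided bin count.
#' @param eps Log offset.
#' @return A `nbins x n_frames` matrix of class `ecg_spectrogram`.
#' @export
log_spectrogram <- function(x, win = 64L, hop = 32L, nbins = 64L, eps = 1e-6) {
  L <- length(x)
  if (L < win) stop("signal shorter than one window", call. = FALSE)
  nfft <- 2L * nbins - 2L
  starts <- seq.int(1L, L - win + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(win) - 1L) / win)) # periodic Hann
  frames <- matrix(x[outer(seq_len(win) - 1L, starts, "+")], nrow = win)
  frames <- frames * w
  padded <- rbind(frames, matrix(0, nfft - win, ncol(frames)))
  mag <- Mod(stats::mvfft(padded))[seq_len(nbins), , drop = FALSE]
  out <- log(mag + eps)
  structure(out, class = c("ecg_spectrogram", "matrix"),
            win = win, hop = hop, eps = eps)
}

#' Pad or crop a signal to a fixed length
#'
#' Shorter signals are right-padded with zeros; longer signals are
#' center-cropped.
#'
#' @param x Numeric signal.
#' @param target_len Desired output length (>= 1).
#' @return Signal of length exactly `target_len`.
#' @export
pad_or_crop <- function(x, target_len) {
  stopifnot(target_len >= 1L)
  L <- length(x)
  if (L == target_len) return(x)
  if (L < target_len) return(c(x, numeric(target_len - L)))
  start <- (L - target_len) %/% 2L + 1L
  x[start:(start + target_len - 1L)]
}

#' Detect R-peaks with the Hamilton rules
#'
#' QRS detection following the Hamilton scheme: 8-16 Hz bandpass,
#' differentiation, rectification, an 80 ms moving-average envelope, and an
#' adaptive threshold between running signal- and noise-peak estimates with a
#' 200 ms refractory period and RR-based search-back. Detections are refined
#' to the largest absolute deflection of the raw signal near the envelope
#' peak.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @return Strictly increasing integer vector of R-peak sample indices
#'   (possibly empty).
#' @export
detect_r_peaks <- function(x, fs) {
  stopifnot(fs > 0)
  L <- length(x)
  if (L < fs || all(x == 0)) return(integer(0))
  taps <- 2L * round(0.1 * fs) + 1L
  bp <- fir_bandpass(x, fs, 8, 16, numtaps = taps)
  env <- abs(c(0, diff(bp)))
  w <- max(3L, round(0.08 * fs))
  cs <- cumsum(c(0, env))
  half <- w %/% 2L
  lo <- pmax(seq_len(L) - half, 1L)
  hi <- pmin(seq_len(L) + half, L)
  env <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)

  # candidate envelope peaks (local maxima)
  is_pk <- c(FALSE, env[2:(L - 1)] >= env[1:(L - 2)] &
               env[2:(L - 1)] > env[3:L], FALSE)
  cand <- which(is_pk)
  if (length(cand) == 0L) return(integer(0))

  refract <- round(0.2 * fs)
  init <- env[seq_len(min(L, 2L * fs))]
  spk <- max(init)
  npk <- mean(init)
  th <- function() npk + 0.3125 * (spk - npk)
  qrs <- integer(0)
  rr_hist <- numeric(0)
  missed <- integer(0) # sub-threshold candidates since the last detection
  for (p in cand) {
    if (length(qrs) && p - qrs[length(qrs)] < refract) next
    if (env[p] > th()) {
      qrs <- c(qrs, p)
      spk <- 0.875 * spk + 0.125 * env[p]
      if (length(qrs) >= 2L)
        rr_hist <- tail(c(rr_hist, diff(tail(qrs, 2L))), 8L)
      missed <- integer(0)
    } else {
      npk <- 0.875 * npk + 0.125 * env[p]
      missed <- c(missed, p)
      # search-back: a long RR gap re-examines skipped candidates at half
      # threshold
      if (length(rr_hist) >= 2L && length(qrs)) {
        gap <- p - qrs[length(qrs)]
        if (gap > 1.5 * mean(rr_hist)) {
          ok <- missed[env[missed] > 0.5 * th() &
                         missed - qrs[length(qrs)] >= refract]
          if (length(ok)) {
            bb <- ok[which.max(env[ok])]
            qrs <- c(qrs, bb)
            spk <- 0.875 * spk + 0.125 * env[bb]
            rr_hist <- tail(c(rr_hist, diff(tail(qrs, 2L))), 8L)
            missed <- integer(0)
          }
        }
      }
    }
  }
  if (length(qrs) == 0L) return(integer(0))
  # refine each detection to the dominant raw deflection nearby
  halfw <- as.integer(round(0.1 * fs))
  out <- vapply(qrs, function(p) {
    a <- max(1L, as.integer(p) - halfw)
    b <- min(L, as.integer(p) + halfw)
    a + which.max(abs(x[a:b])) - 1L
  }, integer(1L))
  sort(unique(out))
}

#' Segment a signal into two-second beats around R-peaks
#'
#' Each segment spans one second before and one second after its R-peak
#' (`2 * fs` samples), zero-padded where the window crosses the record
#' boundary, so the beat sequence retains R-peak spacing information.
#'
#' @param x Numeric signal.
#' @param rpeaks Integer vector of R-peak sample indices.
#' @param fs Sampling rate (Hz); `2 * fs` must be a whole number.
#' @return A list of `beat_segment` objects (fields `values`, `r_index`).
#' @export
segment_beats <- function(x, rpeaks, fs) {
  n <- as.integer(round(fs))
  L <- length(x)
  lapply(as.integer(rpeaks), function(r) {
    idx <- (r - n):(r + n - 1L)
    vals <- numeric(2L * n)
    ok <- idx >= 1L & idx <= L
    vals[ok] <- x[idx[ok]]
    structure(list(values = vals, r_index = r), class = "beat_segment")
  })
}
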