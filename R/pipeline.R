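# Family-aware preprocessing pipeline configuration and record-to-tensor
# conversion. The dual-domain families standardize the raw signal, pad it to
# a fixed length and compute the log-spectrogram; the RCLSTM family bandpass
# filters, standardizes, detects R-peaks and segments beats, and feeds the
# padded signal to its ResNet branch.

#' Configure the preprocessing pipeline
#'
#' @param fs Nominal sampling rate (Hz) of the records.
#' @param band FIR bandpass edges in Hz (conventional diagnostic ECG band).
#' @param numtaps FIR tap count (odd).
#' @param target_len Fixed padded signal length in samples. The default of
#'   18000 (60 s at 300 Hz) covers the longest CinC 2017 recordings; shorter
#'   values are appropriate for desk-scale experiments.
#' @param win,hop,nbins,eps Log-spectrogram parameters (see
#'   [log_spectrogram()]).
#' @param frame_len Samples per step fed to the sequence (signal) encoders.
#' @param max_beats Beat-segment cap per record for the RCLSTM branch.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(fs = 300, band = c(0.5, 40), numtaps = 301L,
                              target_len = 18000L, win = 64L, hop = 32L,
                              nbins = 64L, eps = 1e-6, frame_len = 32L,
                              max_beats = 60L) {
  stopifnot(target_len >= win)
  structure(list(fs = fs, band = band, numtaps = numtaps,
                 target_len = as.integer(target_len), win = win, hop = hop,
                 nbins = nbins, eps = eps, frame_len = as.integer(frame_len),
                 max_beats = as.integer(max_beats)),
            class = "preprocess_config")
}

# Preprocess one record for a model family; augmentation (if any) must have
# been applied to the raw signal beforehand.
preprocess_record <- function(signal, fs, pp, family) {
  if (family %in% c("dualnet", "dualnet_pp")) {
    x <- pad_or_crop(standardize(signal), pp$target_len)
    list(sig = x,
         spec = log_spectrogram(x, win = pp$win, hop = pp$hop,
                                nbins = pp$nbins, eps = pp$eps))
  } else if (family == "rclstm") {
    x <- standardize(fir_bandpass(signal, fs, pp$band[1L], pp$band[2L],
                                  numtaps = min(pp$numtaps,
                                                2L * (length(signal) %/% 2L) - 1L)))
    rp <- detect_r_peaks(x, fs)
    if (length(rp) > pp$max_beats) rp <- rp[seq_len(pp$max_beats)]
    list(sig = pad_or_crop(x, pp$target_len),
         beats = segment_beats(x, rp, fs))
  } else {
    stop("unknown model family: ", family, call. = FALSE)
  }
}

# Split a batch signal matrix (N x L) into frames: a list over time steps of
# N x frame_len matrices (last frame zero-padded).
signal_frames <- function(sig, frame_len) {
  n <- nrow(sig)
  L <- ncol(sig)
  T <- ceiling(L / frame_len)
  pad <- T * frame_len - L
  if (pad > 0L) sig <- cbind(sig, matrix(0, n, pad))
  lapply(seq_len(T), function(t) {
    ad_const(sig[, (t - 1L) * frame_len + seq_len(frame_len), drop = FALSE])
  })
}

# Stack per-record preprocessed inputs into the batch tensors each family
# consumes (see nn-layers.R for the channel x (spatial * batch) layout).
make_batch <- function(pre, family, pp) {
  n <- length(pre)
  sig <- do.call(rbind, lapply(pre, function(p) p$sig))
  if (family %in% c("dualnet", "dualnet_pp")) {
    specs <- lapply(pre, function(p) as.vector(unclass(p$spec)))
    H <- nrow(pre[[1L]]$spec)
    W <- ncol(pre[[1L]]$spec)
    list(n = n,
         frames = signal_frames(sig, pp$frame_len),
         spec = ad_const(matrix(unlist(specs), nrow = 1L)),
         H = H, W = W)
  } else {
    beats <- lapply(pre, function(p) p$beats)
    counts <- lengths(beats)
    beat_len <- if (any(counts > 0L))
      length(beats[[which(counts > 0L)[1L]]][[1L]]$values) else 2L * pp$fs
    flat <- unlist(lapply(beats, function(bs)
      lapply(bs, function(b) b$values)), recursive = FALSE)
    beat_mat <- if (length(flat))
      matrix(unlist(flat), nrow = 1L) else matrix(0, 1L, 0L)
    list(n = n,
         sig = ad_const(matrix(as.vector(t(sig)), nrow = 1L)),
         L = ncol(sig),
         beats = ad_const(beat_mat), beat_len = beat_len,
         beat_counts = counts)
  }
}
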