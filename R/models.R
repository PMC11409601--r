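# Model configuration, construction, the beat-interval baseline, and the
# uniform prediction interface.

# Default per-size architecture tables. Widths/depths are package defaults
# (overridable through model_config(...)); parameter counts increase strictly
# along S < M < L < XL within each family. The DualNet++ "130M" tier is named
# after the original full-scale variant of roughly 130 million parameters;
# the default widths here keep the strict size ordering at desk scale.
.dualnet_sizes <- list(
  S = list(chans = c(32, 64, 128, 256, 256), latent = 128, lstm_layers = 1L),
  M = list(chans = c(48, 96, 192, 384, 384), latent = 192, lstm_layers = 1L),
  L = list(chans = c(64, 128, 256, 512, 512), latent = 256, lstm_layers = 2L),
  XL = list(chans = c(96, 192, 384, 768, 768), latent = 384, lstm_layers = 2L))

.dualnet_pp_sizes <- list(
  S = list(d_model = 64, heads = 4L, enc_layers = 1L, res_ch = c(32, 64), latent = 128),
  M = list(d_model = 96, heads = 4L, enc_layers = 1L, res_ch = c(48, 96), latent = 192),
  L = list(d_model = 128, heads = 4L, enc_layers = 2L, res_ch = c(64, 128), latent = 256),
  XL = list(d_model = 192, heads = 8L, enc_layers = 2L, res_ch = c(96, 192), latent = 384),
  `130M` = list(d_model = 256, heads = 8L, enc_layers = 3L, res_ch = c(128, 256), latent = 512))

.rclstm_sizes <- list(
  S = list(res_ch = c(24, 48, 96, 96), beat_ch = 8L, lstm_hidden = 32L),
  M = list(res_ch = c(32, 64, 128, 128), beat_ch = 12L, lstm_hidden = 48L),
  L = list(res_ch = c(48, 96, 192, 192), beat_ch = 16L, lstm_hidden = 64L),
  XL = list(res_ch = c(64, 128, 256, 256), beat_ch = 24L, lstm_hidden = 96L))

#' Configure a classifier architecture
#'
#' @param family One of `"dualnet"` (LSTM signal encoder + five CBN-ResNet
#'   spectrogram blocks), `"dualnet_pp"` (Transformer signal encoder + two
#'   CBN-ResNet and three axial-attention spectrogram blocks), `"rclstm"`
#'   (1-D ResNet over the whole signal + CNN-LSTM over beat segments), or
#'   `"baseline"` (beat-interval threshold classifier).
#' @param size Size tier: `"S"`, `"M"`, `"L"`, `"XL"` (plus `"130M"` for
#'   `dualnet_pp`). Ignored by the baseline.
#' @param n_classes 2 (NSR/AFib) or 4 (all rhythm classes).
#' @param threshold Baseline decision threshold on the RR-interval standard
#'   deviation, in seconds.
#' @param ... Named overrides of the per-size defaults (e.g. `chans`,
#'   `latent`, `d_model`, `res_ch`, `beat_ch`, `lstm_hidden`).
#' @return A `model_config` list.
#' @export
model_config <- function(family = c("dualnet", "dualnet_pp", "rclstm", "baseline"),
                         size = "S", n_classes = 4L, threshold = 0.1, ...) {
  family <- match.arg(family)
  stopifnot(n_classes %in% c(2L, 4L))
  sizes <- switch(family,
                  dualnet = .dualnet_sizes,
                  dualnet_pp = .dualnet_pp_sizes,
                  rclstm = .rclstm_sizes,
                  baseline = NULL)
  arch <- list()
  if (!is.null(sizes)) {
    if (!size %in% names(sizes))
      stop("unknown size ", size, " for family ", family, call. = FALSE)
    arch <- sizes[[size]]
  }
  overrides <- list(...)
  arch[names(overrides)] <- overrides
  structure(c(list(family = family, size = size,
                   n_classes = as.integer(n_classes), threshold = threshold),
              arch),
            class = "model_config")
}

#' Build a model from its configuration
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `afib_model` object with a family-specific forward pass behind
#'   the uniform [predict_dataset()] interface.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  switch(config$family,
         dualnet = build_dualnet(config),
         dualnet_pp = build_dualnet_pp(config),
         rclstm = build_rclstm(config),
         baseline = structure(list(family = "baseline", size = config$size,
                                   n_classes = 2L, config = config,
                                   threshold = config$threshold),
                              class = c("afib_baseline", "afib_model")))
}

#' Count trainable parameters
#'
#' @param model An `afib_model`.
#' @param prefix Optional parameter-name prefix restricting the count to one
#'   component (e.g. `"resnet."` or `"clstm."` for the RCLSTM branches).
#' @return Number of trainable scalar parameters.
#' @export
count_parameters <- function(model, prefix = NULL) {
  if (inherits(model, "afib_baseline")) return(0)
  nn_param_count(model$ctx, prefix)
}

#' @export
print.afib_model <- function(x, ...) {
  cat(sprintf("<afib_model %s-%s: %d classes, %s parameters>\n",
              x$family, x$size, x$n_classes,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

model_classes <- function(model) {
  if (model$n_classes == 2L) afib_classes()[1:2] else afib_classes()
}

#' Beat-interval baseline classifier
#'
#' Detects R-peaks, computes the standard deviation of successive
#' beat-to-beat intervals, and labels the record AFib when that standard
#' deviation exceeds the threshold, exploiting the irregular beat-to-beat
#' intervals characteristic of atrial fibrillation. Records with fewer than
#' three detected peaks are labeled NSR (documented degenerate rule).
#'
#' @param record An [ecg_record()].
#' @param threshold Decision threshold in seconds.
#' @return A one-row tibble with `record_id`, one-hot class probabilities and
#'   the predicted `label`.
#' @export
baseline_bbi <- function(record, threshold = 0.1) {
  stopifnot(inherits(record, "ecg_record"))
  rp <- detect_r_peaks(record$signal, record$fs)
  lab <- if (length(rp) < 3L) "NSR" else {
    rr <- diff(rp) / record$fs
    if (stats::sd(rr) > threshold) "AFib" else "NSR"
  }
  tibble::tibble(record_id = record$record_id,
                 p_NSR = as.numeric(lab == "NSR"),
                 p_AFib = as.numeric(lab == "AFib"),
                 label = label_factor(lab))
}

#' Predict labels for a set of records
#'
#' Runs the model in inference mode (augmentation disabled, normalization on
#' running statistics) and returns one prediction per record, in input order,
#' deterministically. Softmax ties break toward the lowest class index
#' (NSR before AFib before Other before Noisy).
#'
#' @param model An `afib_model`.
#' @param records List of [ecg_record()] objects.
#' @param pp A [preprocess_config()].
#' @param batch_size Records per forward pass.
#' @return A tibble with `record_id`, per-class probability columns
#'   (`p_<class>`) and the argmax `label`.
#' @export
predict_dataset <- function(model, records, pp = preprocess_config(),
                            batch_size = 16L) {
  UseMethod("predict_dataset")
}

#' @export
predict_dataset.afib_baseline <- function(model, records,
                                          pp = preprocess_config(),
                                          batch_size = 16L) {
  do.call(rbind, lapply(records, baseline_bbi, threshold = model$threshold))
}

#' @export
predict_dataset.afib_nn <- function(model, records, pp = preprocess_config(),
                                    batch_size = 16L) {
  classes <- model_classes(model)
  out <- vector("list", length(records))
  idx <- split(seq_along(records),
               ceiling(seq_along(records) / batch_size))
  for (batch_ids in idx) {
    pre <- lapply(records[batch_ids], function(r)
      preprocess_record(r$signal, r$fs, pp, model$family))
    batch <- make_batch(pre, model$family, pp)
    logits <- model$forward(batch, train = FALSE)
    probs <- ad_softmax_rows(logits)$value
    for (k in seq_along(batch_ids)) {
      i <- batch_ids[k]
      p <- probs[k, ]
      row <- c(list(record_id = records[[i]]$record_id),
               stats::setNames(as.list(p), paste0("p_", classes)),
               list(label = label_factor(classes[which.max(p)])))
      out[[i]] <- tibble::as_tibble(row)
    }
  }
  do.call(rbind, out)
}
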