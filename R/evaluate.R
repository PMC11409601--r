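# Challenge scoring: the binary F1 with AFib positive, the four-class macro
# F1, the CinC 2017 challenge score (mean of the NSR, AFib and Other
# one-vs-rest F1 terms), supporting metrics (accuracy, one-vs-rest macro
# AUROC/AUPRC), the binary relabeling conventions, and a local
# submission-scoring store with the 5-run quota.

align_labels <- function(pred, ref) {
  # Both tibbles (record_id, label). Every prediction id must exist in the
  # reference; reference records without a prediction are scored as NSR.
  stopifnot(all(c("record_id", "label") %in% names(ref)))
  stopifnot(all(c("record_id", "label") %in% names(pred)))
  extra <- setdiff(pred$record_id, ref$record_id)
  if (length(extra))
    stop("predictions for unknown record ids: ",
         paste(head(extra, 5L), collapse = ", "), call. = FALSE)
  m <- match(ref$record_id, pred$record_id)
  p <- as.character(pred$label)[m]
  p[is.na(p)] <- "NSR"
  tibble::tibble(record_id = ref$record_id,
                 ref = label_factor(as.character(ref$label)),
                 pred = label_factor(p))
}

as_label_tbl <- function(x) {
  if (is.data.frame(x)) x
  else tibble::tibble(record_id = seq_along(x), label = as.character(x))
}

#' Reduce four-class labels to the binary NSR/AFib scoring task
#'
#' Applies the binary-score conventions: records whose ground truth is Other
#' or Noisy are dropped; predicted Other/Noisy labels are relabeled NSR;
#' reference records without a prediction are scored as NSR.
#'
#' @param pred,ref Tibbles with columns `record_id` and `label`. A prediction
#'   id absent from the reference is an error.
#' @return A tibble with columns `record_id`, `ref`, `pred` restricted to
#'   NSR/AFib ground truth.
#' @export
relabel_for_binary <- function(pred, ref) {
  pairs <- align_labels(as_label_tbl(pred), as_label_tbl(ref))
  pairs <- pairs[pairs$ref %in% c("NSR", "AFib"), , drop = FALSE]
  p <- as.character(pairs$pred)
  p[p %in% c("Other", "Noisy")] <- "NSR"
  pairs$pred <- label_factor(p)
  pairs
}

#' Confusion matrix over the rhythm classes
#'
#' @param pred,ref Label vectors (or factors) of equal length.
#' @param classes Class order; defaults to the four rhythm classes.
#' @return A `C x C` integer matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(pred, ref, classes = afib_classes()) {
  stopifnot(length(pred) == length(ref))
  table(factor(as.character(ref), levels = classes),
        factor(as.character(pred), levels = classes),
        dnn = c("truth", "prediction"))
}

# One-vs-rest F1 for class i of a confusion matrix; 0/0 (class absent from
# both truth and prediction) is defined as 1.
f1_from_cm <- function(cm, i) {
  tp <- cm[i, i]
  fp <- sum(cm[-i, i])
  fn <- sum(cm[i, -i])
  den <- tp + 0.5 * (fp + fn)
  if (den == 0) 1 else tp / den
}

#' Binary F1 with AFib as the positive class
#'
#' `F1 = TP / (TP + (FP + FN) / 2)` where TP counts records correctly
#' labeled AFib. The degenerate case TP = FP = FN = 0 scores 1.
#'
#' @param pairs Output of [relabel_for_binary()] (columns `ref`, `pred`).
#' @return F1 score in `[0, 1]`.
#' @export
f1_binary <- function(pairs) {
  cm <- confusion_matrix(pairs$pred, pairs$ref, classes = c("NSR", "AFib"))
  f1_from_cm(cm, 2L)
}

four_class_pairs <- function(pred, ref) {
  if (is.data.frame(pred) || is.data.frame(ref)) {
    align_labels(as_label_tbl(pred), as_label_tbl(ref))
  } else {
    stopifnot(length(pred) == length(ref))
    tibble::tibble(ref = label_factor(as.character(ref)),
                   pred = label_factor(as.character(pred)))
  }
}

#' Four-class macro F1
#'
#' Unweighted mean of the four one-vs-rest F1 terms. Accepts either aligned
#' label vectors or `(record_id, label)` tibbles (missing predictions score
#' as NSR).
#'
#' @param pred,ref Predicted and reference labels.
#' @return Macro F1 in `[0, 1]`.
#' @export
f1_macro <- function(pred, ref) {
  pairs <- four_class_pairs(pred, ref)
  cm <- confusion_matrix(pairs$pred, pairs$ref)
  mean(vapply(1:4, function(i) f1_from_cm(cm, i), numeric(1L)))
}

#' CinC 2017 challenge score
#'
#' Mean of the NSR, AFib and Other one-vs-rest F1 terms; the Noisy class
#' participates in the confusion matrix but not in the average.
#'
#' @inheritParams f1_macro
#' @return Challenge score in `[0, 1]`.
#' @export
f1_cinc <- function(pred, ref) {
  pairs <- four_class_pairs(pred, ref)
  cm <- confusion_matrix(pairs$pred, pairs$ref)
  mean(vapply(1:3, function(i) f1_from_cm(cm, i), numeric(1L)))
}

# Rank-based (Mann-Whitney) AUROC for one positive class.
auc_roc <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision (step-wise integral of the precision-recall curve).
auc_pr <- function(score, positive) {
  n1 <- sum(positive)
  if (n1 == 0L || all(positive)) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  pos <- positive[ord]
  tp <- cumsum(pos)
  prec <- tp / seq_along(pos)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

ovr_macro <- function(probs, truth, fun) {
  classes <- colnames(probs)
  vals <- vapply(classes, function(cl)
    fun(probs[, cl], as.character(truth) == cl), numeric(1L))
  mean(vals, na.rm = TRUE)
}

#' Score a prediction file against a reference file
#'
#' Computes the full score report: binary F1 under the relabeling
#' conventions, macro F1, the CinC challenge score, per-class F1, four-class
#' accuracy (missing predictions scored as NSR), both confusion matrices,
#' and — when a probability file is supplied — one-vs-rest macro AUROC and
#' AUPRC over the four classes.
#'
#' @param pred_file Two-column prediction CSV (`record_id,symbol`).
#' @param ref_file Reference CSV in the same format.
#' @param probs_file Optional CSV with header `record_id,NSR,AFib,Other,Noisy`
#'   giving per-class probabilities.
#' @return An `afib_score` object; see [glance.afib_score()].
#' @export
score_submission <- function(pred_file, ref_file, probs_file = NULL) {
  pred <- read_labels(pred_file)
  ref <- read_labels(ref_file)
  pairs2 <- relabel_for_binary(pred, ref)
  pairs4 <- align_labels(pred, ref)
  cm4 <- confusion_matrix(pairs4$pred, pairs4$ref)
  per_class <- vapply(1:4, function(i) f1_from_cm(cm4, i), numeric(1L))
  names(per_class) <- afib_classes()
  out <- list(
    f1_binary = f1_binary(pairs2),
    f1_macro = mean(per_class),
    f1_cinc = mean(per_class[1:3]),
    per_class_f1 = per_class,
    accuracy = mean(as.character(pairs4$pred) == as.character(pairs4$ref)),
    confusion_binary = confusion_matrix(pairs2$pred, pairs2$ref,
                                        classes = c("NSR", "AFib")),
    confusion_4class = cm4,
    n_scored = nrow(pairs4),
    auroc = NA_real_, auprc = NA_real_)
  if (!is.null(probs_file)) {
    pr <- utils::read.csv(probs_file, check.names = FALSE)
    cls <- intersect(afib_classes(), names(pr))
    if (!("record_id" %in% names(pr)) || length(cls) < 2L)
      stop("probability file needs a record_id column and at least two of ",
           paste(afib_classes(), collapse = "/"), call. = FALSE)
    m <- match(pairs4$record_id, pr$record_id)
    probs <- as.matrix(pr[m, cls])
    keep <- stats::complete.cases(probs)
    out$auroc <- ovr_macro(probs[keep, , drop = FALSE], pairs4$ref[keep], auc_roc)
    out$auprc <- ovr_macro(probs[keep, , drop = FALSE], pairs4$ref[keep], auc_pr)
  }
  structure(out, class = "afib_score")
}

#' @export
print.afib_score <- function(x, ...) {
  cat(sprintf("ECG scoring report (%d records)\n", x$n_scored))
  cat(sprintf("  F1 (binary, AFib+): %.4f\n", x$f1_binary))
  cat(sprintf("  F1 macro:           %.4f\n", x$f1_macro))
  cat(sprintf("  F1 CinC:            %.4f\n", x$f1_cinc))
  cat(sprintf("  Accuracy:           %.4f\n", x$accuracy))
  if (!is.na(x$auroc))
    cat(sprintf("  AUROC/AUPRC macro:  %.4f / %.4f\n", x$auroc, x$auprc))
  invisible(x)
}

#' One-row summary of a score report
#'
#' @param x An `afib_score` from [score_submission()].
#' @param ... Unused.
#' @return A one-row tibble of the headline metrics.
#' @export
glance.afib_score <- function(x, ...) {
  tibble::tibble(f1_binary = x$f1_binary, f1_macro = x$f1_macro,
                 f1_cinc = x$f1_cinc, accuracy = x$accuracy,
                 auroc = x$auroc, auprc = x$auprc, n_scored = x$n_scored)
}

#' @export
glance <- function(x, ...) UseMethod("glance")

## ---- submission store -------------------------------------------------------

read_store <- function(path) {
  if (file.exists(path)) jsonlite::read_json(path, simplifyVector = FALSE)
  else list(runs = list())
}

#' Record a scored run in the local submission store
#'
#' Persists the run (team, model name, scores, confusion matrix, metadata,
#' timestamp) in a single-file JSON store and returns the updated ranking.
#' Each team is allowed 5 successful runs; further submissions are rejected
#' unless `force = TRUE`.
#'
#' @param store Path to the store file (created on first use).
#' @param team Team identifier.
#' @param model_name Model name shown in the ranking.
#' @param report An `afib_score` from [score_submission()].
#' @param metadata Optional named list stored alongside the run.
#' @param force Override the submission quota.
#' @return The updated [leaderboard()] tibble, invisibly.
#' @export
record_run <- function(store, team, model_name, report, metadata = list(),
                       force = FALSE) {
  stopifnot(inherits(report, "afib_score"))
  db <- read_store(store)
  n_team <- sum(vapply(db$runs, function(r) identical(r$team, team), logical(1L)))
  if (n_team >= 5L && !force)
    stop("submission quota reached: team '", team,
         "' already has 5 successful runs", call. = FALSE)
  db$runs[[length(db$runs) + 1L]] <- list(
    team = team, model_name = model_name,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    f1_binary = report$f1_binary, f1_macro = report$f1_macro,
    f1_cinc = report$f1_cinc, accuracy = report$accuracy,
    confusion_4class = as.vector(report$confusion_4class),
    metadata = metadata)
  jsonlite::write_json(db, store, auto_unbox = TRUE, digits = NA)
  invisible(leaderboard(store))
}

#' Current ranking from the submission store
#'
#' @param store Path to the store file.
#' @param by Score used for ranking (default the binary F1, the final-ranking
#'   convention).
#' @return A tibble sorted by the chosen score, best first.
#' @export
leaderboard <- function(store, by = "f1_binary") {
  db <- read_store(store)
  if (!length(db$runs)) {
    return(tibble::tibble(pos = integer(), team = character(),
                          model_name = character(), f1_binary = numeric(),
                          f1_macro = numeric(), f1_cinc = numeric(),
                          timestamp = character()))
  }
  tb <- do.call(rbind, lapply(db$runs, function(r)
    tibble::tibble(team = r$team, model_name = r$model_name,
                   f1_binary = r$f1_binary, f1_macro = r$f1_macro,
                   f1_cinc = r$f1_cinc, timestamp = r$timestamp)))
  tb <- tb[order(-tb[[by]]), , drop = FALSE]
  tibble::tibble(pos = seq_len(nrow(tb)), tb)
}
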