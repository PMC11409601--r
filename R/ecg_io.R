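# Record and label file I/O in the PhysioNet/CinC 2017 storage dialect:
# a MATLAB v4 .mat file holding one int16 sample vector, a sibling WFDB .hea
# header carrying sampling rate and gain, and header-less two-column CSV
# label/prediction files.

#' Construct a single-lead ECG record
#'
#' @param record_id Record identifier (used as the filename stem on disk).
#' @param signal Numeric sample vector in physical units (mV).
#' @param fs Sampling rate in Hz.
#' @param label Optional rhythm class, one of [afib_classes()], or `NULL`
#'   for an unlabeled record.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, signal, fs = 300, label = NULL) {
  signal <- as.numeric(signal)
  if (length(signal) < 1L) stop("signal must have length >= 1", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (!is.null(label)) {
    label <- as.character(label)
    if (!label %in% afib_classes())
      stop("label must be one of ", paste(afib_classes(), collapse = ", "), call. = FALSE)
  }
  structure(list(record_id = as.character(record_id), signal = signal,
                 fs = as.numeric(fs), label = label),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d samples @ %g Hz (%.1f s)%s>\n",
              x$record_id, length(x$signal), x$fs, length(x$signal) / x$fs,
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

# MATLAB v4 numeric type codes (the P digit of the MOPT header).
.mat4_precisions <- c("0" = 8L, "2" = 4L, "3" = 2L, "4" = 2L, "5" = 1L)

#' Read an ECG record from disk
#'
#' Reads a MATLAB v4 `.mat` file containing a single sample vector. If a
#' sibling WFDB `.hea` header exists, the sampling rate and ADC gain are taken
#' from it; otherwise the CinC 2017 conventions (300 Hz, gain 1000 per mV)
#' apply. Raw integer samples are converted to millivolts by dividing by the
#' gain. The record id is the filename stem.
#'
#' @param path Path to the `.mat` file (the extension may be omitted).
#' @return An [ecg_record()] (unlabeled).
#' @export
read_record <- function(path) {
  if (!grepl("\\.mat$", path)) path <- paste0(path, ".mat")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  record_id <- sub("\\.mat$", "", basename(path))
  hea <- sub("\\.mat$", ".hea", path)
  fs <- 300
  gain <- 1000
  if (file.exists(hea)) {
    meta <- read_hea(hea)
    fs <- meta$fs
    gain <- meta$gain
  }
  raw <- read_mat4_vector(path)
  if (length(raw) < 1L) stop("empty signal in ", path, call. = FALSE)
  ecg_record(record_id, raw / gain, fs = fs)
}

read_mat4_vector <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "integer", n = 5L, size = 4L, endian = "little")
  if (length(hdr) < 5L) stop("corrupt MAT header in ", path, call. = FALSE)
  type <- hdr[1L]
  endian <- if (type %/% 1000L == 0L) "little" else "big"
  if (endian == "big") {
    # header was read little-endian; re-read it big-endian
    seek(con, 0L)
    hdr <- readBin(con, "integer", n = 5L, size = 4L, endian = "big")
    type <- hdr[1L]
  }
  p <- (type %/% 10L) %% 10L
  size <- .mat4_precisions[as.character(p)]
  if (is.na(size)) stop("unsupported MAT v4 precision code ", p, call. = FALSE)
  mrows <- hdr[2L]; ncols <- hdr[3L]; imagf <- hdr[4L]; namelen <- hdr[5L]
  if (mrows < 0L || ncols < 0L || namelen <= 0L || namelen > 256L)
    stop("corrupt MAT header in ", path, call. = FALSE)
  readBin(con, "raw", n = namelen) # variable name (ignored)
  n <- mrows * ncols
  what <- if (p == 0L) "numeric" else "integer"
  x <- readBin(con, what, n = n, size = size, endian = endian,
               signed = !(p %in% c(4L, 5L)))
  if (length(x) != n) stop("truncated MAT data in ", path, call. = FALSE)
  if (imagf != 0L) readBin(con, what, n = n, size = size, endian = endian)
  as.numeric(x)
}

read_hea <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) < 1L) stop("empty header file: ", path, call. = FALSE)
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  fs <- if (length(top) >= 3L) suppressWarnings(as.numeric(top[3L])) else NA_real_
  if (is.na(fs) || fs <= 0) fs <- 300
  gain <- 1000
  if (length(lines) >= 2L) {
    sig <- strsplit(trimws(lines[2L]), "\\s+")[[1L]]
    if (length(sig) >= 3L) {
      g <- suppressWarnings(as.numeric(sub("/.*$", "", sig[3L])))
      if (!is.na(g) && g > 0) gain <- g
    }
  }
  list(fs = fs, gain = gain)
}

#' Write an ECG record to disk
#'
#' Writes the MATLAB v4 `.mat` / WFDB `.hea` pair read back by
#' [read_record()]. Samples are quantized to int16 at the given gain.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory (created if needed).
#' @param gain ADC gain in units per millivolt.
#' @return Invisibly, a character vector with the `.mat` and `.hea` paths.
#' @export
write_record <- function(record, dir, gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  raw <- as.integer(round(record$signal * gain))
  if (any(abs(raw) > 32767L))
    stop("signal exceeds int16 range at gain ", gain, call. = FALSE)
  mat <- file.path(dir, paste0(record$record_id, ".mat"))
  hea <- file.path(dir, paste0(record$record_id, ".hea"))
  con <- file(mat, "wb")
  writeBin(as.integer(c(30L, 1L, length(raw), 0L, 4L)), con, size = 4L,
           endian = "little")
  writeBin(c(charToRaw("val"), as.raw(0L)), con)
  writeBin(raw, con, size = 2L, endian = "little")
  close(con)
  writeLines(c(sprintf("%s 1 %g %d", record$record_id, record$fs, length(raw)),
               sprintf("%s.mat 16+24 %g/mV 16 0 0 0 0 ECG",
                       record$record_id, gain)),
             hea)
  invisible(c(mat = mat, hea = hea))
}

#' Read a reference label file
#'
#' Parses a header-less two-column CSV (`record_id,symbol`) with symbols in
#' `N/A/O/~`. Order is preserved; duplicated record ids or unknown symbols
#' raise an error naming the offending rows.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `record_id` and `label` (factor over
#'   [afib_classes()]).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ",")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed label rows: ", paste(bad, collapse = ", "), call. = FALSE)
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  syms <- trimws(vapply(parts, `[[`, "", 2L))
  unknown <- which(!syms %in% afib_symbols())
  if (length(unknown))
    stop("unknown label symbols on rows ", paste(unknown, collapse = ", "),
         ": ", paste(unique(syms[unknown]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicated record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  tibble::tibble(record_id = ids, label = label_factor(symbol_to_class(syms)))
}

#' Write a prediction (or reference) label file
#'
#' @param entries A data frame with columns `record_id` and `label` (class
#'   names or symbols).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(entries, path) {
  stopifnot(all(c("record_id", "label") %in% names(entries)))
  lab <- as.character(entries$label)
  sym <- ifelse(lab %in% afib_symbols(), lab, class_to_symbol(lab))
  con <- file(path, "wb") # LF endings on every platform
  writeLines(paste0(entries$record_id, ",", sym), con, sep = "\n")
  close(con)
  invisible(path)
}

#' Read a directory of records with its reference file
#'
#' @param dir Directory containing `.mat`/`.hea` pairs and `REFERENCE.csv`.
#' @return A list of labeled [ecg_record()] objects, in reference-file order.
#' @export
read_dataset <- function(dir) {
  ref <- read_labels(file.path(dir, "REFERENCE.csv"))
  lapply(seq_len(nrow(ref)), function(i) {
    r <- read_record(file.path(dir, ref$record_id[i]))
    r$label <- as.character(ref$label[i])
    r
  })
}
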