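# Shared fixtures, generated in code and cached across test files.

.fx <- new.env(parent = emptyenv())

# Labeled synthetic records, cached by composition/seed/duration.
fixture_records <- function(n_per_class, seed = 1L, duration_s = 10) {
  key <- paste(paste(names(n_per_class), n_per_class, collapse = "_"),
               seed, duration_s, sep = "|")
  if (is.null(.fx[[key]]))
    .fx[[key]] <- generate_records(n_per_class, seed = seed,
                                   duration_s = duration_s)
  .fx[[key]]
}

# A clean (noise-free, regular) record with known R-peak truth.
fixture_clean_record <- function(cls = "NSR", rr = 1.0, duration_s = 30,
                                 rr_cv = 0, noise = 0, seed = 42L) {
  spec <- rhythm_spec(cls, duration_s = duration_s, rr_mean_s = rr,
                      rr_cv = rr_cv, noise_sigma = noise, seed = seed)
  synthesize_ecg(generate_rr_series(spec), spec)
}

# Independent brute-force per-class TP/FP/FN counter (plain loops; no shared
# code with the package's confusion-matrix path).
brute_counts <- function(pred, ref, classes) {
  out <- matrix(0L, nrow = length(classes), ncol = 3L,
                dimnames = list(classes, c("tp", "fp", "fn")))
  for (k in seq_along(classes)) {
    cl <- classes[k]
    for (i in seq_along(ref)) {
      if (ref[i] == cl && pred[i] == cl) out[k, "tp"] <- out[k, "tp"] + 1L
      if (ref[i] != cl && pred[i] == cl) out[k, "fp"] <- out[k, "fp"] + 1L
      if (ref[i] == cl && pred[i] != cl) out[k, "fn"] <- out[k, "fn"] + 1L
    }
  }
  out
}

brute_f1 <- function(tp, fp, fn) {
  den <- tp + 0.5 * (fp + fn)
  if (den == 0) 1 else tp / den
}

# Finite-difference gradient check against the engine's backward pass.
grad_check <- function(build_loss, params, eps = 1e-6, tol = 1e-5) {
  afibnet:::ad_tape_begin()
  loss <- build_loss()
  afibnet:::ad_backward(loss)
  afibnet:::ad_tape_end()
  errs <- vapply(names(params), function(nm) {
    p <- params[[nm]]
    g <- p$grad
    num <- array(0, dim(p$value))
    for (i in seq_along(p$value)) {
      v0 <- p$value[i]
      p$value[i] <- v0 + eps
      lp <- build_loss()$value[1L, 1L]
      p$value[i] <- v0 - eps
      lm <- build_loss()$value[1L, 1L]
      p$value[i] <- v0
      num[i] <- (lp - lm) / (2 * eps)
    }
    p$grad <- NULL
    max(abs(num - g)) / max(1, max(abs(num)))
  }, numeric(1L))
  errs
}
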