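# Reverse-mode automatic differentiation on dense matrices.
#
# The engine is deliberately small: a global tape records operation nodes in
# creation order; ad_backward() walks the tape in reverse and each node's
# adjoint closure accumulates gradients into its parents. Values are plain
# numeric matrices; convolutions are expressed as gather (im2col) + GEMM so
# that all heavy lifting goes through BLAS and the two compiled kernels.
#
# Nodes are environments so gradient accumulation can mutate in place.
# Parameters (ad_param) live outside the tape and persist across batches;
# their $grad fields are zeroed by the optimizer.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_tape_begin <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 512L)
  t$n <- 0L
  .ad$tape <- t
  invisible(t)
}

ad_tape_end <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

# Run fn() with a fresh tape, guaranteeing tape teardown.
ad_with_tape <- function(fn) {
  ad_tape_begin()
  on.exit(ad_tape_end(), add = TRUE)
  fn()
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

ad_node <- function(value, rg = FALSE, bwd = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$rg <- rg
  nd$bwd <- bwd
  nd
}

ad_is_node <- function(x) is.environment(x) && !is.null(x$value)

ad_const <- function(x) ad_node(as_mat(x), rg = FALSE)

ad_param <- function(x) ad_node(as_mat(x), rg = TRUE)

ad_wrap <- function(x) if (ad_is_node(x)) x else ad_const(x)

# Record an op node on the active tape (only if something upstream needs grads).
ad_record <- function(nd) {
  t <- .ad$tape
  if (!is.null(t) && nd$rg) {
    n <- t$n + 1L
    if (n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
    t$nodes[[n]] <- nd
    t$n <- n
  }
  nd
}

acc_grad <- function(nd, g) {
  if (nd$rg) nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

#' @keywords internal
ad_backward <- function(loss) {
  t <- .ad$tape
  if (is.null(t)) stop("ad_backward() requires an active tape", call. = FALSE)
  loss$grad <- matrix(1, nrow(loss$value), ncol(loss$value))
  if (t$n > 0L) {
    for (i in seq.int(t$n, 1L)) {
      nd <- t$nodes[[i]]
      if (!is.null(nd$grad) && !is.null(nd$bwd)) nd$bwd(nd$grad)
    }
  }
  invisible(NULL)
}

## ---- primitive operations ---------------------------------------------------

ad_matmul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  nd <- ad_node(a$value %*% b$value, rg = a$rg || b$rg)
  nd$bwd <- function(g) {
    acc_grad(a, g %*% t(b$value))
    acc_grad(b, crossprod(a$value, g))
  }
  ad_record(nd)
}

ad_add <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  nd <- ad_node(a$value + b$value, rg = a$rg || b$rg)
  nd$bwd <- function(g) { acc_grad(a, g); acc_grad(b, g) }
  ad_record(nd)
}

ad_sub <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  nd <- ad_node(a$value - b$value, rg = a$rg || b$rg)
  nd$bwd <- function(g) { acc_grad(a, g); acc_grad(b, -g) }
  ad_record(nd)
}

ad_mul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  nd <- ad_node(a$value * b$value, rg = a$rg || b$rg)
  nd$bwd <- function(g) { acc_grad(a, g * b$value); acc_grad(b, g * a$value) }
  ad_record(nd)
}

ad_scale <- function(a, s) {
  a <- ad_wrap(a)
  nd <- ad_node(a$value * s, rg = a$rg)
  nd$bwd <- function(g) acc_grad(a, g * s)
  ad_record(nd)
}

# b is a 1 x d row vector broadcast over the rows of a (n x d).
ad_add_rowvec <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  nd <- ad_node(sweep(a$value, 2L, as.vector(b$value), "+"), rg = a$rg || b$rg)
  nd$bwd <- function(g) {
    acc_grad(a, g)
    acc_grad(b, matrix(colSums(g), nrow = 1L))
  }
  ad_record(nd)
}

ad_mul_rowvec <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  nd <- ad_node(sweep(a$value, 2L, as.vector(b$value), "*"), rg = a$rg || b$rg)
  nd$bwd <- function(g) {
    acc_grad(a, sweep(g, 2L, as.vector(b$value), "*"))
    acc_grad(b, matrix(colSums(g * a$value), nrow = 1L))
  }
  ad_record(nd)
}

# b is an r x 1 column vector broadcast over the columns of a (r x c).
ad_add_colvec <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  nd <- ad_node(a$value + as.vector(b$value), rg = a$rg || b$rg)
  nd$bwd <- function(g) {
    acc_grad(a, g)
    acc_grad(b, matrix(rowSums(g), ncol = 1L))
  }
  ad_record(nd)
}

ad_mul_colvec <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  nd <- ad_node(a$value * as.vector(b$value), rg = a$rg || b$rg)
  nd$bwd <- function(g) {
    acc_grad(a, g * as.vector(b$value))
    acc_grad(b, matrix(rowSums(g * a$value), ncol = 1L))
  }
  ad_record(nd)
}

ad_tanh <- function(a) {
  a <- ad_wrap(a)
  v <- tanh(a$value)
  nd <- ad_node(v, rg = a$rg)
  nd$bwd <- function(g) acc_grad(a, g * (1 - v * v))
  ad_record(nd)
}

ad_sigmoid <- function(a) {
  a <- ad_wrap(a)
  v <- 1 / (1 + exp(-a$value))
  nd <- ad_node(v, rg = a$rg)
  nd$bwd <- function(g) acc_grad(a, g * v * (1 - v))
  ad_record(nd)
}

ad_relu <- function(a) {
  a <- ad_wrap(a)
  v <- relu_forward(a$value)
  nd <- ad_node(v, rg = a$rg)
  nd$bwd <- function(g) acc_grad(a, relu_backward(v, g))
  ad_record(nd)
}

ad_t <- function(a) {
  a <- ad_wrap(a)
  nd <- ad_node(t(a$value), rg = a$rg)
  nd$bwd <- function(g) acc_grad(a, t(g))
  ad_record(nd)
}

# Row-wise softmax.
ad_softmax_rows <- function(a) {
  a <- ad_wrap(a)
  m <- apply(a$value, 1L, max)
  e <- exp(a$value - m)
  p <- e / rowSums(e)
  nd <- ad_node(p, rg = a$rg)
  nd$bwd <- function(g) {
    acc_grad(a, p * (g - rowSums(g * p)))
  }
  ad_record(nd)
}

# Column slice; idx must not contain duplicates (all internal uses comply).
ad_slice_cols <- function(a, idx) {
  a <- ad_wrap(a)
  nd <- ad_node(a$value[, idx, drop = FALSE], rg = a$rg)
  dims <- dim(a$value)
  nd$bwd <- function(g) {
    gi <- matrix(0, dims[1L], dims[2L])
    gi[, idx] <- g
    acc_grad(a, gi)
  }
  ad_record(nd)
}

ad_slice_rows <- function(a, idx) {
  a <- ad_wrap(a)
  nd <- ad_node(a$value[idx, , drop = FALSE], rg = a$rg)
  dims <- dim(a$value)
  nd$bwd <- function(g) {
    gi <- matrix(0, dims[1L], dims[2L])
    gi[idx, ] <- g
    acc_grad(a, gi)
  }
  ad_record(nd)
}

ad_cbind <- function(parts) {
  parts <- lapply(parts, ad_wrap)
  nd <- ad_node(do.call(cbind, lapply(parts, function(p) p$value)),
                rg = any(vapply(parts, function(p) p$rg, logical(1L))))
  widths <- vapply(parts, function(p) ncol(p$value), integer(1L))
  nd$bwd <- function(g) {
    at <- 0L
    for (k in seq_along(parts)) {
      acc_grad(parts[[k]], g[, at + seq_len(widths[k]), drop = FALSE])
      at <- at + widths[k]
    }
  }
  ad_record(nd)
}

ad_rbind <- function(parts) {
  parts <- lapply(parts, ad_wrap)
  nd <- ad_node(do.call(rbind, lapply(parts, function(p) p$value)),
                rg = any(vapply(parts, function(p) p$rg, logical(1L))))
  heights <- vapply(parts, function(p) nrow(p$value), integer(1L))
  nd$bwd <- function(g) {
    at <- 0L
    for (k in seq_along(parts)) {
      acc_grad(parts[[k]], g[at + seq_len(heights[k]), , drop = FALSE])
      at <- at + heights[k]
    }
  }
  ad_record(nd)
}

# im2col gather: idx indexes linearly into a's value (0 reads zero padding);
# the output is a matrix with nrow_out rows.
ad_gather <- function(a, idx, nrow_out) {
  a <- ad_wrap(a)
  v <- gather0(a$value, idx)
  dim(v) <- c(nrow_out, length(idx) %/% nrow_out)
  nd <- ad_node(v, rg = a$rg)
  dims <- dim(a$value)
  nd$bwd <- function(g) {
    gi <- scatter_add0(g, idx, length(a$value))
    dim(gi) <- dims
    acc_grad(a, gi)
  }
  ad_record(nd)
}

# Fused convolution in compiled code: kernel-offset decomposition (one GEMM
# per kernel tap on column subsets). `pairs` holds the precomputed 0-based
# output/input column index pairs per tap; `outcols` is the output width.
ad_conv <- function(x, W, pairs, c_in, outcols) {
  x <- ad_wrap(x)
  nd <- ad_node(conv_forward(x$value, W$value, pairs, c_in, outcols),
                rg = x$rg || W$rg)
  nd$bwd <- function(g) {
    bw <- conv_backward(x$value, W$value, g, pairs, c_in, need_dx = x$rg)
    acc_grad(W, bw$dW)
    if (x$rg) acc_grad(x, bw$dx)
  }
  ad_record(nd)
}

# Repeat each column of a (C x N) `times` times: C x (times*N), image-major.
ad_expand_cols <- function(a, times) {
  a <- ad_wrap(a)
  n <- ncol(a$value)
  grp <- rep(seq_len(n), each = times)
  nd <- ad_node(a$value[, grp, drop = FALSE], rg = a$rg)
  nd$bwd <- function(g) {
    acc_grad(a, t(rowsum(t(g), group = grp)))
  }
  ad_record(nd)
}

# Mean over consecutive blocks of `times` columns: C x (times*N) -> C x N.
ad_pool_cols <- function(a, times) {
  a <- ad_wrap(a)
  n <- ncol(a$value) %/% times
  grp <- rep(seq_len(n), each = times)
  nd <- ad_node(t(rowsum(t(a$value), group = grp)) / times, rg = a$rg)
  nd$bwd <- function(g) {
    acc_grad(a, g[, grp, drop = FALSE] / times)
  }
  ad_record(nd)
}

# Row-wise standardization with population variance (batch-norm / layer-norm
# core). Each row is normalized over its columns.
ad_norm_rows <- function(a, eps = 1e-5) {
  a <- ad_wrap(a)
  fw <- rownorm_forward(a$value, eps)
  nd <- ad_node(fw$y, rg = a$rg)
  nd$bwd <- function(g) acc_grad(a, rownorm_backward(fw$y, g, fw$inv))
  ad_record(nd)
}

# FiLM affine modulation: x (C x times*N, image-major) scaled and shifted by
# per-image, per-channel gamma/beta (C x N).
ad_film <- function(x, gamma, beta, times) {
  x <- ad_wrap(x); gamma <- ad_wrap(gamma); beta <- ad_wrap(beta)
  nd <- ad_node(film_forward(x$value, gamma$value, beta$value, times),
                rg = x$rg || gamma$rg || beta$rg)
  nd$bwd <- function(g) {
    bw <- film_backward(x$value, gamma$value, g, times)
    acc_grad(x, bw$dx)
    acc_grad(gamma, bw$dgamma)
    acc_grad(beta, bw$dbeta)
  }
  ad_record(nd)
}

# Fused weighted cross-entropy on logits (numerically stable log-softmax).
# y: one-hot constant matrix N x C; alpha: numeric length-C class weights.
ad_wce_logits <- function(logits, y, alpha) {
  logits <- ad_wrap(logits)
  n <- nrow(logits$value)
  m <- apply(logits$value, 1L, max)
  e <- exp(logits$value - m)
  se <- rowSums(e)
  logp <- logits$value - m - log(se)
  p <- e / se
  aw <- matrix(alpha, nrow = n, ncol = length(alpha), byrow = TRUE)
  loss <- -sum(aw * y * logp) / n
  nd <- ad_node(matrix(loss, 1L, 1L), rg = logits$rg)
  w <- rowSums(y * aw) # per-row weight of the true class
  nd$bwd <- function(g) {
    acc_grad(logits, (g[1L, 1L] / n) * w * (p - y))
  }
  ad_record(nd)
}
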