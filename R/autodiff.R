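# Minimal reverse-mode automatic differentiation on a linear tape.
#
# Every tracked quantity is an `adnode`: an environment holding a numeric
# matrix `value`, the tape it lives on, its parent nodes and a vector-Jacobian
# product closure. A forward pass builds the tape in execution order;
# `ad_backward()` walks it once in reverse. One tape per forward pass; model
# parameters are plain matrices wrapped freshly with `ad_var()` each pass and
# their gradients read back after `ad_backward()`.
#
# All values are dense base-R matrices (vectors are n x 1 matrices). This is
# deliberately small: only the operations the graph-attention models need.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

.ad_node <- function(tape, value, parents = list(), vjp = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$tape <- tape
  n$parents <- parents
  n$vjp <- vjp
  n$grad <- NULL
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    length(tape$nodes) <- 2L * length(tape$nodes)
  }
  tape$nodes[[tape$n]] <- n
  n$idx <- tape$n
  class(n) <- "adnode"
  n
}

is_adnode <- function(x) inherits(x, "adnode")

#' @noRd
ad_value <- function(x) if (is_adnode(x)) x$value else x

.ad_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

# Tracked leaf (parameter or input).
ad_var <- function(tape, value) {
  .ad_node(tape, .ad_mat(value))
}

.ad_tape_of <- function(...) {
  for (a in list(...)) if (is_adnode(a)) return(a$tape)
  stop("no adnode among arguments", call. = FALSE)
}

# Accumulate gradient g into node p (if tracked), coercing to p's shape.
.ad_acc <- function(p, g) {
  if (is_adnode(p)) {
    if (!is.matrix(g)) g <- matrix(g, nrow(p$value), ncol(p$value))
    p$grad <- if (is.null(p$grad)) g else p$grad + g
  }
  invisible(NULL)
}

#' Reverse sweep: populate `grad` on every node reachable from `root`.
#' `root` must be scalar-valued.
#' @noRd
ad_backward <- function(root) {
  stopifnot(is_adnode(root), length(root$value) == 1L)
  tape <- root$tape
  for (i in seq_len(tape$n)) tape$nodes[[i]]$grad <- NULL
  root$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$vjp)) next
    gs <- nd$vjp(nd$grad)
    for (k in seq_along(nd$parents)) .ad_acc(nd$parents[[k]], gs[[k]])
  }
  invisible(root)
}

ad_grad <- function(x) {
  if (is.null(x$grad)) matrix(0, nrow(x$value), ncol(x$value)) else x$grad
}

# ---- primitive operations ----------------------------------------------------

ad_matmul <- function(a, b) {
  tape <- .ad_tape_of(a, b)
  av <- .ad_mat(ad_value(a)); bv <- .ad_mat(ad_value(b))
  .ad_node(tape, av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

ad_add <- function(a, b) {
  tape <- .ad_tape_of(a, b)
  av <- ad_value(a); bv <- ad_value(b)
  stopifnot(length(av) == length(bv) || length(av) == 1L || length(bv) == 1L)
  avv <- if (length(av) == 1L) as.numeric(av) else av
  bvv <- if (length(bv) == 1L) as.numeric(bv) else bv
  .ad_node(tape, .ad_mat(avv + bvv), list(a, b), function(g) {
    ga <- if (length(av) == 1L) sum(g) else g
    gb <- if (length(bv) == 1L) sum(g) else g
    list(ga, gb)
  })
}

ad_sub <- function(a, b) {
  tape <- .ad_tape_of(a, b)
  av <- ad_value(a); bv <- ad_value(b)
  stopifnot(length(av) == length(bv) || length(av) == 1L || length(bv) == 1L)
  avv <- if (length(av) == 1L) as.numeric(av) else av
  bvv <- if (length(bv) == 1L) as.numeric(bv) else bv
  .ad_node(tape, .ad_mat(avv - bvv), list(a, b), function(g) {
    ga <- if (length(av) == 1L) sum(g) else g
    gb <- if (length(bv) == 1L) -sum(g) else -g
    list(ga, gb)
  })
}

ad_mul <- function(a, b) {
  tape <- .ad_tape_of(a, b)
  av <- ad_value(a); bv <- ad_value(b)
  stopifnot(length(av) == length(bv) || length(av) == 1L || length(bv) == 1L)
  avv <- if (length(av) == 1L) as.numeric(av) else av
  bvv <- if (length(bv) == 1L) as.numeric(bv) else bv
  .ad_node(tape, .ad_mat(avv * bvv), list(a, b), function(g) {
    ga <- if (length(av) == 1L) sum(g * bvv) else g * bvv
    gb <- if (length(bv) == 1L) sum(g * avv) else g * avv
    list(ga, gb)
  })
}

ad_div <- function(a, b) {
  tape <- .ad_tape_of(a, b)
  av <- ad_value(a); bv <- ad_value(b)
  stopifnot(length(av) == length(bv) || length(av) == 1L || length(bv) == 1L)
  avv <- if (length(av) == 1L) as.numeric(av) else av
  bvv <- if (length(bv) == 1L) as.numeric(bv) else bv
  .ad_node(tape, .ad_mat(avv / bvv), list(a, b), function(g) {
    ga <- if (length(av) == 1L) sum(g / bvv) else g / bvv
    gbfull <- -g * avv / (bvv * bvv)
    gb <- if (length(bv) == 1L) sum(gbfull) else gbfull
    list(ga, gb)
  })
}

# x^p for constant p; x must be >= 0 when p is non-integer.
ad_pow <- function(a, p) {
  tape <- .ad_tape_of(a)
  av <- ad_value(a)
  .ad_node(tape, av^p, list(a), function(g) list(g * p * av^(p - 1)))
}

ad_sqrt <- function(a) ad_pow(a, 0.5)

ad_exp <- function(a) {
  tape <- .ad_tape_of(a)
  v <- exp(ad_value(a))
  .ad_node(tape, v, list(a), function(g) list(g * v))
}

ad_log <- function(a) {
  tape <- .ad_tape_of(a)
  av <- ad_value(a)
  .ad_node(tape, log(av), list(a), function(g) list(g / av))
}

ad_tanh <- function(a) {
  tape <- .ad_tape_of(a)
  v <- tanh(ad_value(a))
  .ad_node(tape, v, list(a), function(g) list(g * (1 - v * v)))
}

ad_relu <- function(a) {
  tape <- .ad_tape_of(a)
  av <- ad_value(a)
  .ad_node(tape, pmax(av, 0), list(a), function(g) list(g * (av > 0)))
}

ad_leakyrelu <- function(a, slope = 0.2) {
  tape <- .ad_tape_of(a)
  av <- ad_value(a)
  fac <- ifelse(av > 0, 1, slope)
  .ad_node(tape, av * fac, list(a), function(g) list(g * fac))
}

ad_sum <- function(a) {
  tape <- .ad_tape_of(a)
  av <- ad_value(a)
  .ad_node(tape, matrix(sum(av), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g), nrow(av), ncol(av)))
  })
}

ad_mean <- function(a) {
  tape <- .ad_tape_of(a)
  av <- ad_value(a)
  .ad_node(tape, matrix(mean(av), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g) / length(av), nrow(av), ncol(av)))
  })
}

# Row sums of an n x d matrix -> n x 1.
ad_rowsums <- function(a) {
  tape <- .ad_tape_of(a)
  av <- .ad_mat(ad_value(a))
  .ad_node(tape, matrix(rowSums(av), ncol = 1L), list(a), function(g) {
    list(matrix(as.numeric(g), nrow(av), ncol(av)))
  })
}

# Row means of an n x d matrix -> n x 1 (per-node pooling).
ad_rowmeans <- function(a) {
  tape <- .ad_tape_of(a)
  av <- .ad_mat(ad_value(a))
  .ad_node(tape, matrix(rowMeans(av), ncol = 1L), list(a), function(g) {
    list(matrix(as.numeric(g) / ncol(av), nrow(av), ncol(av)))
  })
}

# Gather rows: out[k, ] = x[idx[k], ].
ad_gather_rows <- function(a, idx) {
  tape <- .ad_tape_of(a)
  av <- .ad_mat(ad_value(a))
  .ad_node(tape, av[idx, , drop = FALSE], list(a), function(g) {
    list(.segment_rowsum(g, idx, nrow(av)))
  })
}

# Scatter-add rows: out has n rows; out[i, ] = sum over k with idx[k] == i of x[k, ].
ad_scatter_rows <- function(a, idx, n) {
  tape <- .ad_tape_of(a)
  av <- .ad_mat(ad_value(a))
  v <- .segment_rowsum(av, idx, n)
  .ad_node(tape, v, list(a), function(g) list(g[idx, , drop = FALSE]))
}

# Plain-numeric helper: sum rows of x into n groups given by idx (1..n).
.segment_rowsum <- function(x, idx, n) {
  out <- matrix(0, n, ncol(x))
  rs <- rowsum(x, idx, reorder = TRUE)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# Softmax within segments: x and seg are length-E; normalization over entries
# sharing a segment id. Returns E x 1.
ad_segment_softmax <- function(a, seg, nseg) {
  tape <- .ad_tape_of(a)
  av <- as.numeric(ad_value(a))
  mx <- rep(-Inf, nseg)
  mxagg <- tapply(av, seg, max)
  mx[as.integer(names(mxagg))] <- mxagg
  ex <- exp(av - mx[seg])
  den <- as.numeric(.segment_rowsum(matrix(ex, ncol = 1L), seg, nseg))
  alpha <- ex / den[seg]
  .ad_node(tape, matrix(alpha, ncol = 1L), list(a), function(g) {
    gv <- as.numeric(g)
    s <- as.numeric(.segment_rowsum(matrix(gv * alpha, ncol = 1L), seg, nseg))
    list(matrix(alpha * (gv - s[seg]), ncol = 1L))
  })
}

# Multiply row k of x (E x d) by scalar s[k]; s may be tracked (E x 1).
ad_scale_rows <- function(a, s) {
  tape <- .ad_tape_of(a, s)
  av <- .ad_mat(ad_value(a))
  sv <- as.numeric(ad_value(s))
  stopifnot(length(sv) == nrow(av))
  .ad_node(tape, av * sv, list(a, s), function(g) {
    list(g * sv, matrix(rowSums(g * av), ncol = 1L))
  })
}

# Add a 1 x d row vector to every row of an n x d matrix.
ad_add_rowvec <- function(a, b) {
  tape <- .ad_tape_of(a, b)
  av <- .ad_mat(ad_value(a)); bv <- .ad_mat(ad_value(b))
  stopifnot(ncol(av) == ncol(bv), nrow(bv) == 1L)
  .ad_node(tape, sweep(av, 2L, as.numeric(bv), "+"), list(a, b), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

ad_concat_cols <- function(a, b) {
  tape <- .ad_tape_of(a, b)
  av <- .ad_mat(ad_value(a)); bv <- .ad_mat(ad_value(b))
  na <- ncol(av)
  .ad_node(tape, cbind(av, bv), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

# Numerically stable log(sum(exp(x))) over all entries -> scalar.
ad_logsumexp <- function(a) {
  tape <- .ad_tape_of(a)
  av <- ad_value(a)
  m <- max(av)
  v <- m + log(sum(exp(av - m)))
  sm <- exp(av - v)
  .ad_node(tape, matrix(v, 1L, 1L), list(a), function(g) {
    list(as.numeric(g) * sm)
  })
}

# Stable softmax over all entries of a vector (n x 1 in, n x 1 out).
ad_softmax_vec <- function(a) {
  tape <- .ad_tape_of(a)
  av <- as.numeric(ad_value(a))
  p <- exp(av - max(av))
  p <- p / sum(p)
  .ad_node(tape, matrix(p, ncol = 1L), list(a), function(g) {
    gv <- as.numeric(g)
    list(matrix(p * (gv - sum(gv * p)), ncol = 1L))
  })
}

# ---- Adam optimizer ----------------------------------------------------------

#' Create an Adam optimizer state for a named list of parameter matrices.
#' L2 weight decay is applied by adding `weight_decay * theta` to the gradient.
#' @noRd
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  st <- list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
             weight_decay = weight_decay, t = 0L,
             m = lapply(params, function(p) p * 0),
             v = lapply(params, function(p) p * 0))
  st
}

#' One Adam update. `grads` is a named list aligned with `params`
#' (missing/NULL entries are treated as zero gradient).
#' @noRd
adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- params[[nm]] * 0
    if (state$weight_decay > 0) g <- g + state$weight_decay * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(state = state, params = params)
}
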