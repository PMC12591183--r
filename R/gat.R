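# Graph attention layer.
#
# A layer follows the standard multi-head GAT update: per head, attention
# logits LeakyReLU(a^T [W2 h_i || W2 h_j]) are softmax-normalized over each
# node's in-neighborhood, multiplied by the (non-learned) edge weight e_ij,
# and used to aggregate linearly transformed neighbor states W1 h_j. Hidden
# layers concatenate heads; output layers average them. Edge weights enter
# multiplicatively after normalization, which is what makes them a natural
# handle for integrated-gradients attribution later.

#' Initialize parameters for one GAT layer
#'
#' Glorot-uniform initialization. Parameters are returned as a flat named
#' list of matrices, keyed `<prefix>.<name>.<head>`; the flat layout is what
#' the Adam optimizer and checkpoints operate on.
#'
#' @param d_in input feature dimension.
#' @param d_out total output dimension (split across heads when `concat`).
#' @param heads number of attention heads.
#' @param concat concatenate head outputs (`TRUE`, hidden layers) or average
#'   them (`FALSE`, output layers).
#' @param prefix name prefix for the parameter list.
#' @return named list of parameter matrices with attribute `meta`.
#' @keywords internal
gat_init <- function(d_in, d_out, heads = 4L, concat = TRUE, prefix = "gat") {
  d_head <- if (concat) {
    if (d_out %% heads != 0L) stop("d_out must be divisible by heads under concat")
    d_out %/% heads
  } else d_out
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  params <- list()
  for (h in seq_len(heads)) {
    params[[sprintf("%s.W1.%d", prefix, h)]] <- glorot(d_in, d_head)
    params[[sprintf("%s.W2.%d", prefix, h)]] <- glorot(d_in, d_head)
    params[[sprintf("%s.a1.%d", prefix, h)]] <- glorot(d_head, 1L)
    params[[sprintf("%s.a2.%d", prefix, h)]] <- glorot(d_head, 1L)
  }
  attr(params, "meta") <- list(d_in = d_in, d_out = d_out, heads = heads,
                               concat = concat, d_head = d_head, prefix = prefix)
  params
}

# Tape-level layer application. `H` is an adnode (N x d_in); `pw` a named list
# of adnodes holding this layer's parameters; `src`/`dst` 1-based edge
# endpoints (dst receives); `w` edge weights, numeric or adnode (E x 1).
# Returns adnode N x d_out.
.gat_layer <- function(tape, H, src, dst, w, pw, meta, n_nodes,
                       negative_slope = 0.2, train = FALSE, dropout_p = 0,
                       collect = NULL) {
  heads_out <- vector("list", meta$heads)
  for (h in seq_len(meta$heads)) {
    W1 <- pw[[sprintf("%s.W1.%d", meta$prefix, h)]]
    W2 <- pw[[sprintf("%s.W2.%d", meta$prefix, h)]]
    a1 <- pw[[sprintf("%s.a1.%d", meta$prefix, h)]]
    a2 <- pw[[sprintf("%s.a2.%d", meta$prefix, h)]]
    HW1 <- ad_matmul(H, W1)
    HW2 <- ad_matmul(H, W2)
    s_dst <- ad_matmul(HW2, a1)   # pairs with the receiving node h_i
    s_src <- ad_matmul(HW2, a2)   # pairs with the neighbor h_j
    logit <- ad_leakyrelu(
      ad_add(ad_gather_rows(s_dst, dst), ad_gather_rows(s_src, src)),
      negative_slope)
    alpha <- ad_segment_softmax(logit, dst, n_nodes)
    if (!is.null(collect)) collect$alpha[[h]] <- as.numeric(ad_value(alpha))
    if (train && dropout_p > 0) {
      keep <- (stats::runif(length(src)) >= dropout_p) / (1 - dropout_p)
      alpha <- ad_mul(alpha, matrix(keep, ncol = 1L))
    }
    coef <- if (is_adnode(w) || any(ad_value(w) != 1)) ad_mul(alpha, w) else alpha
    msg <- ad_scale_rows(ad_gather_rows(HW1, src), coef)
    heads_out[[h]] <- ad_scatter_rows(msg, dst, n_nodes)
  }
  if (meta$concat) {
    out <- heads_out[[1L]]
    for (h in seq_len(meta$heads)[-1L]) out <- ad_concat_cols(out, heads_out[[h]])
    out
  } else {
    out <- heads_out[[1L]]
    for (h in seq_len(meta$heads)[-1L]) out <- ad_add(out, heads_out[[h]])
    ad_mul(out, 1 / meta$heads)
  }
}

#' Apply one graph-attention layer
#'
#' Evaluation-mode forward pass over an explicit edge list. Every node must
#' receive at least one edge (callers are expected to add self-loops); the
#' softmax over an empty in-neighborhood is undefined and raises an error.
#'
#' @param H numeric matrix, nodes x input-dim.
#' @param edges list with integer vectors `src`, `dst` (1-based; `dst`
#'   receives) and optionally `w`, per-edge weights (default 1).
#' @param params parameter list from [gat_init()].
#' @param train logical; enables attention-coefficient dropout.
#' @param dropout_p dropout probability on normalized attention coefficients.
#' @param negative_slope LeakyReLU slope for attention logits.
#' @param return_attention also return the normalized attention coefficients.
#' @return numeric matrix, nodes x output-dim; with `return_attention`, a
#'   list with `H` and `attention` (edges x heads matrix of coefficients,
#'   rows aligned with the edge list).
#' @examples
#' set.seed(1)
#' p <- gat_init(3, 4, heads = 2)
#' H <- matrix(rnorm(6), 2, 3)
#' edges <- list(src = c(1L, 2L, 1L, 2L), dst = c(1L, 2L, 2L, 1L))
#' gat_forward(H, edges, p)
#' @export
gat_forward <- function(H, edges, params, train = FALSE, dropout_p = 0,
                        negative_slope = 0.2, return_attention = FALSE) {
  H <- as.matrix(H)
  if (!all(is.finite(H))) stop("non-finite entries in input features")
  n <- nrow(H)
  src <- as.integer(edges$src); dst <- as.integer(edges$dst)
  if (length(src) != length(dst)) stop("src/dst length mismatch")
  if (any(src < 1L | src > n | dst < 1L | dst > n)) stop("edge index out of range")
  missing_dst <- setdiff(seq_len(n), unique(dst))
  if (length(missing_dst) > 0L) {
    stop("nodes without incoming edges (add self-loops): ",
         paste(utils::head(missing_dst, 5L), collapse = ", "))
  }
  w <- if (is.null(edges$w)) rep(1, length(src)) else as.numeric(edges$w)
  meta <- attr(params, "meta")
  tape <- ad_tape()
  pw <- lapply(params, function(p) ad_var(tape, p))
  attr(pw, "meta") <- meta
  Hn <- ad_var(tape, H)
  collect <- if (return_attention) new.env(parent = emptyenv()) else NULL
  if (!is.null(collect)) collect$alpha <- vector("list", meta$heads)
  out <- .gat_layer(tape, Hn, src, dst, matrix(w, ncol = 1L), pw, meta, n,
                    negative_slope = negative_slope, train = train,
                    dropout_p = dropout_p, collect = collect)
  if (return_attention) {
    list(H = ad_value(out), attention = do.call(cbind, collect$alpha))
  } else {
    ad_value(out)
  }
}

# Add a self-loop for every node to an edge list (weight 1).
add_self_loops <- function(edges, n_nodes) {
  has_loop <- edges$src == edges$dst
  keep <- !has_loop
  src <- c(edges$src[keep], seq_len(n_nodes))
  dst <- c(edges$dst[keep], seq_len(n_nodes))
  w <- c((if (is.null(edges$w)) rep(1, length(edges$src)) else edges$w)[keep],
         rep(1, n_nodes))
  list(src = as.integer(src), dst = as.integer(dst), w = as.numeric(w))
}

# Symmetrize a directed edge list (used for the pretraining CRE-CRE graph).
make_undirected_edges <- function(edges) {
  key <- paste(pmin(edges$src, edges$dst), pmax(edges$src, edges$dst))
  keep <- !duplicated(key) & edges$src != edges$dst
  s <- edges$src[keep]; d <- edges$dst[keep]
  list(src = as.integer(c(s, d)), dst = as.integer(c(d, s)))
}
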