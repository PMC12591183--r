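# Self-supervised masked graph autoencoder (SSGAE).
#
# Per-cell accessibility graphs share one CRE-CRE topology; node features are
# each cell's accessibility values. Training masks a fraction of nodes
# (features replaced by a learnable mask token), encodes the corrupted graph
# with two GAT layers, decodes with one GAT layer, and minimizes the scaled
# cosine error (SCE) on the masked nodes. Because raw node features are
# scalars — on which a cosine is degenerate — features are first lifted to the
# hidden dimension by a learnable linear embedding, and the reconstruction
# target is the lifted (stop-gradient) encoder-input representation.

#' Initialize an SSGAE model
#'
#' Encoder: two multi-head GAT layers (heads concatenated, LeakyReLU between
#' them); decoder: one GAT layer with heads averaged. All hidden states have
#' dimension `hidden_dim`.
#'
#' @param hidden_dim node hidden-state dimension (default 64).
#' @param heads attention heads per layer (default 4).
#' @param mask_ratio fraction of nodes masked during training (default 0.5).
#' @param gamma SCE focusing exponent, > 1 (default 2).
#' @param dropout_p dropout on normalized attention coefficients (default 0.5).
#' @param negative_slope LeakyReLU slope (default 0.2).
#' @param seed RNG seed for parameter initialization.
#' @return object of class `ssgae_model`.
#' @export
init_ssgae <- function(hidden_dim = 64, heads = 4, mask_ratio = 0.5,
                       gamma = 2, dropout_p = 0.5, negative_slope = 0.2,
                       seed = 1L) {
  stopifnot(mask_ratio > 0, mask_ratio < 1)
  set.seed(seed)
  params <- list()
  lim <- sqrt(6 / (1 + hidden_dim))
  params[["lift.W"]] <- matrix(stats::runif(hidden_dim, -lim, lim), 1L, hidden_dim)
  params[["lift.b"]] <- matrix(0, 1L, hidden_dim)
  params[["mask_token"]] <- matrix(stats::rnorm(hidden_dim, sd = 0.1), 1L, hidden_dim)
  enc1 <- gat_init(hidden_dim, hidden_dim, heads, concat = TRUE, prefix = "enc1")
  enc2 <- gat_init(hidden_dim, hidden_dim, heads, concat = TRUE, prefix = "enc2")
  dec <- gat_init(hidden_dim, hidden_dim, heads, concat = FALSE, prefix = "dec")
  meta <- list(enc1 = attr(enc1, "meta"), enc2 = attr(enc2, "meta"),
               dec = attr(dec, "meta"))
  params <- c(params, enc1, enc2, dec)
  structure(list(params = params,
                 config = list(hidden_dim = hidden_dim, heads = heads,
                               mask_ratio = mask_ratio, gamma = gamma,
                               dropout_p = dropout_p,
                               negative_slope = negative_slope,
                               layer_meta = meta),
                 trained = FALSE, loss_trace = numeric(0)),
            class = "ssgae_model")
}

#' @export
print.ssgae_model <- function(x, ...) {
  cat(sprintf(paste0("ssgae_model: hidden_dim=%d, heads=%d, mask_ratio=%.2f, ",
                     "gamma=%g%s\n"),
              x$config$hidden_dim, x$config$heads, x$config$mask_ratio,
              x$config$gamma,
              if (x$trained) sprintf(" [trained, %d steps]", length(x$loss_trace))
              else " [untrained]"))
  invisible(x)
}

#' Mask node features with a token
#'
#' Samples `floor(mask_ratio * M)` nodes uniformly without replacement and
#' replaces their feature rows with `token`. Sampling uses R's RNG; fix the
#' seed beforehand for reproducibility.
#'
#' @param X numeric matrix, nodes x feature-dim.
#' @param mask_ratio fraction of nodes to mask, in (0, 1).
#' @param token numeric vector of length `ncol(X)` (default all zero).
#' @return list with `X_masked` and integer `masked_idx`.
#' @export
mask_node_features <- function(X, mask_ratio, token = rep(0, ncol(X))) {
  stopifnot(mask_ratio > 0, mask_ratio < 1)
  X <- as.matrix(X)
  n_mask <- floor(mask_ratio * nrow(X))
  if (n_mask < 1L) stop("mask_ratio yields zero masked nodes")
  idx <- sort(sample.int(nrow(X), n_mask))
  X[idx, ] <- matrix(token, n_mask, ncol(X), byrow = TRUE)
  list(X_masked = X, masked_idx = idx)
}

#' Scaled cosine error over masked nodes
#'
#' `mean over masked nodes of (1 - cos(x_m, z_m))^gamma`. Down-weights easy
#' (already well-reconstructed) nodes for `gamma > 1`.
#'
#' @param X original node features (nodes x d).
#' @param Z reconstructed node features (same shape).
#' @param masked_idx integer indices of masked nodes (non-empty).
#' @param gamma focusing exponent; values <= 1 trigger a warning.
#' @return scalar loss, >= 0.
#' @export
sce_loss <- function(X, Z, masked_idx, gamma = 2) {
  if (length(masked_idx) == 0L) stop("masked_idx is empty")
  if (gamma <= 1) warning("gamma <= 1: easy samples are not down-weighted")
  X <- as.matrix(X)[masked_idx, , drop = FALSE]
  Z <- as.matrix(Z)[masked_idx, , drop = FALSE]
  eps <- 1e-8
  cosv <- rowSums(X * Z) /
    (sqrt(rowSums(X * X) + eps) * sqrt(rowSums(Z * Z) + eps))
  mean((1 - cosv)^gamma)
}

# Wrap model params as adnodes on a fresh tape, preserving layer meta.
.wrap_params <- function(tape, params) {
  lapply(params, function(p) ad_var(tape, p))
}

# Encoder on the tape: lift -> GAT1 -> LeakyReLU -> GAT2. `Xcol` is the
# numeric M x 1 feature column; `mask_idx` NULL for no masking.
.ssgae_encode_tape <- function(tape, pw, cfg, Xcol, edges, n, mask_idx = NULL,
                               train = FALSE) {
  X_emb <- ad_add_rowvec(ad_matmul(Xcol, pw[["lift.W"]]), pw[["lift.b"]])
  target <- ad_value(X_emb)   # stop-gradient reconstruction target
  if (!is.null(mask_idx)) {
    keep <- rep(1, n); keep[mask_idx] <- 0
    maskcol <- matrix(as.numeric(seq_len(n) %in% mask_idx), ncol = 1L)
    X_emb <- ad_add(ad_scale_rows(X_emb, matrix(keep, ncol = 1L)),
                    ad_matmul(maskcol, pw[["mask_token"]]))
  }
  w <- matrix(edges$w, ncol = 1L)
  h1 <- ad_leakyrelu(
    .gat_layer(tape, X_emb, edges$src, edges$dst, w, pw,
               cfg$layer_meta$enc1, n, cfg$negative_slope, train, cfg$dropout_p),
    cfg$negative_slope)
  h2 <- .gat_layer(tape, h1, edges$src, edges$dst, w, pw,
                   cfg$layer_meta$enc2, n, cfg$negative_slope, train,
                   cfg$dropout_p)
  list(H = h2, target = target)
}

# Full masked-autoencoder loss on the tape for one cell.
.ssgae_loss_tape <- function(tape, pw, cfg, Xcol, edges, n, mask_idx,
                             train = TRUE) {
  enc <- .ssgae_encode_tape(tape, pw, cfg, Xcol, edges, n, mask_idx, train)
  w <- matrix(edges$w, ncol = 1L)
  Z <- .gat_layer(tape, enc$H, edges$src, edges$dst, w, pw,
                  cfg$layer_meta$dec, n, cfg$negative_slope, train,
                  cfg$dropout_p)
  Zm <- ad_gather_rows(Z, mask_idx)
  Tm <- enc$target[mask_idx, , drop = FALSE]
  eps <- 1e-8
  # cosine between reconstructed and target rows
  dotp <- ad_rowsums(ad_mul(Zm, Tm))
  zn <- ad_sqrt(ad_add(ad_rowsums(ad_mul(Zm, Zm)), eps))
  tn <- matrix(sqrt(rowSums(Tm * Tm) + eps), ncol = 1L)
  cosv <- ad_div(dotp, ad_mul(zn, tn))
  ad_mean(ad_pow(ad_sub(1, cosv), cfg$gamma))
}

#' Pretrain an SSGAE on per-cell accessibility graphs
#'
#' Adam optimization of the masked-node SCE, one optimizer step per cell
#' graph per epoch (batch size 1), cells shuffled each epoch. Deterministic
#' under a fixed seed and single-threaded BLAS.
#'
#' @param model an `ssgae_model` from [init_ssgae()].
#' @param X_cells numeric matrix, cells x nodes: per-cell node features
#'   (e.g. `log1p` aggregated accessibility counts).
#' @param edges shared symmetric edge list with self-loops
#'   (see [pretrain_graph_edges()]).
#' @param epochs number of passes over the cells.
#' @param lr Adam learning rate (default 1e-4).
#' @param weight_decay L2 weight decay (default 1e-4).
#' @param seed RNG seed governing masking, shuffling and dropout.
#' @param accum gradient-accumulation steps (emulates larger batches).
#' @return the trained `ssgae_model` with a per-step `loss_trace`.
#' @export
pretrain_ssgae <- function(model, X_cells, edges, epochs = 10, lr = 1e-4,
                           weight_decay = 1e-4, seed = 1L, accum = 1L) {
  stopifnot(inherits(model, "ssgae_model"))
  X_cells <- as.matrix(X_cells)
  n_cells <- nrow(X_cells); n_nodes <- ncol(X_cells)
  if (n_cells < 1L) stop("need at least one cell graph")
  cfg <- model$config
  params <- model$params
  opt <- adam_init(params, lr = lr, weight_decay = weight_decay)
  trace <- numeric(0)
  set.seed(seed)
  acc_grads <- NULL; acc_n <- 0L
  for (ep in seq_len(epochs)) {
    order_cells <- sample.int(n_cells)
    for (ci in order_cells) {
      n_mask <- floor(cfg$mask_ratio * n_nodes)
      if (n_mask < 1L) stop("mask_ratio yields zero masked nodes")
      mask_idx <- sort(sample.int(n_nodes, n_mask))
      tape <- ad_tape()
      pw <- .wrap_params(tape, params)
      loss <- .ssgae_loss_tape(tape, pw, cfg,
                               matrix(X_cells[ci, ], ncol = 1L),
                               edges, n_nodes, mask_idx, train = TRUE)
      lv <- as.numeric(ad_value(loss))
      if (!is.finite(lv)) stop("divergent (non-finite) SSGAE loss at epoch ", ep)
      trace <- c(trace, lv)
      ad_backward(loss)
      g <- lapply(pw, ad_grad)
      if (is.null(acc_grads)) acc_grads <- g
      else for (nm in names(g)) acc_grads[[nm]] <- acc_grads[[nm]] + g[[nm]]
      acc_n <- acc_n + 1L
      if (acc_n >= accum) {
        if (accum > 1L) acc_grads <- lapply(acc_grads, function(x) x / accum)
        upd <- adam_step(opt, params, acc_grads)
        opt <- upd$state; params <- upd$params
        acc_grads <- NULL; acc_n <- 0L
      }
    }
  }
  model$params <- params
  model$trained <- TRUE
  model$loss_trace <- trace
  model
}

#' Encode node features with a (pre)trained SSGAE encoder
#'
#' Evaluation mode: no masking, no dropout.
#' @param model an `ssgae_model`.
#' @param x numeric vector (or 1-column matrix) of node features.
#' @param edges edge list with self-loops.
#' @return numeric matrix, nodes x hidden_dim.
#' @export
ssgae_encode <- function(model, x, edges) {
  stopifnot(inherits(model, "ssgae_model"))
  Xcol <- matrix(as.numeric(x), ncol = 1L)
  n <- nrow(Xcol)
  tape <- ad_tape()
  pw <- .wrap_params(tape, model$params)
  enc <- .ssgae_encode_tape(tape, pw, model$config, Xcol, edges, n,
                            mask_idx = NULL, train = FALSE)
  ad_value(enc$H)
}
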