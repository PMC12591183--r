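# Cis-regulation simulation with a causal graph-attention layer (GCAT).
#
# Node features (CRE accessibility; gene nodes initialized from the CRE
# nearest their TSS) are encoded two ways — a fresh linear+ReLU encoder and,
# unless running without pretraining ("wop"), the frozen SSGAE encoder — and
# concatenated. One GAT layer runs on the masked directed graph (evidence
# CRE->gene edges plus self-loops), so information flows only along
# evidence-supported links. Per-node pooling yields a predicted expression
# value per gene; after standardization and softmax this is matched to the
# cell type's pseudobulk expression distribution by KL divergence, plus a
# class-balanced cross-entropy on a cell-type classifier head.

#' Initialize gene-node features from the nearest CRE
#'
#' Each gene's feature is the accessibility of the CRE whose interval
#' midpoint is nearest to the gene's TSS (same chromosome); distance ties go
#' to the CRE with the smaller start coordinate.
#'
#' @param atac_row numeric vector of CRE accessibility aligned to `cres` rows.
#' @param cres CRE interval table.
#' @param genes gene table.
#' @return numeric vector of length `nrow(genes)`.
#' @export
init_gene_features <- function(atac_row, cres, genes) {
  idx <- nearest_cre_index(cres, genes)
  as.numeric(atac_row)[idx]
}

#' Index of the CRE nearest to each gene's TSS
#' @inheritParams init_gene_features
#' @return integer vector mapping genes to CRE row indices.
#' @export
nearest_cre_index <- function(cres, genes) {
  mid <- (cres$start + cres$end) / 2
  idx <- integer(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    on_chr <- which(cres$chrom == genes$chrom[g])
    if (length(on_chr) == 0L) {
      bad <- genes$gene_id[!genes$chrom %in% unique(cres$chrom)]
      stop("genes on chromosomes without CREs: ",
           paste(utils::head(bad, 10L), collapse = ", "))
    }
    d <- abs(mid[on_chr] - genes$tss[g])
    best <- on_chr[order(d, cres$start[on_chr])][1L]
    idx[g] <- best
  }
  idx
}

#' Standardize a gene output vector
#'
#' `(u - mean(u)) / sqrt(var(u) + epsilon)` with population variance; the
#' epsilon guards constant vectors.
#' @param u_gene numeric vector.
#' @param epsilon stability constant (default 1e-5).
#' @return standardized numeric vector.
#' @export
normalize_gene_vector <- function(u_gene, epsilon = 1e-5) {
  u <- as.numeric(u_gene)
  v <- mean((u - mean(u))^2)
  (u - mean(u)) / sqrt(v + epsilon)
}

#' Softmax transform of a standardized gene vector
#' @param u_norm numeric vector.
#' @return probability vector (strictly positive, sums to 1).
#' @export
expression_distribution <- function(u_norm) {
  x <- as.numeric(u_norm)
  p <- exp(x - max(x))
  p / sum(p)
}

#' KL divergence between predicted and pseudobulk expression distributions
#'
#' `KL(u_pred || u_true)`; terms with `u_pred = 0` contribute 0 and `u_true`
#' is floored at 1e-12.
#' @param u_pred predicted probability vector.
#' @param u_true cell-type pseudobulk probability vector (same length).
#' @return scalar divergence, >= 0.
#' @export
kl_expression_loss <- function(u_pred, u_true) {
  p <- as.numeric(u_pred); q <- as.numeric(u_true)
  if (length(p) != length(q)) stop("length mismatch between u_pred and u_true")
  q <- pmax(q, 1e-12)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Class-balanced cross-entropy over a batch
#'
#' `-(1/N) * sum_n (1 / N_{c(n)}) * log y_{n, c(n)}`, where `N_c` are the
#' training-set class counts.
#' @param y_pred_batch matrix of predicted class probabilities (cells x C).
#' @param labels integer vector of true class indices (1-based).
#' @param class_counts integer vector of length C of training-set counts.
#' @return scalar loss, >= 0.
#' @export
celltype_loss <- function(y_pred_batch, labels, class_counts) {
  y <- as.matrix(y_pred_batch)
  n <- nrow(y)
  picked <- y[cbind(seq_len(n), labels)]
  if (any(picked <= 0)) {
    warning("zero predicted probability for a true class; clamping at 1e-12")
    picked <- pmax(picked, 1e-12)
  }
  mean(log(picked) * (-1 / class_counts[labels]))
}

#' Combine expression and cell-type losses
#' @param L1 expression (KL) loss.
#' @param L2 cell-type loss.
#' @param lambda weight on `L2` (default 1).
#' @return `L1 + lambda * L2`.
#' @export
total_loss <- function(L1, L2, lambda = 1) L1 + lambda * L2

#' Stratified train/validation/test split of cells
#'
#' Fractions are applied within each cell type (so type proportions are
#' preserved up to rounding) and the three sets partition all cells.
#' @param cell_types character vector of per-cell labels.
#' @param fractions train/val/test fractions summing to 1 (default
#'   `c(0.5, 0.1, 0.4)`).
#' @param seed RNG seed.
#' @return list with integer index vectors `train`, `val`, `test` and `seed`.
#' @export
split_cells <- function(cell_types, fractions = c(0.5, 0.1, 0.4), seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  set.seed(seed)
  train <- integer(0); val <- integer(0); test <- integer(0)
  for (tp in sort(unique(cell_types))) {
    idx <- which(cell_types == tp)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    n_tr <- round(fractions[1L] * n)
    n_va <- round(fractions[2L] * n)
    n_va <- min(n_va, n - n_tr)
    train <- c(train, idx[seq_len(n_tr)])
    if (n_va > 0L) val <- c(val, idx[n_tr + seq_len(n_va)])
    if (n - n_tr - n_va > 0L) test <- c(test, idx[(n_tr + n_va + 1L):n])
  }
  list(train = sort(train), val = sort(val), test = sort(test), seed = seed)
}

#' Assemble per-cell simulation inputs
#'
#' Joins the aggregated accessibility matrix with a CRE->gene evidence graph
#' and the normalized pseudobulk profiles. Node features are
#' `log1p(counts)`; gene-node features come from [init_gene_features()].
#'
#' @param atac aggregated accessibility [cell_matrix()] whose features cover
#'   the graph's CREs.
#' @param graph an `evidence_graph` of kind `"cre_gene"`.
#' @param profiles normalized `expression_profile` whose genes cover the
#'   graph's genes and whose cell types cover the cells'.
#' @return object of class `sim_data`.
#' @export
build_sim_data <- function(atac, graph, profiles) {
  stopifnot(inherits(atac, "cell_matrix"), inherits(graph, "evidence_graph"),
            graph$kind == "cre_gene", inherits(profiles, "expression_profile"))
  fi <- match(graph$cres$id, atac$feature_ids)
  if (anyNA(fi)) stop("graph CREs missing from accessibility matrix")
  A <- as.matrix(atac$values[, fi, drop = FALSE])
  n_cre <- nrow(graph$cres); n_gene <- nrow(graph$genes)
  gi <- match(graph$genes$gene_id, profiles$gene_ids)
  if (anyNA(gi)) stop("graph genes missing from expression profiles")
  u_true <- profiles$values[, gi, drop = FALSE]
  colnames(u_true) <- graph$genes$gene_id
  types <- sort(unique(atac$cell_types))
  if (!all(types %in% profiles$cell_types))
    stop("cell types missing from expression profiles: ",
         paste(setdiff(types, profiles$cell_types), collapse = ", "))
  u_true <- u_true[match(types, profiles$cell_types), , drop = FALSE]
  nearest <- nearest_cre_index(graph$cres, graph$genes)
  Xcre <- log1p(A)
  feats <- cbind(Xcre, Xcre[, nearest, drop = FALSE])
  colnames(feats) <- c(graph$cres$id, graph$genes$gene_id)
  structure(list(features = feats,
                 edges = sim_graph_edges(graph),
                 n_cre = n_cre, n_gene = n_gene,
                 gene_idx = n_cre + seq_len(n_gene),
                 cell_ids = atac$cell_ids,
                 cell_types = atac$cell_types,
                 type_levels = types,
                 u_true = u_true,
                 graph = graph),
            class = "sim_data")
}

#' Initialize the cis-regulation simulation model
#'
#' @param n_genes number of gene nodes.
#' @param n_types number of cell-type classes.
#' @param mode `"full"`, `"posd"` (both use SSGAE embeddings) or `"wop"`
#'   (no pretrained embeddings; GCAT input is the fresh encoding alone).
#' @param hidden_dim hidden dimension (default 64).
#' @param heads attention heads (default 4).
#' @param lambda weight on the cell-type loss (default 1).
#' @param epsilon standardization stability constant (default 1e-5).
#' @param dropout_p attention-coefficient dropout (default 0.5).
#' @param seed RNG seed for initialization.
#' @return object of class `gcat_model` (untrained).
#' @export
init_gcat <- function(n_genes, n_types, mode = c("full", "wop", "posd"),
                      hidden_dim = 64, heads = 4, lambda = 1, epsilon = 1e-5,
                      dropout_p = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  d_in <- if (mode == "wop") hidden_dim else 2L * hidden_dim
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  params <- list("fe.W" = glorot(1L, hidden_dim),
                 "fe.b" = matrix(0, 1L, hidden_dim))
  gcat <- gat_init(d_in, hidden_dim, heads, concat = TRUE, prefix = "gcat")
  params <- c(params, gcat)
  params[["cls.W1"]] <- glorot(hidden_dim, n_genes)
  params[["cls.b1"]] <- matrix(0, hidden_dim, 1L)
  params[["cls.W2"]] <- glorot(n_types, hidden_dim)
  params[["cls.b2"]] <- matrix(0, n_types, 1L)
  structure(list(params = params,
                 config = list(mode = mode, hidden_dim = hidden_dim,
                               heads = heads, lambda = lambda,
                               epsilon = epsilon, dropout_p = dropout_p,
                               negative_slope = 0.2,
                               gcat_meta = attr(gcat, "meta"),
                               n_genes = n_genes, n_types = n_types),
                 trained = FALSE, metrics = NULL, best_epoch = NA_integer_),
            class = "gcat_model")
}

#' @export
print.gcat_model <- function(x, ...) {
  cat(sprintf("gcat_model (%s): %d genes, %d cell types, hidden_dim=%d%s\n",
              x$config$mode, x$config$n_genes, x$config$n_types,
              x$config$hidden_dim,
              if (x$trained) sprintf(" [trained, best epoch %d]", x$best_epoch)
              else " [untrained]"))
  invisible(x)
}

# Frozen SSGAE embeddings for every cell's simulation-node features,
# computed once (the encoder runs on the masked simulation topology).
.precompute_h2 <- function(ssgae, sim_data) {
  lapply(seq_len(nrow(sim_data$features)), function(ci) {
    ssgae_encode(ssgae, sim_data$features[ci, ], sim_data$edges)
  })
}

# One cell's forward pass on the tape. `wnode` replaces the edge-weight
# vector when attributing (adnode, E x 1); H2 is a constant matrix or NULL.
.gcat_forward_tape <- function(tape, pw, cfg, x_feat, H2, edges, n_nodes,
                               gene_idx, wnode = NULL, train = FALSE) {
  Xcol <- matrix(x_feat, ncol = 1L)
  H1 <- ad_relu(ad_add_rowvec(ad_matmul(Xcol, pw[["fe.W"]]), pw[["fe.b"]]))
  Hin <- if (is.null(H2)) H1 else ad_concat_cols(H1, H2)
  w <- if (is.null(wnode)) matrix(edges$w, ncol = 1L) else wnode
  Hout <- .gat_layer(tape, Hin, edges$src, edges$dst, w, pw, cfg$gcat_meta,
                     n_nodes, cfg$negative_slope, train, cfg$dropout_p)
  u_F <- ad_rowmeans(Hout)
  u_gene <- ad_gather_rows(u_F, gene_idx)
  mu <- ad_mean(u_gene)
  centered <- ad_sub(u_gene, mu)
  varv <- ad_mean(ad_pow(centered, 2))
  u_norm <- ad_div(centered, ad_sqrt(ad_add(varv, cfg$epsilon)))
  u_pred <- ad_softmax_vec(u_norm)
  z1 <- ad_relu(ad_add(ad_matmul(pw[["cls.W1"]], u_norm), pw[["cls.b1"]]))
  logits <- ad_add(ad_matmul(pw[["cls.W2"]], z1), pw[["cls.b2"]])
  list(u_gene = u_gene, u_norm = u_norm, u_pred = u_pred, logits = logits)
}

# Tape-level loss for one cell: KL(u_pred || u_true) + lambda * weighted CE.
.gcat_loss_tape <- function(tape, pw, cfg, fwd, u_true_row, label, class_wt) {
  q <- pmax(as.numeric(u_true_row), 1e-12)
  lse <- ad_logsumexp(fwd$u_norm)
  logp <- ad_sub(fwd$u_norm, lse)
  kl <- ad_sum(ad_mul(fwd$u_pred, ad_sub(logp, matrix(log(q), ncol = 1L))))
  lse_y <- ad_logsumexp(fwd$logits)
  ce <- ad_mul(ad_sub(lse_y, ad_gather_rows(fwd$logits, label)), class_wt)
  ad_add(kl, ad_mul(ce, cfg$lambda))
}

#' Train the cis-regulation simulation model
#'
#' Adam on `KL + lambda * weighted-CE` over the training cells (one step per
#' cell, shuffled each epoch). After each epoch the mean validation KL is
#' computed in evaluation mode; the best-validation parameters are kept and
#' training stops early after `patience` epochs without improvement.
#'
#' @param model an untrained `gcat_model` from [init_gcat()].
#' @param sim_data a `sim_data` bundle from [build_sim_data()].
#' @param split cell split from [split_cells()].
#' @param ssgae a pretrained `ssgae_model` (required unless mode is "wop";
#'   kept frozen).
#' @param epochs maximum epochs (default 50).
#' @param lr Adam learning rate (default 5e-4).
#' @param weight_decay L2 weight decay (default 1e-4).
#' @param seed RNG seed (shuffling, dropout).
#' @param patience early-stopping patience on validation KL (default 10).
#' @return the trained `gcat_model` with per-epoch `metrics` and the
#'   training-set class counts used for loss weighting.
#' @export
train_simulation <- function(model, sim_data, split, ssgae = NULL, epochs = 50,
                             lr = 5e-4, weight_decay = 1e-4, seed = 1L,
                             patience = 10) {
  stopifnot(inherits(model, "gcat_model"), inherits(sim_data, "sim_data"))
  cfg <- model$config
  if (cfg$mode != "wop" && is.null(ssgae))
    stop("modes 'full' and 'posd' require a pretrained ssgae model")
  n_nodes <- sim_data$n_cre + sim_data$n_gene
  labels <- match(sim_data$cell_types, sim_data$type_levels)
  trainval <- c(split$train, split$val)
  class_counts <- tabulate(labels[split$train], nbins = length(sim_data$type_levels))
  if (any(class_counts == 0L)) stop("a cell type has no training cells")
  # u_true from train+val pseudobulk only would require raw RNA here; the
  # profile matrix passed in build_sim_data defines the prior per type.
  H2 <- if (cfg$mode == "wop") NULL else .precompute_h2(ssgae, sim_data)
  params <- model$params
  opt <- adam_init(params, lr = lr, weight_decay = weight_decay)
  set.seed(seed)
  best_val <- Inf; best_params <- params; best_epoch <- 0L; stall <- 0L
  metrics <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_kl = numeric(0))
  val_kl_of <- function(params) {
    if (length(split$val) == 0L) return(NA_real_)
    kls <- vapply(split$val, function(ci) {
      tape <- ad_tape()
      pw <- .wrap_params(tape, params)
      fwd <- .gcat_forward_tape(tape, pw, cfg, sim_data$features[ci, ],
                                if (is.null(H2)) NULL else H2[[ci]],
                                sim_data$edges, n_nodes, sim_data$gene_idx)
      kl_expression_loss(ad_value(fwd$u_pred), sim_data$u_true[labels[ci], ])
    }, 0)
    mean(kls)
  }
  for (ep in seq_len(epochs)) {
    order_cells <- split$train[sample.int(length(split$train))]
    ep_loss <- 0
    for (ci in order_cells) {
      tape <- ad_tape()
      pw <- .wrap_params(tape, params)
      fwd <- .gcat_forward_tape(tape, pw, cfg, sim_data$features[ci, ],
                                if (is.null(H2)) NULL else H2[[ci]],
                                sim_data$edges, n_nodes, sim_data$gene_idx,
                                train = TRUE)
      loss <- .gcat_loss_tape(tape, pw, cfg, fwd,
                              sim_data$u_true[labels[ci], ], labels[ci],
                              1 / class_counts[labels[ci]])
      lv <- as.numeric(ad_value(loss))
      if (!is.finite(lv)) stop("divergent (non-finite) simulation loss at epoch ", ep)
      ep_loss <- ep_loss + lv
      ad_backward(loss)
      upd <- adam_step(opt, params, lapply(pw, ad_grad))
      opt <- upd$state; params <- upd$params
    }
    vk <- val_kl_of(params)
    metrics <- rbind(metrics, data.frame(epoch = ep,
                                         train_loss = ep_loss / length(order_cells),
                                         val_kl = vk))
    if (is.na(vk) || vk < best_val - 1e-9) {
      if (!is.na(vk)) best_val <- vk
      best_params <- params; best_epoch <- ep; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  model$params <- best_params
  model$trained <- TRUE
  model$metrics <- metrics
  model$best_epoch <- best_epoch
  model$class_counts <- class_counts
  model$h2_cache <- H2
  model
}

#' Predict expression distributions and cell types
#'
#' Evaluation-mode forward pass for the requested cells.
#' @param object a trained `gcat_model`.
#' @param sim_data the `sim_data` bundle.
#' @param cells integer cell indices (default: all).
#' @param ssgae the pretrained `ssgae_model` (only needed if the model was
#'   trained in a pretrained mode and no embedding cache is present).
#' @param ... unused.
#' @return list with matrices `u_pred` (cells x genes) and `y_prob`
#'   (cells x types).
#' @export
predict.gcat_model <- function(object, sim_data, cells = NULL, ssgae = NULL, ...) {
  stopifnot(inherits(sim_data, "sim_data"))
  if (is.null(cells)) cells <- seq_along(sim_data$cell_ids)
  cfg <- object$config
  n_nodes <- sim_data$n_cre + sim_data$n_gene
  H2 <- object$h2_cache
  if (cfg$mode != "wop" && is.null(H2)) {
    if (is.null(ssgae)) stop("need ssgae model or cached embeddings")
    H2 <- .precompute_h2(ssgae, sim_data)
  }
  u_pred <- matrix(0, length(cells), cfg$n_genes,
                   dimnames = list(sim_data$cell_ids[cells],
                                   sim_data$graph$genes$gene_id))
  y_prob <- matrix(0, length(cells), cfg$n_types,
                   dimnames = list(sim_data$cell_ids[cells], sim_data$type_levels))
  for (k in seq_along(cells)) {
    ci <- cells[k]
    tape <- ad_tape()
    pw <- .wrap_params(tape, object$params)
    fwd <- .gcat_forward_tape(tape, pw, cfg, sim_data$features[ci, ],
                              if (is.null(H2)) NULL else H2[[ci]],
                              sim_data$edges, n_nodes, sim_data$gene_idx)
    u_pred[k, ] <- as.numeric(ad_value(fwd$u_pred))
    logits <- as.numeric(ad_value(fwd$logits))
    y_prob[k, ] <- exp(logits - max(logits)) / sum(exp(logits - max(logits)))
  }
  list(u_pred = u_pred, y_prob = y_prob)
}
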