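# Integrated-gradients attribution over evidence-edge weights.
#
# Edge weights enter the GCAT layer multiplicatively after attention
# normalization, so scaling all evidence-edge weights along the straight path
# from 0 (baseline) to 1 (input) and integrating the gradient of a gene's
# predicted expression yields a per-edge attribution satisfying completeness.
# Self-loop weights are held at 1 along the path: the path variable scales
# only the candidate cis-regulatory edges. Because the causal mask restricts
# each evidence edge to feed exactly its target gene, the gradient of the
# SUM of gene outputs recovers every edge's attribution with respect to its
# own target gene in a single backward pass (for the pooled target).

#' Integrated gradients over evidence edges for one cell
#'
#' Midpoint-Riemann approximation with `n_steps` of the path integral of
#' gradients from all-zero to all-one evidence-edge weights. The default
#' target `"pooled"` attributes the pre-softmax pooled gene output (linear in
#' the edge weights, so the attribution is exact); `"prob"` attributes the
#' softmax expression probability (nonlinear; one backward pass per gene).
#'
#' @param model a trained `gcat_model`.
#' @param sim_data the `sim_data` bundle.
#' @param cell integer cell index.
#' @param n_steps Riemann steps (>= 4; default 64).
#' @param target `"pooled"` or `"prob"`.
#' @param check_completeness verify `sum(IG) = F(1) - F(0)` per gene and warn
#'   with the measured gap when the relative error exceeds 1%.
#' @return numeric vector of attributions, one per evidence edge (in
#'   `sim_data$graph$edges` order).
#' @export
integrated_gradients_edges <- function(model, sim_data, cell, n_steps = 64,
                                       target = c("pooled", "prob"),
                                       check_completeness = FALSE) {
  target <- match.arg(target)
  if (n_steps < 4) stop("n_steps must be >= 4")
  stopifnot(inherits(model, "gcat_model"), inherits(sim_data, "sim_data"))
  cfg <- model$config
  n_nodes <- sim_data$n_cre + sim_data$n_gene
  ne <- attr(sim_data$edges, "n_evidence")
  H2 <- if (cfg$mode == "wop") NULL else model$h2_cache[[cell]]
  x <- sim_data$features[cell, ]
  edge_dst_gene <- sim_data$edges$dst[seq_len(ne)]
  run_grad <- function(alpha) {
    wv <- matrix(c(rep(alpha, ne), rep(1, n_nodes)), ncol = 1L)
    tape <- ad_tape()
    pw <- .wrap_params(tape, model$params)
    wnode <- ad_var(tape, wv)
    fwd <- .gcat_forward_tape(tape, pw, cfg, x, H2, sim_data$edges, n_nodes,
                              sim_data$gene_idx, wnode = wnode)
    if (target == "pooled") {
      ad_backward(ad_sum(fwd$u_gene))
      as.numeric(ad_grad(wnode))[seq_len(ne)]
    } else {
      g <- numeric(ne)
      for (gg in seq_len(cfg$n_genes)) {
        sel <- which(edge_dst_gene == sim_data$gene_idx[gg])
        if (length(sel) == 0L) next
        ad_backward(ad_gather_rows(fwd$u_pred, gg))
        g[sel] <- as.numeric(ad_grad(wnode))[sel]
      }
      g
    }
  }
  acc <- numeric(ne)
  for (k in seq_len(n_steps)) {
    acc <- acc + run_grad((k - 0.5) / n_steps)
  }
  ig <- acc / n_steps
  if (check_completeness) {
    f_at <- function(alpha) {
      wv <- matrix(c(rep(alpha, ne), rep(1, n_nodes)), ncol = 1L)
      tape <- ad_tape()
      pw <- .wrap_params(tape, model$params)
      fwd <- .gcat_forward_tape(tape, pw, cfg, x, H2, sim_data$edges, n_nodes,
                                sim_data$gene_idx,
                                wnode = ad_var(tape, wv))
      if (target == "pooled") as.numeric(ad_value(fwd$u_gene))
      else as.numeric(ad_value(fwd$u_pred))
    }
    delta <- f_at(1) - f_at(0)
    per_gene <- as.numeric(rowsum(ig, edge_dst_gene - sim_data$n_cre))
    gidx <- sort(unique(edge_dst_gene - sim_data$n_cre))
    gap <- abs(per_gene - delta[gidx])
    rel <- gap / pmax(abs(delta[gidx]), 1e-12)
    if (any(rel > 0.01)) {
      warning(sprintf("IG completeness gap up to %.3g (relative %.3g)",
                      max(gap), max(rel)))
    }
  }
  ig
}

#' Convert attribution vectors to bounded regulation scores
#'
#' Per cell, the attribution vector is divided by its population standard
#' deviation (over all its entries) and squashed with `tanh`, giving scores
#' in `(-1, 1)`. Cells with zero attribution SD get all-zero scores (with a
#' warning). `sd_scope = "global"` uses one SD over the whole matrix instead.
#'
#' @param ig_matrix numeric matrix, cells x evidence edges.
#' @param edge_ids data.frame with columns `cre_id`, `gene_id`.
#' @param cell_ids,cell_types per-row identity labels.
#' @param sd_scope `"per_cell"` (default) or `"global"`.
#' @return a `regulation_scores` object.
#' @export
regulation_scores <- function(ig_matrix, edge_ids, cell_ids, cell_types,
                              sd_scope = c("per_cell", "global")) {
  sd_scope <- match.arg(sd_scope)
  ig <- as.matrix(ig_matrix)
  if (ncol(ig) < 2L) stop("need at least 2 attribution values per cell")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  if (sd_scope == "global") {
    s <- pop_sd(as.numeric(ig))
    if (s == 0) {
      warning("zero attribution SD; all scores set to 0")
      sc <- ig * 0
    } else sc <- tanh(ig / s)
  } else {
    sc <- ig * 0
    zero_rows <- 0L
    for (i in seq_len(nrow(ig))) {
      s <- pop_sd(ig[i, ])
      if (s == 0) zero_rows <- zero_rows + 1L
      else sc[i, ] <- tanh(ig[i, ] / s)
    }
    if (zero_rows > 0L)
      warning(zero_rows, " cell(s) with zero attribution SD; scores set to 0")
  }
  regulation_scores_matrix(sc, edge_ids, cell_ids, cell_types)
}

#' Regulation scores for the test cells
#'
#' Runs [integrated_gradients_edges()] for every test cell of the split and
#' converts the attributions with [regulation_scores()].
#'
#' @param model a trained `gcat_model`.
#' @param sim_data the `sim_data` bundle.
#' @param split cell split from [split_cells()].
#' @param n_steps,target,sd_scope passed through.
#' @return a `regulation_scores` object with one row per test cell.
#' @export
attribute_test_set <- function(model, sim_data, split, n_steps = 64,
                               target = "pooled", sd_scope = "per_cell") {
  cells <- split$test
  ne <- attr(sim_data$edges, "n_evidence")
  ig <- matrix(0, length(cells), ne)
  for (k in seq_along(cells)) {
    ig[k, ] <- integrated_gradients_edges(model, sim_data, cells[k],
                                          n_steps = n_steps, target = target)
  }
  g <- sim_data$graph
  edge_ids <- data.frame(
    cre_id = g$cres$id[g$edges$src],
    gene_id = g$genes$gene_id[g$edges$dst - nrow(g$cres)],
    stringsAsFactors = FALSE)
  regulation_scores(ig, edge_ids, sim_data$cell_ids[cells],
                    sim_data$cell_types[cells], sd_scope = sd_scope)
}

#' Gradient of one gene's pooled output with respect to node features
#'
#' Used to verify the causal-mask guarantee: the gradient is exactly zero for
#' every CRE without an evidence edge into the gene.
#'
#' @param model a trained (or initialized) `gcat_model`.
#' @param sim_data the `sim_data` bundle.
#' @param cell integer cell index.
#' @param gene integer gene index (1-based among gene nodes).
#' @return numeric vector, one gradient entry per node feature.
#' @export
feature_gradients <- function(model, sim_data, cell, gene) {
  cfg <- model$config
  n_nodes <- sim_data$n_cre + sim_data$n_gene
  H2 <- if (cfg$mode == "wop") NULL else model$h2_cache[[cell]]
  tape <- ad_tape()
  pw <- .wrap_params(tape, model$params)
  xnode <- ad_var(tape, matrix(sim_data$features[cell, ], ncol = 1L))
  H1 <- ad_relu(ad_add_rowvec(ad_matmul(xnode, pw[["fe.W"]]), pw[["fe.b"]]))
  Hin <- if (is.null(H2)) H1 else ad_concat_cols(H1, H2)
  Hout <- .gat_layer(tape, Hin, sim_data$edges$src, sim_data$edges$dst,
                     matrix(sim_data$edges$w, ncol = 1L), pw, cfg$gcat_meta,
                     n_nodes, cfg$negative_slope)
  u_F <- ad_rowmeans(Hout)
  u_g <- ad_gather_rows(u_F, sim_data$gene_idx[gene])
  ad_backward(u_g)
  as.numeric(ad_grad(xnode))
}
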