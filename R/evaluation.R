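# Benchmark machinery: matching predicted regulation scores against
# validated cell-type-specific links, rank AUC and AUPR-ratio metrics, and
# distance stratification.
#
# Two complementary views: the cell-level AUC asks whether one cell type's
# scores separate its validated links from the rest; the reg-level AUC asks
# whether one validated link's scores across cell types single out the
# correct type. AUPR is reported as a ratio over the random-predictor
# baseline (the positive prevalence), so values > 1 beat random.

#' Merge cell subtypes under a label mapping
#'
#' @param labels character vector of cell-type labels.
#' @param mapping named character vector `c(old = "new", ...)`; unmapped
#'   labels pass through unchanged.
#' @return character vector of merged labels.
#' @export
merge_subtypes <- function(labels, mapping) {
  hit <- labels %in% names(mapping)
  labels[hit] <- unname(mapping[labels[hit]])
  labels
}

#' Label prediction edges against a validated truth set
#'
#' A prediction edge (CRE c, gene g) is a positive for cell type t iff some
#' truth entry (c', g, t) overlaps c by >= 1 bp with the same gene id; all
#' other evaluated edges are negatives for t. Only edges whose CRE-midpoint
#' to TSS distance is at most `max_dist` are evaluated. Scores are per-type
#' means over cells of that type (set `per_cell = TRUE` to keep per-cell
#' rows).
#'
#' @param scores a `regulation_scores` object.
#' @param truth data.frame with columns chrom, start, end, gene_id,
#'   cell_type and optionally logical `significant` (non-significant tested
#'   pairs count as negatives).
#' @param cres CRE interval table covering the score columns' `cre_id`s.
#' @param genes gene table covering the score columns' `gene_id`s.
#' @param max_dist evaluation window in bp (default 1e6).
#' @param per_cell keep one row per cell instead of per-type means.
#' @return data.frame with columns edge, cre_id, gene_id, distance,
#'   cell_type, label, score (and cell_id when `per_cell`).
#' @export
match_predictions_to_truth <- function(scores, truth, cres, genes,
                                       max_dist = 1e6, per_cell = FALSE) {
  stopifnot(inherits(scores, "regulation_scores"))
  if (!any(scores$edge_ids$gene_id %in% truth$gene_id) &&
      !any(scores$edge_ids$gene_id %in% genes$gene_id))
    stop("empty intersection of gene universes")
  ci <- match(scores$edge_ids$cre_id, cres$id)
  gi <- match(scores$edge_ids$gene_id, genes$gene_id)
  if (anyNA(ci) || anyNA(gi)) stop("edge ids missing from CRE/gene tables")
  mid <- (cres$start[ci] + cres$end[ci]) / 2
  distance <- abs(mid - genes$tss[gi])
  eval_edges <- which(distance <= max_dist)
  if ("significant" %in% names(truth)) truth_pos <- truth[truth$significant, , drop = FALSE]
  else truth_pos <- truth
  # one block per cell type present in the score matrix; types absent from
  # the truth set contribute only negatives
  types <- sort(unique(scores$cell_types))
  pos_key <- character(0)
  if (nrow(truth_pos) > 0L) {
    tr <- data.frame(chrom = truth_pos$chrom, start = truth_pos$start,
                     end = truth_pos$end,
                     id = sprintf("t%06d", seq_len(nrow(truth_pos))),
                     stringsAsFactors = FALSE)
    ce <- cres[ci[eval_edges], , drop = FALSE]
    ce$id <- sprintf("e%06d", seq_along(eval_edges))
    ov <- .overlap_pairs(tr, ce)
    if (nrow(ov) > 0L) {
      same_gene <- scores$edge_ids$gene_id[eval_edges[ov$s]] ==
        truth_pos$gene_id[ov$q]
      pos_key <- unique(paste(eval_edges[ov$s][same_gene],
                              truth_pos$cell_type[ov$q][same_gene]))
    }
  }
  out <- list()
  for (tp in types) {
    if (per_cell) {
      rows <- which(scores$cell_types == tp)
      for (r in rows) {
        out[[length(out) + 1L]] <- data.frame(
          edge = eval_edges,
          cre_id = scores$edge_ids$cre_id[eval_edges],
          gene_id = scores$edge_ids$gene_id[eval_edges],
          distance = distance[eval_edges],
          cell_type = tp, cell_id = scores$cell_ids[r],
          label = as.integer(paste(eval_edges, tp) %in% pos_key),
          score = scores$scores[r, eval_edges],
          stringsAsFactors = FALSE)
      }
    } else {
      rows <- scores$cell_types == tp
      sc <- if (any(rows)) colMeans(scores$scores[rows, eval_edges, drop = FALSE])
      else rep(NA_real_, length(eval_edges))
      out[[length(out) + 1L]] <- data.frame(
        edge = eval_edges,
        cre_id = scores$edge_ids$cre_id[eval_edges],
        gene_id = scores$edge_ids$gene_id[eval_edges],
        distance = distance[eval_edges],
        cell_type = tp,
        label = as.integer(paste(eval_edges, tp) %in% pos_key),
        score = sc,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank-based AUC (Mann-Whitney), ties counting 1/2
#' @param score numeric scores.
#' @param label 0/1 labels (>= 1 of each class).
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(score, label) {
  label <- as.integer(label)
  n1 <- sum(label == 1L); n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) stop("need at least one positive and one negative")
  r <- rank(score)
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve, tie-aware
#'
#' Step-wise integration pooling tied scores: within a tied group precision
#' is evaluated at the group boundary, so a constant predictor scores exactly
#' the positive prevalence.
#' @inheritParams rank_auc
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(score, label) {
  label <- as.integer(label)
  P <- sum(label == 1L)
  if (P == 0L) stop("no positives")
  ord <- order(-score)
  s <- score[ord]; l <- label[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(l, grp, sum)
  n_g <- tapply(l, grp, length)
  tp_cum <- cumsum(tp_g)
  n_cum <- cumsum(n_g)
  prec <- tp_cum / n_cum
  d_rec <- diff(c(0, tp_cum)) / P
  sum(d_rec * prec)
}

#' AUPR ratio over the random-predictor baseline
#'
#' The random predictor's AUPR equals the positive prevalence; values > 1
#' indicate performance above random.
#' @inheritParams rank_auc
#' @return positive scalar.
#' @export
aupr_ratio <- function(score, label) {
  prevalence <- mean(as.integer(label) == 1L)
  aupr(score, label) / prevalence
}

#' Cell-level AUC for one cell type
#'
#' Whether the type's (mean) regulation scores separate its validated links
#' from non-specific ones.
#' @param labeled table from [match_predictions_to_truth()].
#' @param cell_type the cell type to evaluate.
#' @return AUC.
#' @export
cell_level_auc <- function(labeled, cell_type) {
  sub <- labeled[labeled$cell_type == cell_type, , drop = FALSE]
  rank_auc(sub$score, sub$label)
}

#' Reg-level AUC for one validated link
#'
#' Whether the link's scores across cell types single out its validated
#' type(s).
#' @param labeled table from [match_predictions_to_truth()].
#' @param crr edge index (value of the `edge` column).
#' @return AUC.
#' @export
reg_level_auc <- function(labeled, crr) {
  sub <- labeled[labeled$edge == crr, , drop = FALSE]
  rank_auc(sub$score, sub$label)
}

#' Aggregate metric report
#'
#' Per-cell-type cell-level AUC and AUPR ratio, per-validated-link reg-level
#' AUC and AUPR ratio, and their unweighted means.
#' @param labeled table from [match_predictions_to_truth()].
#' @return object of class `metric_report`.
#' @export
metric_report <- function(labeled) {
  types <- sort(unique(labeled$cell_type))
  cell <- lapply(types, function(tp) {
    sub <- labeled[labeled$cell_type == tp, , drop = FALSE]
    if (sum(sub$label) == 0L || sum(sub$label) == nrow(sub))
      return(data.frame(cell_type = tp, auc = NA_real_, aupr_ratio = NA_real_))
    data.frame(cell_type = tp, auc = rank_auc(sub$score, sub$label),
               aupr_ratio = aupr_ratio(sub$score, sub$label))
  })
  cell <- do.call(rbind, cell)
  val_edges <- sort(unique(labeled$edge[labeled$label == 1L]))
  reg <- lapply(val_edges, function(e) {
    sub <- labeled[labeled$edge == e, , drop = FALSE]
    if (sum(sub$label) == 0L || sum(sub$label) == nrow(sub))
      return(data.frame(edge = e, auc = NA_real_, aupr_ratio = NA_real_))
    data.frame(edge = e, auc = rank_auc(sub$score, sub$label),
               aupr_ratio = aupr_ratio(sub$score, sub$label))
  })
  reg <- if (length(reg) > 0L) do.call(rbind, reg) else
    data.frame(edge = integer(0), auc = numeric(0), aupr_ratio = numeric(0))
  structure(list(cell = cell, reg = reg,
                 mean_cell_auc = mean(cell$auc, na.rm = TRUE),
                 mean_cell_aupr_ratio = mean(cell$aupr_ratio, na.rm = TRUE),
                 mean_reg_auc = mean(reg$auc, na.rm = TRUE),
                 mean_reg_aupr_ratio = mean(reg$aupr_ratio, na.rm = TRUE)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("metric_report: mean cell-level AUC %.3f (AUPR ratio %.2f), ",
                     "mean reg-level AUC %.3f (AUPR ratio %.2f)\n"),
              x$mean_cell_auc, x$mean_cell_aupr_ratio,
              x$mean_reg_auc, x$mean_reg_aupr_ratio))
  cat(sprintf("  %d cell types, %d validated links\n",
              nrow(x$cell), nrow(x$reg)))
  invisible(x)
}

#' Metrics stratified by CRE-TSS distance
#'
#' Bins are left-closed; the final bin includes its right edge. Defaults:
#' 0-10 kb, 10-50 kb, 50-100 kb, 100-300 kb, 300 kb-1 Mb.
#' @param labeled table from [match_predictions_to_truth()].
#' @param bins bin boundaries in bp.
#' @return named list of `metric_report`s, one per non-empty bin.
#' @export
stratify_by_distance <- function(labeled,
                                 bins = c(0, 1e4, 5e4, 1e5, 3e5, 1e6)) {
  out <- list()
  for (b in seq_len(length(bins) - 1L)) {
    lo <- bins[b]; hi <- bins[b + 1L]
    keep <- if (b == length(bins) - 1L)
      labeled$distance >= lo & labeled$distance <= hi
    else labeled$distance >= lo & labeled$distance < hi
    if (!any(keep)) next
    nm <- sprintf("[%g,%g%s", lo, hi, if (b == length(bins) - 1L) "]" else ")")
    out[[nm]] <- metric_report(labeled[keep, , drop = FALSE])
  }
  out
}
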