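# Variant interpretation and marker analyses on top of the regulation-score
# matrix, plus a PWM scanner for TF-binding-site prediction in enhancers.

#' Map disease-associated SNPs to CREs
#'
#' SNPs with `pvalue < p_threshold` are intersected with CRE intervals
#' (SNPs are 0-based points occupying one bp).
#' @param snps GWAS table ([read_gwas_table()]).
#' @param cres CRE interval table.
#' @param p_threshold GWAS significance cutoff (default 1e-5, strict `<`).
#' @return data.frame with columns rsid, chrom, pos, pvalue, cre_id.
#' @export
map_snps_to_cres <- function(snps, cres, p_threshold = 1e-5) {
  keep <- snps$pvalue < p_threshold
  snps <- snps[keep, , drop = FALSE]
  if (nrow(snps) == 0L) {
    return(data.frame(rsid = character(0), chrom = character(0),
                      pos = integer(0), pvalue = numeric(0),
                      cre_id = character(0), stringsAsFactors = FALSE))
  }
  sp <- .snp_intervals(snps$chrom, snps$pos)
  ov <- .overlap_pairs(sp, cres)
  data.frame(rsid = snps$rsid[ov$q], chrom = snps$chrom[ov$q],
             pos = snps$pos[ov$q], pvalue = snps$pvalue[ov$q],
             cre_id = cres$id[ov$s], stringsAsFactors = FALSE)
}

#' Per-cell mean regulation score over disease-linked edges
#'
#' @param scores a `regulation_scores` object.
#' @param disease_edges character vector of edge column names
#'   (`"cre::gene"`) or a data.frame with `cre_id`, `gene_id`.
#' @return numeric vector, one mean score per cell.
#' @export
disease_cell_scores <- function(scores, disease_edges) {
  stopifnot(inherits(scores, "regulation_scores"))
  if (is.data.frame(disease_edges))
    disease_edges <- paste0(disease_edges$cre_id, "::", disease_edges$gene_id)
  cols <- which(colnames(scores$scores) %in% disease_edges)
  if (length(cols) == 0L) stop("no disease edges present in score matrix")
  rowMeans(scores$scores[, cols, drop = FALSE])
}

#' Z-scale per-type mean scores across cell types, per CRR
#'
#' Each row (CRR) is centered and scaled by its population SD across cell
#' types; constant rows become zeros with a warning.
#' @param per_type_means matrix, CRRs x cell types.
#' @return Z-scaled matrix of the same shape.
#' @export
scaled_crr_scores <- function(per_type_means) {
  m <- as.matrix(per_type_means)
  out <- m * 0
  n_const <- 0L
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) n_const <- n_const + 1L
    else out[i, ] <- (v - mean(v)) / s
  }
  if (n_const > 0L) warning(n_const, " constant CRR row(s) set to zero")
  out
}

#' Disease-associated CRR table with Z-scaled per-type scores
#'
#' Extracts the score-matrix edges whose CRE carries a disease-associated
#' SNP, averages scores per cell type, and Z-scales each CRR across types.
#' @param scores a `regulation_scores` object.
#' @param snp_cres output of [map_snps_to_cres()].
#' @return list with `edges` (rsid, cre_id, gene_id), `per_type_means` and
#'   `z_scores` matrices (CRRs x cell types).
#' @export
disease_crr_table <- function(scores, snp_cres) {
  stopifnot(inherits(scores, "regulation_scores"))
  hit <- scores$edge_ids$cre_id %in% snp_cres$cre_id
  if (!any(hit)) stop("no CRR involves a disease-associated CRE")
  cols <- which(hit)
  types <- sort(unique(scores$cell_types))
  ptm <- matrix(0, length(cols), length(types),
                dimnames = list(colnames(scores$scores)[cols], types))
  for (k in seq_along(types)) {
    rows <- scores$cell_types == types[k]
    ptm[, k] <- colMeans(scores$scores[rows, cols, drop = FALSE])
  }
  edges <- merge(data.frame(cre_id = scores$edge_ids$cre_id[cols],
                            gene_id = scores$edge_ids$gene_id[cols],
                            stringsAsFactors = FALSE),
                 snp_cres[, c("rsid", "cre_id")], by = "cre_id")
  list(edges = edges[, c("rsid", "cre_id", "gene_id")],
       per_type_means = ptm,
       z_scores = suppressWarnings(scaled_crr_scores(ptm)))
}

#' Cell-type-specific marker CRRs
#'
#' For each CRR and cell type, intra-group distances are pairwise absolute
#' score differences within the type and inter-group distances are pairwise
#' differences between the type's cells and all others. FC is
#' `mean(inter) / mean(intra)`; significance is a one-sided Wilcoxon rank-sum
#' test (inter > intra) with Bonferroni correction over all CRR x type tests.
#'
#' @param scores a `regulation_scores` object (>= 2 cells per type).
#' @param fc_min fold-change threshold (default 1.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.frame with columns edge, cell_type, fc, p, p_adj, marker.
#' @export
marker_crrs <- function(scores, fc_min = 1.5, alpha = 0.05) {
  stopifnot(inherits(scores, "regulation_scores"))
  types <- sort(unique(scores$cell_types))
  singletons <- types[table(scores$cell_types)[types] < 2L]
  if (length(singletons) > 0L) {
    warning("cell types with < 2 cells skipped: ",
            paste(singletons, collapse = ", "))
    types <- setdiff(types, singletons)
  }
  res <- list()
  for (e in seq_len(ncol(scores$scores))) {
    v <- scores$scores[, e]
    for (tp in types) {
      a <- v[scores$cell_types == tp]
      b <- v[scores$cell_types != tp]
      intra <- as.numeric(stats::dist(a))
      inter <- abs(outer(a, b, "-"))
      m_intra <- mean(intra); m_inter <- mean(inter)
      if (m_intra == 0 && m_inter == 0) next  # FC undefined
      fc <- m_inter / m_intra
      p <- suppressWarnings(
        stats::wilcox.test(as.numeric(inter), intra,
                           alternative = "greater")$p.value)
      res[[length(res) + 1L]] <- data.frame(
        edge = colnames(scores$scores)[e], cell_type = tp,
        fc = fc, p = p, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) {
    return(data.frame(edge = character(0), cell_type = character(0),
                      fc = numeric(0), p = numeric(0), p_adj = numeric(0),
                      marker = logical(0)))
  }
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p * nrow(out))   # Bonferroni over all tests
  out$marker <- out$fc > fc_min & out$p_adj < alpha
  out
}

#' Marker genes by fold change and Wilcoxon rank-sum test
#'
#' For each gene and type: FC of mean expression (type vs rest, with a small
#' pseudocount), two-sample Wilcoxon test, Bonferroni correction over all
#' gene x type tests; markers require `fc > fc_min` and `p_adj < alpha`.
#' @param rna a [cell_matrix()] of expression counts.
#' @param fc_min fold-change threshold (default 1.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param pseudocount added to both means (default 1e-9).
#' @return data.frame with columns gene_id, cell_type, fc, p, p_adj, marker.
#' @export
marker_genes_wilcoxon <- function(rna, fc_min = 1.5, alpha = 0.05,
                                  pseudocount = 1e-9) {
  stopifnot(inherits(rna, "cell_matrix"))
  types <- sort(unique(rna$cell_types))
  X <- as.matrix(rna$values)
  res <- list()
  for (tp in types) {
    rows <- rna$cell_types == tp
    for (g in seq_len(ncol(X))) {
      a <- X[rows, g]; b <- X[!rows, g]
      fc <- (mean(a) + pseudocount) / (mean(b) + pseudocount)
      p <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "greater")$p.value)
      res[[length(res) + 1L]] <- data.frame(
        gene_id = rna$feature_ids[g], cell_type = tp, fc = fc, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p * nrow(out))
  out$marker <- out$fc > fc_min & out$p_adj < alpha
  out
}

# Reverse complement of an ACGTN string.
.revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(seq, "")[[1L]]),
                                       collapse = ""))
}

# Log2-odds score matrix from a count/frequency PWM: JASPAR-style 0.8
# pseudocount split uniformly over bases, uniform 0.25 background.
.pwm_logodds <- function(mat, pseudo = 0.8) {
  cs <- colSums(mat)
  p <- sweep(mat + pseudo / 4, 2L, cs + pseudo, "/")
  log2(p / 0.25)
}

# Exact null distribution of the summed column scores for i.i.d. uniform
# background, by dynamic programming on a discretized score grid.
# Returns function(score) -> P(S >= score).
.pwm_pvalue_fun <- function(lo, step = 1e-3) {
  L <- ncol(lo)
  q <- round(lo / step)
  offs <- apply(q, 2L, min)
  span <- sum(apply(q, 2L, max) - offs)
  dist <- c(1, numeric(span))   # prob over shifted integer scores 0..span
  pos <- 0L
  for (j in seq_len(L)) {
    nd <- numeric(span + 1L)
    shifts <- q[, j] - offs[j]
    for (b in 1:4) {
      s <- shifts[b]
      idx <- which(dist > 0)
      nd[idx + s] <- nd[idx + s] + 0.25 * dist[idx]
    }
    dist <- nd
  }
  base <- sum(offs) * step
  cum <- rev(cumsum(rev(dist)))   # P(shifted score >= k)
  # per-column rounding accumulates up to L/2 grid steps of error between a
  # real-valued score and its discretized counterpart; back the query off by
  # that slack so achievable scores equal to the query are always included
  slack <- as.integer(ceiling(L / 2))
  function(score) {
    k <- floor((score - base) / step + 0.5) - slack
    k <- max(0L, min(k, span))
    cum[k + 1L]
  }
}

#' Scan a sequence for PWM matches on both strands
#'
#' Log-odds scoring against a uniform background (JASPAR-style 0.8
#' pseudocount); `N` bases score the column's background expectation.
#' The relative score is `(s - s_min) / (s_max - s_min)`; p-values come from
#' the exact null score distribution over i.i.d. uniform background,
#' enumerated by dynamic programming on a discretized score grid.
#'
#' @param sequence character string over A, C, G, T, N.
#' @param pwm a PWM record from [read_jaspar_pwm()] (or a bare 4 x L matrix).
#' @param rel_score_min minimum relative score to report (default 0.8).
#' @param p_max maximum p-value to report (default 0.05).
#' @return data.frame with columns pos (0-based, forward strand), strand,
#'   rel_score, pvalue; empty when the sequence is shorter than the motif.
#' @export
pwm_scan <- function(sequence, pwm, rel_score_min = 0.8, p_max = 0.05) {
  mat <- if (is.list(pwm)) pwm$matrix else pwm
  lo <- .pwm_logodds(mat)
  L <- ncol(lo)
  empty <- data.frame(pos = integer(0), strand = character(0),
                      rel_score = numeric(0), pvalue = numeric(0),
                      stringsAsFactors = FALSE)
  seq_fwd <- toupper(sequence)
  n <- nchar(seq_fwd)
  if (n < L) return(empty)
  s_min <- sum(apply(lo, 2L, min)); s_max <- sum(apply(lo, 2L, max))
  pfun <- .pwm_pvalue_fun(lo)
  scan_strand <- function(seqchars, strand) {
    nn <- length(seqchars)
    code <- match(seqchars, c("A", "C", "G", "T"))
    colmean <- colMeans(lo)   # background expectation, used for N
    hits <- empty
    for (st in seq_len(nn - L + 1L)) {
      sc <- 0
      for (j in seq_len(L)) {
        b <- code[st + j - 1L]
        sc <- sc + if (is.na(b)) colmean[j] else lo[b, j]
      }
      rel <- (sc - s_min) / (s_max - s_min)
      if (rel >= rel_score_min) {
        pv <- pfun(sc)
        if (pv < p_max) {
          fwd_pos <- if (strand == "+") st - 1L else nn - (st - 1L) - L
          hits <- rbind(hits, data.frame(pos = fwd_pos, strand = strand,
                                         rel_score = rel, pvalue = pv,
                                         stringsAsFactors = FALSE))
        }
      }
    }
    hits
  }
  fw <- scan_strand(strsplit(seq_fwd, "")[[1L]], "+")
  rv <- scan_strand(strsplit(.revcomp(seq_fwd), "")[[1L]], "-")
  out <- rbind(fw, rv)
  out[order(out$pos, out$strand), , drop = FALSE]
}
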