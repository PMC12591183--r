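# Assembly of the empirical-evidence graphs.
#
# Two variants share the machinery: an undirected CRE-CRE graph used for
# autoencoder pretraining, and a directed CRE->gene graph whose edges are the
# candidate cis-regulatory relationships, used by the simulation model under
# a causal attention mask. Edges come from three evidence sources: shared
# promoter windows, chromatin contacts (Hi-C), and eQTL associations.
# "Overlap" is always >= 1 bp intersection of 0-based half-open intervals.

#' Promoter windows around gene TSSs
#'
#' The window spans `up` bp upstream to `down` bp downstream of the TSS,
#' oriented by strand and clipped at coordinate 0. With the default
#' symmetric 2 kb / 2 kb window, strand has no effect.
#'
#' @param genes gene table ([read_gene_table()]).
#' @param up,down window extent in bp (defaults 2000/2000).
#' @return interval data.frame (chrom, start, end, id = gene_id).
#' @export
promoter_regions <- function(genes, up = 2000, down = 2000) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - up, genes$tss - down)
  end <- ifelse(plus, genes$tss + down, genes$tss + up)
  genomic_intervals(data.frame(chrom = genes$chrom,
                               start = pmax(0L, as.integer(start)),
                               end = as.integer(end),
                               id = genes$gene_id,
                               stringsAsFactors = FALSE))
}

# Overlap pairs between two interval tables: data.frame(q, s) of row indices.
.overlap_pairs <- function(query, subject) {
  hits <- GenomicRanges::findOverlaps(.gr(query), .gr(subject))
  data.frame(q = S4Vectors::queryHits(hits), s = S4Vectors::subjectHits(hits))
}

# Interval table for SNP points [pos, pos + 1).
.snp_intervals <- function(chrom, pos) {
  data.frame(chrom = chrom, start = as.integer(pos),
             end = as.integer(pos) + 1L,
             id = sprintf("snp%06d", seq_along(pos)),
             stringsAsFactors = FALSE)
}

# Contact fragments as two interval tables.
.contact_frags <- function(contacts) {
  n <- nrow(contacts)
  list(f1 = data.frame(chrom = contacts$chrom1, start = contacts$start1,
                       end = contacts$end1, id = sprintf("f1_%d", seq_len(n)),
                       stringsAsFactors = FALSE),
       f2 = data.frame(chrom = contacts$chrom2, start = contacts$start2,
                       end = contacts$end2, id = sprintf("f2_%d", seq_len(n)),
                       stringsAsFactors = FALSE))
}

.new_evidence_graph <- function(cres, genes, edges, kind) {
  ord <- order(cres$chrom, cres$start, cres$end, cres$id)
  if (!identical(ord, seq_len(nrow(cres)))) stop("CREs must be coordinate-sorted")
  structure(list(cres = cres, genes = genes, edges = edges, kind = kind),
            class = "evidence_graph")
}

#' Sort CREs deterministically (by coordinate, then id)
#' @param cres interval data.frame.
#' @return sorted interval data.frame.
#' @export
sort_cres <- function(cres) {
  cres <- genomic_intervals(cres)
  out <- cres[order(cres$chrom, cres$start, cres$end, cres$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Merge duplicate (src, dst) edges, unioning provenance labels.
.merge_edges <- function(src, dst, prov) {
  if (length(src) == 0L) {
    return(data.frame(src = integer(0), dst = integer(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  }
  key <- paste(src, dst)
  agg <- tapply(prov, key, function(p) paste(sort(unique(p)), collapse = ","))
  ks <- strsplit(names(agg), " ", fixed = TRUE)
  out <- data.frame(src = as.integer(vapply(ks, `[`, "", 1L)),
                    dst = as.integer(vapply(ks, `[`, "", 2L)),
                    provenance = as.character(agg), stringsAsFactors = FALSE)
  out <- out[order(out$src, out$dst), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the undirected CRE-CRE evidence graph (pretraining)
#'
#' Edges are the union of (a) all pairs of CREs overlapping the same promoter
#' window, (b) for each chromatin contact, the cross product of CREs
#' overlapping fragment 1 with CREs overlapping fragment 2, and (c) for each
#' eQTL, the promoter CREs of its gene crossed with the CRE(s) overlapping
#' the SNP point. Self-edges are dropped; duplicate edges are merged with
#' provenances unioned. Edges are stored once with `src < dst`.
#'
#' @param cres CRE interval table (coordinate-sorted; see [sort_cres()]).
#' @param genes gene table.
#' @param contacts contact pairs ([read_contacts_bedpe()]); may be NULL.
#' @param eqtls eQTL links ([read_eqtl_table()]); may be NULL.
#' @param promoter_up,promoter_down promoter window extent.
#' @return an `evidence_graph` of kind `"cre_cre"`.
#' @export
build_cre_cre_graph <- function(cres, genes, contacts = NULL, eqtls = NULL,
                                promoter_up = 2000, promoter_down = 2000) {
  cres <- sort_cres(cres)
  prom <- promoter_regions(genes, promoter_up, promoter_down)
  src <- integer(0); dst <- integer(0); prov <- character(0)
  # (a) CREs sharing a promoter window
  op <- .overlap_pairs(prom, cres)
  if (nrow(op) > 0L) {
    by_prom <- split(op$s, op$q)
    for (cs in by_prom) {
      if (length(cs) < 2L) next
      pr <- t(utils::combn(sort(cs), 2L))
      src <- c(src, pr[, 1L]); dst <- c(dst, pr[, 2L])
      prov <- c(prov, rep("promoter", nrow(pr)))
    }
  }
  # (b) contacts: CREs in fragment 1 x CREs in fragment 2
  if (!is.null(contacts) && nrow(contacts) > 0L) {
    fr <- .contact_frags(contacts)
    h1 <- .overlap_pairs(fr$f1, cres)
    h2 <- .overlap_pairs(fr$f2, cres)
    j <- merge(h1, h2, by = "q")
    j <- j[j$s.x != j$s.y, , drop = FALSE]
    if (nrow(j) > 0L) {
      src <- c(src, pmin(j$s.x, j$s.y)); dst <- c(dst, pmax(j$s.x, j$s.y))
      prov <- c(prov, rep("hic", nrow(j)))
    }
  }
  # (c) eQTLs: promoter CREs of the gene x CRE overlapping the SNP
  if (!is.null(eqtls) && nrow(eqtls) > 0L) {
    snps <- .snp_intervals(eqtls$snp_chrom, eqtls$snp_pos)
    hs <- .overlap_pairs(snps, cres)
    op2 <- .overlap_pairs(prom, cres)
    prom_of_gene <- split(op2$s, prom$id[op2$q])
    for (r in seq_len(nrow(eqtls))) {
      snp_cres <- hs$s[hs$q == r]
      pcres <- prom_of_gene[[eqtls$gene_id[r]]]
      if (length(snp_cres) == 0L || length(pcres) == 0L) next
      grid <- expand.grid(a = pcres, b = snp_cres)
      grid <- grid[grid$a != grid$b, , drop = FALSE]
      if (nrow(grid) == 0L) next
      src <- c(src, pmin(grid$a, grid$b)); dst <- c(dst, pmax(grid$a, grid$b))
      prov <- c(prov, rep("eqtl", nrow(grid)))
    }
  }
  edges <- .merge_edges(src, dst, prov)
  .new_evidence_graph(cres, genes[0, , drop = FALSE], edges, "cre_cre")
}

#' Build the directed CRE->gene evidence graph (simulation)
#'
#' Candidate cis-regulatory edges from three sources: (a) a CRE overlapping a
#' gene's promoter window; (b) chromatin contacts, applied symmetrically —
#' CREs in either fragment link to genes whose promoter window overlaps the
#' other fragment (set `hic_symmetric = FALSE` for the one-directional rule);
#' (c) eQTLs — the CRE(s) overlapping the SNP link to the associated gene.
#' Gene node indices follow CRE indices: CREs are nodes `1..M`, gene `g` is
#' node `M + g`. Genes with no incident CRE are retained as isolated nodes;
#' their count is attached as attribute `n_isolated_genes` of the edge table.
#'
#' @inheritParams build_cre_cre_graph
#' @param hic_symmetric apply the contact rule in both fragment orders.
#' @return an `evidence_graph` of kind `"cre_gene"`.
#' @export
build_cre_gene_graph <- function(cres, genes, contacts = NULL, eqtls = NULL,
                                 promoter_up = 2000, promoter_down = 2000,
                                 hic_symmetric = TRUE) {
  cres <- sort_cres(cres)
  ncre <- nrow(cres)
  prom <- promoter_regions(genes, promoter_up, promoter_down)
  src <- integer(0); gene <- integer(0); prov <- character(0)
  # (a) CRE inside promoter window
  op <- .overlap_pairs(prom, cres)
  if (nrow(op) > 0L) {
    src <- c(src, op$s); gene <- c(gene, op$q)
    prov <- c(prov, rep("promoter", nrow(op)))
  }
  # (b) contacts
  if (!is.null(contacts) && nrow(contacts) > 0L) {
    fr <- .contact_frags(contacts)
    c1 <- .overlap_pairs(fr$f1, cres); g2 <- .overlap_pairs(fr$f2, prom)
    j <- merge(c1, g2, by = "q")
    if (nrow(j) > 0L) {
      src <- c(src, j$s.x); gene <- c(gene, j$s.y)
      prov <- c(prov, rep("hic", nrow(j)))
    }
    if (hic_symmetric) {
      c2 <- .overlap_pairs(fr$f2, cres); g1 <- .overlap_pairs(fr$f1, prom)
      j2 <- merge(c2, g1, by = "q")
      if (nrow(j2) > 0L) {
        src <- c(src, j2$s.x); gene <- c(gene, j2$s.y)
        prov <- c(prov, rep("hic", nrow(j2)))
      }
    }
  }
  # (c) eQTLs
  if (!is.null(eqtls) && nrow(eqtls) > 0L) {
    snps <- .snp_intervals(eqtls$snp_chrom, eqtls$snp_pos)
    hs <- .overlap_pairs(snps, cres)
    gidx <- match(eqtls$gene_id, genes$gene_id)
    for (r in seq_len(nrow(eqtls))) {
      snp_cres <- hs$s[hs$q == r]
      if (length(snp_cres) == 0L || is.na(gidx[r])) next
      src <- c(src, snp_cres); gene <- c(gene, rep(gidx[r], length(snp_cres)))
      prov <- c(prov, rep("eqtl", length(snp_cres)))
    }
  }
  edges <- .merge_edges(src, ncre + gene, prov)
  attr(edges, "n_isolated_genes") <-
    length(setdiff(seq_len(nrow(genes)) + ncre, edges$dst))
  .new_evidence_graph(cres, genes, edges, "cre_gene")
}

#' @export
print.evidence_graph <- function(x, ...) {
  cat(sprintf("evidence_graph (%s): %d CREs, %d genes, %d edges\n",
              x$kind, nrow(x$cres), nrow(x$genes), nrow(x$edges)))
  if (nrow(x$edges) > 0L) {
    pv <- table(unlist(strsplit(x$edges$provenance, ",")))
    cat("  provenance:", paste(names(pv), pv, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Causal attention mask of a simulation graph
#'
#' `mask[i, j] = 1` iff node `i` is a CRE, node `j` is a gene and the
#' evidence edge i -> j exists, or `i == j` (every node keeps its own state).
#' Attention and gradients therefore never flow gene -> CRE or CRE -> CRE.
#'
#' @param g an `evidence_graph` of kind `"cre_gene"`.
#' @return sparse pattern matrix (nodes x nodes) from the Matrix package.
#' @export
build_causal_mask <- function(g) {
  stopifnot(inherits(g, "evidence_graph"), g$kind == "cre_gene")
  n <- nrow(g$cres) + nrow(g$genes)
  i <- c(g$edges$src, seq_len(n))
  j <- c(g$edges$dst, seq_len(n))
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
}

# Masked directed edge list for the simulation model: evidence CRE->gene
# edges followed by one self-loop per node. The attribute `n_evidence` gives
# how many leading entries are evidence edges (the attributable ones).
sim_graph_edges <- function(g) {
  stopifnot(g$kind == "cre_gene")
  n <- nrow(g$cres) + nrow(g$genes)
  e <- list(src = c(g$edges$src, seq_len(n)),
            dst = c(g$edges$dst, seq_len(n)),
            w = rep(1, nrow(g$edges) + n))
  attr(e, "n_evidence") <- nrow(g$edges)
  e
}

# Symmetric edge list with self-loops for the pretraining CRE-CRE graph.
pretrain_graph_edges <- function(g) {
  stopifnot(g$kind == "cre_cre")
  n <- nrow(g$cres)
  und <- make_undirected_edges(list(src = g$edges$src, dst = g$edges$dst))
  add_self_loops(und, n)
}

#' Overlap between an evidence graph and a validated truth set
#'
#' A truth entry is covered if some evidence edge has >= 1 bp CRE-interval
#' overlap and the same gene id; an evidence edge is "in truth" if it matches
#' some truth entry the same way (cell types are ignored here).
#'
#' @param evidence an `evidence_graph` of kind `"cre_gene"`.
#' @param truth truth-set data.frame with columns chrom, start, end,
#'   gene_id, cell_type.
#' @return list with `frac_truth_covered` and `frac_evidence_in_truth`.
#' @export
evidence_overlap_report <- function(evidence, truth) {
  stopifnot(evidence$kind == "cre_gene")
  if (nrow(truth) == 0L || nrow(evidence$edges) == 0L) {
    return(list(frac_truth_covered = 0, frac_evidence_in_truth = 0))
  }
  tr <- data.frame(chrom = truth$chrom, start = truth$start, end = truth$end,
                   id = sprintf("t%06d", seq_len(nrow(truth))),
                   stringsAsFactors = FALSE)
  ov <- .overlap_pairs(tr, evidence$cres)
  edge_gene <- evidence$genes$gene_id[evidence$edges$dst - nrow(evidence$cres)]
  edge_key <- paste(evidence$edges$src, edge_gene)
  hit_key <- unique(paste(ov$s, truth$gene_id[ov$q]))
  evidence_in_truth <- edge_key %in% hit_key
  covered <- logical(nrow(truth))
  if (nrow(ov) > 0L) {
    cand_key <- paste(ov$s, truth$gene_id[ov$q])
    covered_rows <- ov$q[cand_key %in% edge_key]
    covered[unique(covered_rows)] <- TRUE
  }
  list(frac_truth_covered = mean(covered),
       frac_evidence_in_truth = mean(evidence_in_truth))
}

#' Write an evidence graph as plain-text tables
#'
#' Emits `<prefix>_edges.tsv` (src_id, dst_id, provenance), `<prefix>_cres.bed`
#' and `<prefix>_genes.tsv`.
#' @param g an `evidence_graph`.
#' @param prefix output path prefix.
#' @export
write_evidence_graph <- function(g, prefix) {
  ncre <- nrow(g$cres)
  node_id <- function(i) {
    ifelse(i <= ncre, g$cres$id[pmin(i, ncre)],
           g$genes$gene_id[pmax(i - ncre, 1L)])
  }
  edges <- data.frame(src_id = node_id(g$edges$src),
                      dst_id = node_id(g$edges$dst),
                      provenance = g$edges$provenance,
                      stringsAsFactors = FALSE)
  utils::write.table(edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(g$cres, paste0(prefix, "_cres.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(g$genes, paste0(prefix, "_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
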