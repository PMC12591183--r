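# Synthetic fixtures with planted cis-regulatory ground truth.
#
# The generator lays out genes and CREs on one synthetic chromosome, plants
# cell-type-specific CRE->gene relationships whose CRE-TSS distances span all
# five evaluation bins (0-10 kb up to 0.3-1 Mb), and emits every file the
# pipeline consumes: accessibility and expression count matrices, gene
# models, contact pairs, eQTL links, GWAS SNPs, PWMs, and the truth set.
# Accessibility counts are negative binomial (elevated mean for a CRE active
# in the cell's type); expression is multinomial with gene probabilities
# softmax-proportional to the summed accessibility of the cell's active
# incident CREs, so accessibility causally drives expression through exactly
# the planted edges. Decoy evidence edges use CREs at background
# accessibility in every profiled type — evidence imported from unprofiled
# tissues — and carry no expression effect.

#' Fixture specification with study-condition defaults
#'
#' @param n_cells_per_type cells per cell type (default 70).
#' @param cell_types cell-type labels (default 3 types).
#' @param n_cres total CREs (default 300).
#' @param n_genes genes (default 40).
#' @param n_true_crrs planted cell-type-specific CRRs (default 60).
#' @param n_decoy_edges decoy evidence edges (default 120).
#' @param chrom_length synthetic chromosome length in bp (default 12 Mb).
#' @param effect_size per-accessibility-count contribution to a gene's
#'   expression logit (default 0.4).
#' @param mu_hi,mu_lo negative-binomial accessibility means for active /
#'   background CREs (defaults 5 and 0.3).
#' @param dispersion negative-binomial size parameter (default 2).
#' @param library_size mean expression counts per cell (default 2000).
#' @param seed RNG seed.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_cells_per_type = 70,
                         cell_types = c("TypeA", "TypeB", "TypeC"),
                         n_cres = 300, n_genes = 40, n_true_crrs = 60,
                         n_decoy_edges = 120, chrom_length = 12e6,
                         effect_size = 0.4, mu_hi = 5, mu_lo = 0.3,
                         dispersion = 2, library_size = 2000, seed = 1L) {
  spec <- list(n_cells_per_type = n_cells_per_type, cell_types = cell_types,
               n_cres = n_cres, n_genes = n_genes, n_true_crrs = n_true_crrs,
               n_decoy_edges = n_decoy_edges, chrom_length = chrom_length,
               effect_size = effect_size, mu_hi = mu_hi, mu_lo = mu_lo,
               dispersion = dispersion, library_size = library_size,
               seed = as.integer(seed))
  if (spec$n_cres < spec$n_true_crrs + spec$n_decoy_edges)
    stop("n_cres must cover planted and decoy CREs")
  class(spec) <- "fixture_spec"
  spec
}

# CRE-TSS offsets covering the five evaluation distance bins; 1 kb lands
# inside the promoter window and yields promoter-provenance edges.
.fixture_offsets <- c(1e3, 5e3, 3e4, 7.5e4, 2e5, 6e5)

# Deterministic geometry: gene/CRE layout, planted + decoy edges, evidence
# files, GWAS SNPs, PWMs. Consumes RNG state.
.fixture_geometry <- function(spec) {
  ng <- spec$n_genes
  spacing <- floor((spec$chrom_length - 2e6) / ng)
  tss <- as.integer(1e6 + (seq_len(ng) - 1L) * spacing)
  genes <- data.frame(gene_id = sprintf("gene%02d", seq_len(ng)),
                      chrom = "chrS", tss = tss,
                      strand = rep(c("+", "-"), length.out = ng),
                      stringsAsFactors = FALSE)
  width <- 500L
  place_cre <- function(gene_idx, offset_idx, jitter = 0L) {
    off <- .fixture_offsets[(offset_idx - 1L) %% length(.fixture_offsets) + 1L]
    sgn <- if (offset_idx %% 2L == 0L) 1L else -1L
    pos <- tss[gene_idx] + sgn * off + jitter
    if (pos < 0L || pos + width > spec$chrom_length) pos <- tss[gene_idx] - sgn * off + jitter
    as.integer(pos - width %/% 2L)
  }
  # planted edges: every gene gets one, the first n_true_crrs - ng a second
  k <- seq_len(spec$n_true_crrs)
  p_gene <- (k - 1L) %% ng + 1L
  p_type <- spec$cell_types[(k - 1L) %% length(spec$cell_types) + 1L]
  p_start <- mapply(place_cre, p_gene, k)
  planted_cres <- data.frame(chrom = "chrS", start = p_start,
                             end = p_start + width,
                             id = sprintf("creP%03d", k),
                             stringsAsFactors = FALSE)
  # decoy edges on distinct CREs, offsets >= 5 kb (outside promoter windows)
  dk <- seq_len(spec$n_decoy_edges)
  d_gene <- sample.int(ng, spec$n_decoy_edges, replace = TRUE)
  d_start <- mapply(place_cre, d_gene, dk + 1L,
                    jitter = as.integer(1500 + (dk %% 5L) * 500L))
  decoy_cres <- data.frame(chrom = "chrS", start = d_start,
                           end = d_start + width,
                           id = sprintf("creD%03d", dk),
                           stringsAsFactors = FALSE)
  # background CREs away from promoters
  n_bg <- spec$n_cres - spec$n_true_crrs - spec$n_decoy_edges
  bg_start <- integer(0)
  while (length(bg_start) < n_bg) {
    cand <- as.integer(stats::runif(2L * n_bg, 0, spec$chrom_length - width))
    near_prom <- vapply(cand, function(p) any(abs(p - tss) < 3000), TRUE)
    bg_start <- unique(c(bg_start, cand[!near_prom]))
  }
  bg_start <- bg_start[seq_len(n_bg)]
  bg_cres <- data.frame(chrom = "chrS", start = bg_start,
                        end = bg_start + width,
                        id = sprintf("creB%03d", seq_len(n_bg)),
                        stringsAsFactors = FALSE)
  cres <- rbind(planted_cres, decoy_cres, bg_cres)
  planted <- data.frame(cre_id = planted_cres$id,
                        gene_id = genes$gene_id[p_gene],
                        cell_type = p_type,
                        distance = abs((planted_cres$start + width / 2) -
                                         tss[p_gene]),
                        stringsAsFactors = FALSE)
  decoys <- data.frame(cre_id = decoy_cres$id,
                       gene_id = genes$gene_id[d_gene],
                       distance = abs((decoy_cres$start + width / 2) -
                                        tss[d_gene]),
                       stringsAsFactors = FALSE)
  # evidence files: promoter-range edges arise from position alone; the rest
  # alternate between contact pairs and eQTL links
  all_edges <- rbind(
    data.frame(cre_id = planted$cre_id, gene_id = planted$gene_id,
               gi = p_gene, dist = planted$distance, stringsAsFactors = FALSE),
    data.frame(cre_id = decoys$cre_id, gene_id = decoys$gene_id,
               gi = d_gene, dist = decoys$distance, stringsAsFactors = FALSE))
  cre_lookup <- stats::setNames(seq_len(nrow(cres)), cres$id)
  contacts <- NULL; eqtls <- NULL
  for (r in seq_len(nrow(all_edges))) {
    if (all_edges$dist[r] <= 2000) next   # promoter rule covers it
    ci <- cre_lookup[[all_edges$cre_id[r]]]
    if (r %% 2L == 0L) {
      contacts <- rbind(contacts, data.frame(
        chrom1 = "chrS", start1 = cres$start[ci] - 250L,
        end1 = cres$end[ci] + 250L,
        chrom2 = "chrS", start2 = tss[all_edges$gi[r]] - 500L,
        end2 = tss[all_edges$gi[r]] + 500L,
        tissue = "synthetic", stringsAsFactors = FALSE))
    } else {
      eqtls <- rbind(eqtls, data.frame(
        snp_chrom = "chrS",
        snp_pos = as.integer(cres$start[ci] + width %/% 2L),
        gene_id = all_edges$gene_id[r], tissue = "synthetic",
        stringsAsFactors = FALSE))
    }
  }
  # GWAS: significant SNPs inside the first planted CREs, background SNPs not
  n_sig <- min(10L, nrow(planted_cres))
  gwas <- rbind(
    data.frame(chrom = "chrS",
               pos = as.integer(planted_cres$start[seq_len(n_sig)] + 100L),
               rsid = sprintf("rs%05d", seq_len(n_sig)),
               pvalue = 10^(-stats::runif(n_sig, 6, 10)),
               stringsAsFactors = FALSE),
    data.frame(chrom = "chrS",
               pos = as.integer(stats::runif(10, 0, spec$chrom_length)),
               rsid = sprintf("rs9%04d", 1:10),
               pvalue = stats::runif(10, 0.001, 0.5),
               stringsAsFactors = FALSE))
  pwms <- list(
    list(tf_name = "SYNTF1",
         matrix = matrix(c(8, 0, 0, 0,  0, 8, 0, 0,  0, 0, 8, 0,  0, 0, 0, 8,
                           8, 0, 0, 0,  0, 8, 0, 0), 4L, 6L,
                         dimnames = list(c("A", "C", "G", "T"), NULL))),
    list(tf_name = "SYNTF2",
         matrix = matrix(c(6, 2, 0, 0,  0, 0, 6, 2,  2, 6, 0, 0,  0, 0, 2, 6,
                           6, 0, 2, 0,  0, 6, 0, 2, 3, 3, 1, 1), 4L, 7L,
                         dimnames = list(c("A", "C", "G", "T"), NULL))))
  truth <- data.frame(chrom = "chrS",
                      start = planted_cres$start, end = planted_cres$end,
                      gene_id = planted$gene_id, cell_type = planted$cell_type,
                      significant = TRUE, stringsAsFactors = FALSE)
  list(genes = genes, cres = cres, planted = planted, decoys = decoys,
       contacts = contacts, eqtls = eqtls, gwas = gwas, pwms = pwms,
       truth = truth)
}

# Sample accessibility and expression counts given the geometry and a
# planted-edge -> type assignment. Consumes RNG state.
.sample_fixture_cells <- function(geom, spec, edge_type, cell_prefix = "cell") {
  types <- spec$cell_types
  n_cells <- spec$n_cells_per_type * length(types)
  cell_types <- rep(types, each = spec$n_cells_per_type)
  cell_ids <- sprintf("%s%04d", cell_prefix, seq_len(n_cells))
  cre_ids <- geom$cres$id
  n_cre <- length(cre_ids)
  # per type, which CREs are active (elevated accessibility)
  active_by_type <- lapply(types, function(tp) {
    geom$planted$cre_id[edge_type == tp]
  })
  names(active_by_type) <- types
  atac <- matrix(0L, n_cells, n_cre)
  mu <- matrix(spec$mu_lo, n_cells, n_cre)
  for (tp in types) {
    rows <- cell_types == tp
    cols <- cre_ids %in% active_by_type[[tp]]
    mu[rows, cols] <- spec$mu_hi
  }
  atac[] <- stats::rnbinom(length(mu), size = spec$dispersion, mu = as.numeric(mu))
  # expression: softmax over genes of summed active incident accessibility
  gene_ids <- geom$genes$gene_id
  rna <- matrix(0L, n_cells, length(gene_ids))
  cre_col <- match(geom$planted$cre_id, cre_ids)
  gene_col <- match(geom$planted$gene_id, gene_ids)
  for (i in seq_len(n_cells)) {
    logit <- numeric(length(gene_ids))
    act <- edge_type == cell_types[i]
    if (any(act)) {
      contrib <- spec$effect_size * atac[i, cre_col[act]]
      logit <- logit + as.numeric(
        .segment_rowsum(matrix(contrib, ncol = 1L), gene_col[act],
                        length(gene_ids)))
    }
    p <- exp(logit - max(logit)); p <- p / sum(p)
    size <- stats::rpois(1L, spec$library_size)
    rna[i, ] <- stats::rmultinom(1L, size, p)[, 1L]
  }
  list(atac = cell_matrix(atac, cell_ids, cell_types, cre_ids,
                          feature_table = geom$cres),
       rna = cell_matrix(rna, cell_ids, cell_types, gene_ids))
}

#' Generate a complete fixture with planted ground truth
#'
#' Deterministic for a fixed `spec$seed`: the same spec yields a
#' bit-identical bundle.
#' @param spec a [fixture_spec()].
#' @return list with `atac`, `rna` ([cell_matrix()]s), `genes`, `cres`,
#'   `contacts`, `eqtls`, `gwas`, `pwms`, `truth`, `planted`, `decoys`,
#'   and the `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  geom <- .fixture_geometry(spec)
  cells <- .sample_fixture_cells(geom, spec, geom$planted$cell_type)
  c(geom, cells, list(spec = spec))
}

#' Generate a miniature multi-tissue atlas for pretraining experiments
#'
#' Shares the base fixture's CRE/gene geometry and evidence; each
#' pseudo-tissue re-assigns the planted edges' active types and samples its
#' own cells, emulating accessibility heterogeneity across tissues.
#' @param spec a [fixture_spec()] (its `n_cells_per_type` applies per tissue).
#' @param n_tissues number of pseudo-tissues (default 3).
#' @return list with the shared geometry and `tissues`, a list of
#'   accessibility [cell_matrix()]s.
#' @export
generate_atlas_fixture <- function(spec = fixture_spec(), n_tissues = 3) {
  set.seed(spec$seed)
  geom <- .fixture_geometry(spec)
  tissues <- vector("list", n_tissues)
  for (t in seq_len(n_tissues)) {
    edge_type <- sample(spec$cell_types, nrow(geom$planted), replace = TRUE)
    tissues[[t]] <- .sample_fixture_cells(geom, spec, edge_type,
                                          cell_prefix = sprintf("t%d_cell", t))$atac
  }
  names(tissues) <- sprintf("tissue%d", seq_len(n_tissues))
  c(geom, list(tissues = tissues, spec = spec))
}

#' Write a fixture bundle to disk in the pipeline's input formats
#'
#' Emits Matrix Market + BED/TSV sidecars for both matrices, gene table,
#' BEDPE contacts, eQTL and GWAS TSVs, JASPAR-format PWMs and the truth set.
#' @param fx a fixture from [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(dir, ...)
  Matrix::writeMM(fx$atac$values, pth("atac.mtx"))
  utils::write.table(fx$cres[, c("chrom", "start", "end", "id")],
                     pth("atac_peaks.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(barcode = fx$atac$cell_ids,
                                cell_type = fx$atac$cell_types),
                     pth("atac_cells.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  Matrix::writeMM(fx$rna$values, pth("rna.mtx"))
  writeLines(fx$rna$feature_ids, pth("rna_genes.txt"))
  utils::write.table(data.frame(barcode = fx$rna$cell_ids,
                                cell_type = fx$rna$cell_types),
                     pth("rna_cells.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fx$genes, pth("genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fx$contacts, pth("contacts.bedpe"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(fx$eqtls, pth("eqtls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fx$gwas, pth("gwas.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  con <- file(pth("motifs.jaspar"), "w")
  for (p in fx$pwms) {
    writeLines(sprintf(">%s %s", p$tf_name, p$tf_name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(p$matrix[b, ], collapse = " ")), con)
    }
  }
  close(con)
  utils::write.table(fx$truth, pth("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' Evaluate a score matrix against a fixture's planted truth
#'
#' @param scores a `regulation_scores` object.
#' @param fx a fixture from [generate_fixture()].
#' @param max_dist evaluation window (default 1 Mb).
#' @return a `metric_report` plus the labeled table as attribute `labeled`.
#' @export
fixture_truth_metrics <- function(scores, fx, max_dist = 1e6) {
  labeled <- match_predictions_to_truth(scores, fx$truth, fx$cres, fx$genes,
                                        max_dist = max_dist)
  rep <- metric_report(labeled)
  attr(rep, "labeled") <- labeled
  rep
}
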