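# Readers and writers for every external format the pipeline touches.
#
# Coordinate conventions are strict and uniform: all internal coordinates are
# 0-based half-open (BED convention). SNPs are 0-based points occupying
# [pos, pos + 1). Readers reject malformed or misaligned inputs instead of
# silently truncating.

#' Construct a cell-by-feature count matrix container
#'
#' @param values matrix-like (dense or `Matrix` sparse), rows = cells,
#'   columns = features; non-negative.
#' @param cell_ids,cell_types character vectors aligned to rows.
#' @param feature_ids character vector aligned to columns.
#' @param feature_table optional data.frame of per-feature annotation
#'   (e.g. peak intervals with columns chrom/start/end/id).
#' @return object of class `cell_matrix`.
#' @export
cell_matrix <- function(values, cell_ids, cell_types, feature_ids,
                        feature_table = NULL) {
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (nrow(values) != length(cell_ids))
    stop("cell id count (", length(cell_ids), ") != matrix rows (", nrow(values), ")")
  if (length(cell_types) != length(cell_ids))
    stop("cell_types length != cell_ids length")
  if (ncol(values) != length(feature_ids))
    stop("feature id count (", length(feature_ids), ") != matrix columns (", ncol(values), ")")
  if (any(values@x < 0)) stop("negative counts in cell matrix")
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  rownames(values) <- cell_ids
  colnames(values) <- feature_ids
  structure(list(values = values,
                 cell_ids = as.character(cell_ids),
                 cell_types = as.character(cell_types),
                 feature_ids = as.character(feature_ids),
                 feature_table = feature_table),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d cells x %d features, %d cell types, %.2f%% nonzero\n",
              nrow(x$values), ncol(x$values), length(unique(x$cell_types)),
              100 * length(x$values@x) / prod(dim(x$values))))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$values)

# Subset a cell_matrix by cell and/or feature index.
subset_cells <- function(m, cells = NULL, features = NULL) {
  if (is.null(cells)) cells <- seq_len(nrow(m$values))
  if (is.null(features)) features <- seq_len(ncol(m$values))
  cell_matrix(m$values[cells, features, drop = FALSE],
              m$cell_ids[cells], m$cell_types[cells],
              m$feature_ids[features],
              if (!is.null(m$feature_table)) m$feature_table[features, , drop = FALSE])
}

#' Validate a table of genomic intervals
#'
#' Intervals are 0-based half-open; `start < end` is enforced and ids must be
#' unique within the collection.
#' @param df data.frame with columns chrom, start, end, id.
#' @return the validated data.frame.
#' @export
genomic_intervals <- function(df) {
  need <- c("chrom", "start", "end", "id")
  if (!all(need %in% names(df))) stop("interval table needs columns: ",
                                      paste(need, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(is.na(df$start) | is.na(df$end))) stop("non-integer interval coordinates")
  if (any(df$start < 0)) stop("negative start coordinate")
  if (any(df$start >= df$end)) stop("interval with start >= end")
  if (any(!nzchar(df$chrom))) stop("empty chromosome name")
  if (anyDuplicated(df$id)) stop("duplicate interval ids")
  df[, need]
}

# GRanges view of an interval table (half-open -> 1-based closed shift).
.gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Read a cell-by-feature matrix with sidecar files
#'
#' @param counts_path Matrix Market file (`mtx_triplet`, cells x features) or
#'   dense numeric TSV with a header row (`dense_tsv`).
#' @param features_path BED file of peaks (3-4 columns, no header) or a
#'   one-column id list for genes.
#' @param cells_path TSV with header columns `barcode` and `cell_type`.
#' @param dialect `"mtx_triplet"` or `"dense_tsv"`.
#' @return [cell_matrix()] with peak intervals in `feature_table` when the
#'   feature file is BED.
#' @export
read_cell_matrix <- function(counts_path, features_path, cells_path,
                             dialect = c("mtx_triplet", "dense_tsv")) {
  dialect <- match.arg(dialect)
  cells <- utils::read.delim(cells_path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("barcode", "cell_type") %in% names(cells)))
    stop("cell file ", cells_path, " must have columns barcode, cell_type")
  if (dialect == "mtx_triplet") {
    values <- Matrix::readMM(counts_path)
  } else {
    tab <- utils::read.delim(counts_path, header = TRUE, check.names = FALSE)
    values <- as.matrix(tab)
    if (!is.numeric(values)) stop("non-numeric entries in dense matrix ", counts_path)
  }
  if (any(values < 0)) stop("negative count in ", counts_path)
  first <- readLines(features_path, n = 1L)
  is_bed <- length(strsplit(first, "\t", fixed = TRUE)[[1L]]) >= 3L
  if (is_bed) {
    bed <- utils::read.delim(features_path, header = FALSE, stringsAsFactors = FALSE)
    names(bed)[1:3] <- c("chrom", "start", "end")
    bed$id <- if (ncol(bed) >= 4L) as.character(bed[[4L]]) else
      sprintf("%s:%d-%d", bed$chrom, bed$start, bed$end)
    feature_table <- genomic_intervals(bed)
    feature_ids <- feature_table$id
  } else {
    feature_ids <- readLines(features_path)
    feature_ids <- feature_ids[nzchar(feature_ids)]
    feature_table <- NULL
  }
  if (nrow(values) != nrow(cells))
    stop("cell file ", cells_path, " has ", nrow(cells),
         " rows but matrix has ", nrow(values), " rows")
  if (ncol(values) != length(feature_ids))
    stop("feature file ", features_path, " has ", length(feature_ids),
         " entries but matrix has ", ncol(values), " columns")
  cell_matrix(values, cells$barcode, cells$cell_type, feature_ids, feature_table)
}

#' Read gene models from a TSV table
#'
#' Expects a header with columns `gene_id`, `chrom`, `strand` and either a
#' 0-based `tss` column or 1-based `start`/`end` columns (GTF-derived), in
#' which case the TSS is `start - 1` for `+` genes and `end - 1` for `-`
#' genes. An optional `biotype` column is carried through.
#' @param path TSV path.
#' @return data.frame with columns gene_id, chrom, tss, strand (, biotype).
#' @export
read_gene_table <- function(path) {
  g <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "chrom", "strand") %in% names(g)))
    stop("gene table needs columns gene_id, chrom, strand")
  if (!"tss" %in% names(g)) {
    if (!all(c("start", "end") %in% names(g)))
      stop("gene table needs a tss column or start/end columns")
    g$tss <- ifelse(g$strand == "+", g$start - 1L, g$end - 1L)
  }
  g$tss <- as.integer(g$tss)
  if (any(is.na(g$tss) | g$tss < 0)) stop("invalid TSS coordinates")
  if (anyDuplicated(g$gene_id)) stop("duplicate gene ids")
  if (!all(g$strand %in% c("+", "-"))) stop("strand must be + or -")
  g
}

#' Read chromatin contacts from BEDPE
#'
#' First six tab-separated columns are chrom1, start1, end1, chrom2, start2,
#' end2 (0-based half-open, kept as written); an optional seventh column is a
#' tissue label. Records with `start >= end` on either fragment, or with two
#' identical fragments, are rejected; their count is attached as attribute
#' `n_rejected`.
#' @param path BEDPE path (no header).
#' @return data.frame of contact pairs.
#' @export
read_contacts_bedpe <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 6L) stop("BEDPE ", path, " has ", ncol(x), " columns; need >= 6")
  names(x)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  x$tissue <- if (ncol(x) >= 7L) as.character(x[[7L]]) else NA_character_
  for (cc in c("start1", "end1", "start2", "end2")) {
    x[[cc]] <- as.integer(x[[cc]])
    if (any(is.na(x[[cc]]))) stop("non-integer coordinate in ", path)
  }
  bad <- x$start1 >= x$end1 | x$start2 >= x$end2 |
    (x$chrom1 == x$chrom2 & x$start1 == x$start2 & x$end1 == x$end2)
  out <- x[!bad, c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "tissue")]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Read eQTL links from a TSV table
#'
#' Header columns: `snp_chrom`, `snp_pos` (0-based point), `gene_id`, and
#' optionally `tissue`. Links whose gene id is absent from `genes` are
#' skipped; the skip count is attached as attribute `n_skipped`.
#' @param path TSV path.
#' @param genes gene table ([read_gene_table()]).
#' @return data.frame of eQTL links.
#' @export
read_eqtl_table <- function(path, genes) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("snp_chrom", "snp_pos", "gene_id")
  if (!all(need %in% names(x))) stop("eQTL table needs columns: ",
                                     paste(need, collapse = ", "))
  x$snp_pos <- suppressWarnings(as.integer(x$snp_pos))
  if (any(is.na(x$snp_pos)) || any(x$snp_pos < 0))
    stop("malformed snp_pos in ", path)
  if (!"tissue" %in% names(x)) x$tissue <- NA_character_
  keep <- x$gene_id %in% genes$gene_id
  out <- x[keep, c("snp_chrom", "snp_pos", "gene_id", "tissue")]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Read a GWAS SNP table
#'
#' Header columns: `chrom`, `pos` (0-based point), `rsid`, `pvalue`.
#' @param path TSV path.
#' @return data.frame of SNP records.
#' @export
read_gwas_table <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "rsid", "pvalue")
  if (!all(need %in% names(x))) stop("GWAS table needs columns: ",
                                     paste(need, collapse = ", "))
  x$pos <- as.integer(x$pos)
  if (any(is.na(x$pos) | x$pos < 0)) stop("malformed pos in ", path)
  if (any(!is.finite(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1))
    stop("p-values must lie in (0, 1]")
  x[, need]
}

#' Read position weight matrices in JASPAR text format
#'
#' Records are `>ID NAME` header lines followed by four base rows (A, C, G,
#' T), each like `A [ 4 19 0 ... ]` or plain whitespace-separated counts.
#' @param path JASPAR-format file.
#' @return list of PWMs; each a list with `tf_name` and a 4 x L `matrix`
#'   with rownames A, C, G, T.
#' @export
read_jaspar_pwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) return(list())
  bounds <- c(heads, length(lines) + 1L)
  out <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[k]])
    toks <- strsplit(trimws(hdr), "\\s+")[[1L]]
    name <- if (length(toks) >= 2L) toks[2L] else toks[1L]
    body <- lines[(heads[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(body) != 4L)
      stop("PWM record ", name, " has ", length(body), " base rows; need 4")
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*", "", trimws(ln))
      ln <- gsub("\\[|\\]", " ", ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("PWM record ", name, " has unequal row lengths")
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    if (any(m < 0)) stop("negative PWM entries in ", name)
    if (any(colSums(m) == 0)) stop("all-zero PWM column in ", name)
    out[[k]] <- list(tf_name = name, matrix = m)
  }
  out
}

#' Construct a regulation-score matrix container
#'
#' @param scores numeric matrix, cells x edges, entries in `[-1, 1]`.
#' @param edge_ids data.frame with columns `cre_id`, `gene_id`.
#' @param cell_ids,cell_types character vectors aligned to rows.
#' @return object of class `regulation_scores`.
#' @export
regulation_scores_matrix <- function(scores, edge_ids, cell_ids, cell_types) {
  scores <- as.matrix(scores)
  if (anyNA(scores) || any(!is.finite(scores))) stop("non-finite regulation scores")
  if (any(abs(scores) > 1)) stop("regulation scores must lie in [-1, 1]")
  if (nrow(scores) != length(cell_ids)) stop("cell_ids length != rows")
  if (length(cell_types) != length(cell_ids)) stop("cell_types length != cell_ids")
  if (ncol(scores) != nrow(edge_ids)) stop("edge_ids rows != columns")
  colnames(scores) <- paste0(edge_ids$cre_id, "::", edge_ids$gene_id)
  rownames(scores) <- cell_ids
  structure(list(scores = scores, edge_ids = edge_ids,
                 cell_ids = as.character(cell_ids),
                 cell_types = as.character(cell_types)),
            class = "regulation_scores")
}

#' @export
print.regulation_scores <- function(x, ...) {
  cat(sprintf("regulation_scores: %d cells x %d CRR edges (%d cell types)\n",
              nrow(x$scores), ncol(x$scores), length(unique(x$cell_types))))
  invisible(x)
}

#' Write a regulation-score matrix to TSV
#'
#' Cells as rows, CRR edge ids (`creId::geneId`) as columns, preceded by
#' `cell_id` and `cell_type` columns. Scores are formatted with 6 significant
#' digits; a read/write/read cycle through [read_regulation_matrix()] is
#' bit-identical.
#' @param scores a `regulation_scores` object.
#' @param path output TSV path.
#' @export
write_regulation_matrix <- function(scores, path) {
  stopifnot(inherits(scores, "regulation_scores"))
  if (anyNA(scores$scores)) stop("NaN regulation score")
  df <- data.frame(cell_id = scores$cell_ids, cell_type = scores$cell_types,
                   check.names = FALSE, stringsAsFactors = FALSE)
  sc <- signif(scores$scores, 6L)
  for (j in seq_len(ncol(sc))) df[[colnames(scores$scores)[j]]] <- sc[, j]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a regulation-score matrix written by [write_regulation_matrix()]
#' @param path TSV path.
#' @return a `regulation_scores` object.
#' @export
read_regulation_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  edge_cols <- setdiff(names(df), c("cell_id", "cell_type"))
  sc <- as.matrix(df[, edge_cols, drop = FALSE])
  parts <- strsplit(edge_cols, "::", fixed = TRUE)
  edge_ids <- data.frame(cre_id = vapply(parts, `[`, "", 1L),
                         gene_id = vapply(parts, `[`, "", 2L),
                         stringsAsFactors = FALSE)
  regulation_scores_matrix(sc, edge_ids, df$cell_id, df$cell_type)
}
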