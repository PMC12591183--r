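# Quality control, LSI embedding, neighborhood aggregation, pseudobulk
# profiles and marker-gene selection.
#
# The accessibility workflow mirrors standard scATAC-seq practice: percentile
# QC on per-cell peak counts, per-cell-type peak occurrence filtering, TF-IDF
# + truncated SVD (LSI), and aggregation of each cell with its k nearest
# neighbors to mitigate sparsity.

#' Filter cells by captured-peak percentiles
#'
#' Removes cells whose number of nonzero peaks falls strictly below the
#' `low_pct` percentile or strictly above the `high_pct` percentile of the
#' per-cell nonzero-count distribution (linear-interpolation percentiles).
#'
#' @param m a [cell_matrix()].
#' @param low_pct,high_pct percentile cutoffs (defaults 1 and 99).
#' @return filtered `cell_matrix`; survivor order preserved.
#' @export
filter_cells_by_peak_count <- function(m, low_pct = 1, high_pct = 99) {
  stopifnot(inherits(m, "cell_matrix"))
  if (nrow(m$values) == 0L) stop("empty cell matrix")
  counts <- Matrix::rowSums(m$values > 0)
  lo <- stats::quantile(counts, low_pct / 100, type = 7, names = FALSE)
  hi <- stats::quantile(counts, high_pct / 100, type = 7, names = FALSE)
  keep <- which(counts >= lo & counts <= hi)
  if (length(keep) == 0L) stop("all cells removed by peak-count filter")
  subset_cells(m, cells = keep)
}

#' Filter peaks by per-cell-type occurrence
#'
#' A peak is kept iff, for every cell type, the fraction of that type's cells
#' with nonzero signal is at least `min_frac` (the boundary is inclusive).
#'
#' @param m a [cell_matrix()] with cell types assigned.
#' @param min_frac minimum occurrence fraction within each type (default 0.05).
#' @return filtered `cell_matrix`.
#' @export
filter_peaks_by_occurrence <- function(m, min_frac = 0.05) {
  stopifnot(inherits(m, "cell_matrix"))
  types <- unique(m$cell_types)
  n_per <- table(m$cell_types)
  if (any(n_per == 0L)) stop("cell type with zero cells")
  ind <- m$values > 0
  occ <- matrix(0, length(types), ncol(m$values))
  for (i in seq_along(types)) {
    rows <- m$cell_types == types[i]
    occ[i, ] <- Matrix::colSums(ind[rows, , drop = FALSE]) / sum(rows)
  }
  keep <- which(apply(occ >= min_frac, 2L, all))
  subset_cells(m, features = keep)
}

#' Latent semantic indexing embedding of an accessibility matrix
#'
#' Pipeline: library-size normalization, selection of the top `n_hvf`
#' features by variance (all features if fewer), per-feature scaling to unit
#' variance, TF-IDF weighting with `idf = log(1 + n_cells / doc_freq)`, and
#' truncated SVD to `dims` components. The embedding is `U %*% diag(d)` with
#' each component's sign fixed so its largest-magnitude loading is positive,
#' making the result deterministic.
#'
#' @param m a [cell_matrix()].
#' @param n_hvf number of highly variable features to keep (default 50000).
#' @param dims number of components (default 50).
#' @return list with `coords` (cells x dims), `component_count`, and
#'   `sdev` (singular values), class `lsi_embedding`.
#' @export
lsi_embed <- function(m, n_hvf = 50000, dims = 50) {
  stopifnot(inherits(m, "cell_matrix"))
  n <- nrow(m$values); p <- ncol(m$values)
  if (dims >= min(n, p)) stop("dims (", dims, ") must be < min(cells, features)")
  if (n < dims + 1L || p < dims + 1L) stop("need at least dims + 1 cells and features")
  X <- as.matrix(m$values)
  tot <- rowSums(X)
  tot[tot == 0] <- 1
  Xn <- X / tot * stats::median(rowSums(X))
  v <- apply(Xn, 2L, stats::var)
  ord <- order(v, decreasing = TRUE)
  hvf <- sort(ord[seq_len(min(n_hvf, p))])
  Xh <- Xn[, hvf, drop = FALSE]
  sdv <- apply(Xh, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(Xh, 2L, sdv, "/")
  df <- colSums(X[, hvf, drop = FALSE] > 0)
  df[df == 0] <- 1
  idf <- log(1 + n / df)
  Xt <- sweep(Xs, 2L, idf, "*")
  sv <- svd(Xt, nu = dims, nv = 0L)
  U <- sv$u
  d <- sv$d[seq_len(dims)]
  for (j in seq_len(dims)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  coords <- U * rep(d, each = n)
  rownames(coords) <- m$cell_ids
  structure(list(coords = coords, component_count = dims, sdev = d),
            class = "lsi_embedding")
}

#' Aggregate each cell with its k nearest neighbors
#'
#' Euclidean nearest neighbors in the LSI embedding; each output row is the
#' sum (or mean, with `average = TRUE`) of the cell's own raw counts and its
#' `k` neighbors' raw counts — k + 1 cells in total. Distance ties are broken
#' by cell index.
#'
#' @param m a [cell_matrix()] of raw counts.
#' @param emb an `lsi_embedding` aligned with `m`.
#' @param k number of neighbors (default 10); `k = 0` returns `m` unchanged.
#' @param average average instead of sum.
#' @return aggregated `cell_matrix`.
#' @export
aggregate_neighbors <- function(m, emb, k = 10, average = FALSE) {
  stopifnot(inherits(m, "cell_matrix"), inherits(emb, "lsi_embedding"))
  n <- nrow(m$values)
  if (nrow(emb$coords) != n) stop("embedding rows do not match cell matrix")
  if (k >= n) stop("k must be smaller than the number of cells")
  if (k == 0) return(m)
  D <- as.matrix(stats::dist(emb$coords))
  X <- as.matrix(m$values)
  out <- matrix(0, n, ncol(X))
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    ord <- ord[ord != i]
    nb <- c(i, ord[seq_len(k)])
    out[i, ] <- colSums(X[nb, , drop = FALSE])
  }
  if (average) out <- out / (k + 1)
  cell_matrix(out, m$cell_ids, m$cell_types, m$feature_ids, m$feature_table)
}

#' Pseudobulk expression profiles per cell type
#'
#' Sums raw expression counts over all cells sharing a cell-type label.
#' @param rna a [cell_matrix()] of expression counts.
#' @return object of class `expression_profile` with `values`
#'   (cell types x genes), `cell_types`, `gene_ids`; un-normalized.
#' @export
pseudobulk_profiles <- function(rna) {
  stopifnot(inherits(rna, "cell_matrix"))
  types <- sort(unique(rna$cell_types))
  vals <- matrix(0, length(types), ncol(rna$values),
                 dimnames = list(types, rna$feature_ids))
  for (i in seq_along(types)) {
    rows <- rna$cell_types == types[i]
    vals[i, ] <- Matrix::colSums(rna$values[rows, , drop = FALSE])
  }
  structure(list(values = vals, cell_types = types, gene_ids = rna$feature_ids),
            class = "expression_profile")
}

# Cross-type cosine scores used for marker selection: for gene g and type t,
# c_t = v_t / ||v|| where v is the gene's per-type mean-expression vector;
# the penalized score is c_t^2 / (c_t^2 + mu * (1 - c_t^2)), signed by c_t.
.cosg_scores <- function(type_means, mu = 1) {
  nrm <- sqrt(rowSums(type_means^2))
  nrm[nrm == 0] <- 1
  C <- type_means / nrm   # gene x type cosine with each type indicator
  C2 <- C^2
  S <- C2 / (C2 + mu * (1 - C2))
  S * sign(C)
}

#' Select marker genes per cell type (COSG-style score)
#'
#' For each gene, the cross-type mean-expression vector is compared by cosine
#' similarity with each type's indicator vector; the squared cosine is
#' penalized by the remaining types' share with weight `mu`. The top
#' `n_per_type` genes per type are taken and their union returned,
#' deduplicated, in the input feature order.
#'
#' @param rna a [cell_matrix()] of expression counts (>= 2 cell types).
#' @param n_per_type markers per type (default 300).
#' @param mu penalty weight on expression in other types (default 1).
#' @return character vector of marker gene ids.
#' @export
select_marker_genes <- function(rna, n_per_type = 300, mu = 1) {
  stopifnot(inherits(rna, "cell_matrix"))
  types <- sort(unique(rna$cell_types))
  if (length(types) < 2L) stop("need at least 2 cell types")
  means <- matrix(0, ncol(rna$values), length(types),
                  dimnames = list(rna$feature_ids, types))
  for (i in seq_along(types)) {
    rows <- rna$cell_types == types[i]
    means[, i] <- Matrix::colMeans(rna$values[rows, , drop = FALSE])
  }
  if (n_per_type > nrow(means)) {
    warning("n_per_type exceeds gene count; returning all genes")
    return(rna$feature_ids)
  }
  S <- .cosg_scores(means, mu = mu)
  sel <- character(0)
  for (i in seq_along(types)) {
    ord <- order(-S[, i], rna$feature_ids)
    sel <- c(sel, rna$feature_ids[ord[seq_len(n_per_type)]])
  }
  rna$feature_ids[rna$feature_ids %in% sel]
}

#' Normalize expression profiles over a marker-gene set
#'
#' Restricts columns to `markers` and divides each cell type's row by its
#' sum, so every row sums to 1.
#' @param p an `expression_profile` from [pseudobulk_profiles()].
#' @param markers character vector of gene ids to keep.
#' @return normalized `expression_profile`.
#' @export
normalize_profiles <- function(p, markers) {
  stopifnot(inherits(p, "expression_profile"))
  missing <- setdiff(markers, p$gene_ids)
  if (length(missing) > 0L) stop("markers absent from profile: ",
                                 paste(utils::head(missing, 5L), collapse = ", "))
  vals <- p$values[, markers, drop = FALSE]
  rs <- rowSums(vals)
  if (any(rs == 0)) stop("cell type expresses no marker gene: ",
                         paste(p$cell_types[rs == 0], collapse = ", "))
  structure(list(values = vals / rs, cell_types = p$cell_types,
                 gene_ids = markers),
            class = "expression_profile")
}
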