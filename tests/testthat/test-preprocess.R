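# QC filters, LSI embedding, neighbor aggregation, pseudobulk profiles and
# marker selection.

# cells x peaks matrix in which cell i has exactly i nonzero peaks
staircase_matrix <- function(n_cells = 100, n_peaks = 100) {
  m <- matrix(0, n_cells, n_peaks)
  for (i in seq_len(n_cells)) m[i, seq_len(i)] <- 1
  cell_matrix(m, sprintf("c%03d", seq_len(n_cells)),
              rep(c("A", "B"), length.out = n_cells),
              sprintf("p%03d", seq_len(n_peaks)))
}

test_that("percentile cell filter drops the tails by linear interpolation", {
  m <- staircase_matrix()
  # counts 1..100: 1st percentile = 1.99, 99th = 99.01 -> cells 1, 100 out
  f <- filter_cells_by_peak_count(m, 1, 99)
  expect_equal(nrow(f$values), 98L)
  expect_equal(f$cell_ids, sprintf("c%03d", 2:99))   # order preserved
  # degenerate distribution: nothing removed
  u <- cell_matrix(matrix(1, 10, 4), paste0("c", 1:10), rep("A", 10),
                   paste0("p", 1:4))
  expect_equal(dim(filter_cells_by_peak_count(u)), c(10L, 4L))
  # (0, 100) is the identity
  expect_equal(dim(filter_cells_by_peak_count(m, 0, 100)), dim(m))
  # idempotent on a tied bulk with outlier tails: after one pass the
  # percentile thresholds fall inside the tied mass and nothing else moves
  x2 <- matrix(0, 60, 60)
  counts <- c(1, rep(30, 58), 60)
  for (i in 1:60) x2[i, seq_len(counts[i])] <- 1
  m2 <- cell_matrix(x2, sprintf("d%02d", 1:60), rep("A", 60),
                    sprintf("q%02d", 1:60))
  f2 <- filter_cells_by_peak_count(m2, 5, 95)
  expect_equal(nrow(f2$values), 58L)
  expect_equal(dim(filter_cells_by_peak_count(f2, 5, 95)), dim(f2))
})

test_that("peak occurrence filter requires min_frac in every cell type", {
  # 2 types x 20 cells each (min_frac 0.05 -> at least 1 cell per type)
  types <- rep(c("A", "B"), each = 20)
  m <- matrix(0, 40, 3)
  m[c(1, 2, 21), 1] <- 1   # p1: 10% of A, 5% of B -> kept (boundary incl.)
  m[1:2, 2] <- 1           # p2: 10% of A, 0% of B -> removed
  m[, 3] <- 1              # p3: everywhere -> kept
  cm <- cell_matrix(m, sprintf("c%02d", 1:40), types, c("p1", "p2", "p3"))
  f <- filter_peaks_by_occurrence(cm, 0.05)
  expect_equal(f$feature_ids, c("p1", "p3"))
  # idempotent: removing peaks does not change per-type occurrence
  expect_equal(filter_peaks_by_occurrence(f, 0.05)$feature_ids,
               f$feature_ids)
})

test_that("LSI captures a rank-1 matrix in its first component", {
  set.seed(3)
  u <- runif(30, 1, 2); v <- runif(12, 1, 3)
  m <- cell_matrix(outer(u, v), paste0("c", 1:30), rep("A", 30),
                   paste0("p", 1:12))
  emb <- lsi_embed(m, dims = 5)
  expect_gt(emb$sdev[1]^2 / sum(emb$sdev^2), 0.999)
  # deterministic and equal to a dense SVD oracle on the weighted matrix
  emb_again <- lsi_embed(m, dims = 5)
  expect_identical(emb$coords, emb_again$coords)
  # duplicate cells map to identical embedding rows
  x <- matrix(rpois(20 * 15, 3), 20, 15)
  x[7, ] <- x[3, ]
  m2 <- cell_matrix(x, paste0("c", 1:20), rep("A", 20), paste0("p", 1:15))
  emb2 <- lsi_embed(m2, dims = 4)
  expect_equal(emb2$coords[3, ], emb2$coords[7, ], ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_error(lsi_embed(m2, dims = 60), "dims")
})

test_that("neighbor aggregation equals the brute-force all-pairs oracle", {
  set.seed(4)
  n <- 5
  x <- matrix(rpois(n * 8, 4), n, 8)
  m <- cell_matrix(x, paste0("c", 1:n), rep("A", n), paste0("p", 1:8))
  emb <- lsi_embed(m, dims = 3)
  k <- 2
  agg <- aggregate_neighbors(m, emb, k = k)
  # O(n^2) oracle: full distance matrix, pick k nearest (ties by index)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(emb$coords) - emb$coords[i, ])^2))
    ord <- setdiff(order(d, seq_len(n)), i)[seq_len(k)]
    expect_equal(as.numeric(agg$values[i, ]),
                 colSums(x[c(i, ord), , drop = FALSE]))
  }
  # k = 0 is the identity
  expect_equal(as.matrix(aggregate_neighbors(m, emb, k = 0)$values),
               as.matrix(m$values))
  # two identical cells with k = 1 double each other
  m2 <- cell_matrix(rbind(x[1, ], x[1, ]), c("a", "b"), c("A", "A"),
                    paste0("p", 1:8))
  emb2 <- structure(list(coords = matrix(0, 2, 2), component_count = 2L,
                         sdev = c(1, 1)), class = "lsi_embedding")
  agg2 <- aggregate_neighbors(m2, emb2, k = 1)
  expect_equal(as.numeric(agg2$values[1, ]), 2 * x[1, ])
  expect_error(aggregate_neighbors(m, emb, k = 5), "smaller")
})

test_that("aggregation conserves counts up to neighborhood multiplicity", {
  set.seed(5)
  n <- 12
  x <- matrix(rpois(n * 6, 2), n, 6)
  m <- cell_matrix(x, paste0("c", 1:n), rep("A", n), paste0("p", 1:6))
  emb <- lsi_embed(m, dims = 3)
  k <- 3
  agg <- aggregate_neighbors(m, emb, k = k)
  # recompute in-neighbor degree with the same tie rule
  deg <- integer(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(emb$coords) - emb$coords[i, ])^2))
    nb <- setdiff(order(d, seq_len(n)), i)[seq_len(k)]
    deg[nb] <- deg[nb] + 1L
  }
  expect_equal(sum(agg$values), sum(rowSums(x) * (1 + deg)))
})

test_that("pseudobulk profiles are per-type column sums", {
  x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), 6, 2)
  m <- cell_matrix(x, paste0("c", 1:6), c("A", "B", "A", "B", "C", "C"),
                   c("g1", "g2"))
  p <- pseudobulk_profiles(m)
  expect_equal(p$values["A", ], c(g1 = 1 + 3, g2 = 7 + 9))
  expect_equal(p$values["C", ], c(g1 = 5 + 6, g2 = 11 + 12))
  # permuting cells leaves the profile unchanged
  perm <- c(4, 2, 6, 1, 3, 5)
  m2 <- cell_matrix(x[perm, ], m$cell_ids[perm], m$cell_types[perm],
                    m$feature_ids)
  expect_equal(pseudobulk_profiles(m2)$values, p$values)
})

test_that("marker scores rank genes like the direct formula", {
  set.seed(6)
  n_gene <- 10
  x <- matrix(rpois(30 * n_gene, 2), 30, n_gene)
  x[1:10, 1] <- 50   # gene 1 exclusive to type A
  types <- rep(c("A", "B", "C"), each = 10)
  m <- cell_matrix(x, paste0("c", 1:30), types, sprintf("g%02d", 1:n_gene))
  sel <- select_marker_genes(m, n_per_type = 3)
  expect_true("g01" %in% sel)
  # direct formula oracle: per-type means -> cosine -> penalized score
  means <- sapply(c("A", "B", "C"), function(tp)
    colMeans(x[types == tp, , drop = FALSE]))
  S <- ns$.cosg_scores(means, mu = 1)
  expect_equal(which.max(S[, "A"]), 1L)   # exclusive gene tops type A
  oracle <- character(0)
  for (tp in c("A", "B", "C")) {
    ord <- order(-S[, tp], m$feature_ids)
    oracle <- c(oracle, m$feature_ids[ord[1:3]])
  }
  expect_setequal(sel, unique(oracle))
  # a uniformly expressed gene scores identically across types
  Su <- ns$.cosg_scores(matrix(5, 3, 2, dimnames = list(NULL, c("A", "B"))))
  expect_equal(unname(Su[, 1]), unname(Su[, 2]))
  expect_warning(select_marker_genes(m, n_per_type = 99), "all genes")
})

test_that("profile normalization makes rows sum to one over markers", {
  p <- structure(list(values = matrix(c(2, 1, 2, 3, 0, 4), 2, 3,
                                      dimnames = list(c("A", "B"),
                                                      c("g1", "g2", "g3"))),
                      cell_types = c("A", "B"),
                      gene_ids = c("g1", "g2", "g3")),
                 class = "expression_profile")
  np <- normalize_profiles(p, c("g1", "g2"))
  expect_equal(rowSums(np$values), c(A = 1, B = 1), tolerance = 1e-12)
  expect_equal(np$values["A", ], c(g1 = 0.5, g2 = 0.5))
  # already-normalized rows unchanged
  np2 <- normalize_profiles(np, c("g1", "g2"))
  expect_equal(np2$values, np$values)
  # a type expressing no marker is an error
  p$values["B", c(1, 2)] <- 0
  expect_error(normalize_profiles(p, c("g1", "g2")), "no marker")
})
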