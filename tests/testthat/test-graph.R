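# Evidence-graph assembly vs brute-force interval-overlap oracles, causal
# mask structure, and the evidence/truth overlap report.

# naive >= 1 bp overlap of 0-based half-open intervals
iv_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

test_that("promoter windows follow strand and clip at zero", {
  g <- data.frame(gene_id = c("a", "b", "c"), chrom = "c1",
                  tss = c(10000, 1000, 10000), strand = c("+", "+", "-"))
  p <- promoter_regions(g)
  expect_equal(p$start, c(8000L, 0L, 8000L))
  expect_equal(p$end, c(12000L, 3000L, 12000L))
  # asymmetric window is strand-oriented
  p2 <- promoter_regions(g[3, ], up = 3000, down = 1000)
  expect_equal(c(p2$start, p2$end), c(9000L, 13000L))
})

test_that("CRE-CRE edges match the quadratic rule oracle", {
  inp <- tiny_graph_inputs()
  g <- build_cre_cre_graph(inp$cres, inp$genes, inp$contacts, inp$eqtls)
  cres <- g$cres
  prom <- promoter_regions(inp$genes)
  # brute-force oracle over all CRE pairs
  oracle <- character(0)
  n <- nrow(cres)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    hit <- FALSE
    for (r in seq_len(nrow(prom))) {
      if (iv_overlap(cres$start[i], cres$end[i], prom$start[r], prom$end[r]) &&
          iv_overlap(cres$start[j], cres$end[j], prom$start[r], prom$end[r]))
        hit <- TRUE
    }
    for (r in seq_len(nrow(inp$contacts))) {
      in1 <- iv_overlap(cres$start, cres$end, inp$contacts$start1[r],
                        inp$contacts$end1[r])
      in2 <- iv_overlap(cres$start, cres$end, inp$contacts$start2[r],
                        inp$contacts$end2[r])
      if ((in1[i] && in2[j]) || (in1[j] && in2[i])) hit <- TRUE
    }
    for (r in seq_len(nrow(inp$eqtls))) {
      sp <- inp$eqtls$snp_pos[r]
      snp_hit <- iv_overlap(cres$start, cres$end, sp, sp + 1)
      pr <- prom[prom$id == inp$eqtls$gene_id[r], ]
      in_prom <- iv_overlap(cres$start, cres$end, pr$start, pr$end)
      if ((snp_hit[i] && in_prom[j]) || (snp_hit[j] && in_prom[i])) hit <- TRUE
    }
    if (hit) oracle <- c(oracle, paste(i, j))
  }
  expect_setequal(paste(g$edges$src, g$edges$dst), oracle)
  # two CREs inside one promoter yield a promoter edge
  expect_true(any(grepl("promoter", g$edges$provenance)))
})

test_that("a contact with 2 x 3 fragment CREs yields six edges", {
  cres <- data.frame(chrom = "c1",
                     start = c(100, 300, 5000, 5200, 5400, 9000),
                     end = c(200, 400, 5100, 5300, 5500, 9100),
                     id = paste0("c", 1:6))
  genes <- data.frame(gene_id = "g", chrom = "c1", tss = 50000, strand = "+")
  contacts <- data.frame(chrom1 = "c1", start1 = 0, end1 = 450,
                         chrom2 = "c1", start2 = 4900, end2 = 5600,
                         tissue = NA)
  g <- build_cre_cre_graph(cres, genes, contacts, NULL)
  expect_equal(nrow(g$edges), 6L)
  expect_true(all(g$edges$provenance == "hic"))
})

test_that("CRE->gene edges match the oracle and record provenance", {
  inp <- tiny_graph_inputs()
  g <- build_cre_gene_graph(inp$cres, inp$genes, inp$contacts, inp$eqtls)
  cres <- g$cres
  prom <- promoter_regions(inp$genes)
  ncre <- nrow(cres)
  oracle <- character(0)
  for (i in seq_len(ncre)) for (r in seq_len(nrow(inp$genes))) {
    hit <- FALSE
    if (iv_overlap(cres$start[i], cres$end[i], prom$start[r], prom$end[r]))
      hit <- TRUE
    for (cc in seq_len(nrow(inp$contacts))) {
      c1 <- iv_overlap(cres$start[i], cres$end[i], inp$contacts$start1[cc],
                       inp$contacts$end1[cc])
      c2 <- iv_overlap(cres$start[i], cres$end[i], inp$contacts$start2[cc],
                       inp$contacts$end2[cc])
      p1 <- iv_overlap(prom$start[r], prom$end[r], inp$contacts$start1[cc],
                       inp$contacts$end1[cc])
      p2 <- iv_overlap(prom$start[r], prom$end[r], inp$contacts$start2[cc],
                       inp$contacts$end2[cc])
      if ((c1 && p2) || (c2 && p1)) hit <- TRUE   # symmetric contact rule
    }
    for (ee in seq_len(nrow(inp$eqtls))) {
      sp <- inp$eqtls$snp_pos[ee]
      if (inp$eqtls$gene_id[ee] == inp$genes$gene_id[r] &&
          iv_overlap(cres$start[i], cres$end[i], sp, sp + 1)) hit <- TRUE
    }
    if (hit) oracle <- c(oracle, paste(i, ncre + r))
  }
  expect_setequal(paste(g$edges$src, g$edges$dst), oracle)
  # eQTL rule: the SNP-overlapping CRE links to the gene
  snp_cre <- which(cres$start <= 26200 & 26200 < cres$end)
  gC <- ncre + which(inp$genes$gene_id == "gC")
  expect_true(paste(snp_cre, gC) %in% paste(g$edges$src, g$edges$dst))
  eq <- g$edges[g$edges$src == snp_cre & g$edges$dst == gC, ]
  expect_true(grepl("eqtl", eq$provenance))
})

test_that("edge construction is invariant to input record order", {
  inp <- tiny_graph_inputs()
  g1 <- build_cre_gene_graph(inp$cres, inp$genes, inp$contacts, inp$eqtls)
  perm <- c(4, 1, 6, 3, 2, 5)
  g2 <- build_cre_gene_graph(inp$cres[perm, ], inp$genes,
                             inp$contacts, inp$eqtls)
  expect_identical(g1$edges, g2$edges)
  expect_identical(g1$cres, g2$cres)
})

test_that("causal mask admits only evidence CRE->gene pairs and the diagonal", {
  inp <- tiny_graph_inputs()
  g <- build_cre_gene_graph(inp$cres, inp$genes, inp$contacts, inp$eqtls)
  M <- as.matrix(build_causal_mask(g))
  n <- nrow(M); ncre <- nrow(g$cres)
  expect_equal(diag(M), rep(1, n), ignore_attr = TRUE)
  # gene -> CRE and CRE -> CRE strictly zero off-diagonal
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (i > ncre || j <= ncre) expect_equal(M[i, j], 0)
  }
  # every evidence edge present
  expect_true(all(M[cbind(g$edges$src, g$edges$dst)] == 1))
  # pretraining adjacency is symmetric
  gp <- build_cre_cre_graph(inp$cres, inp$genes, inp$contacts, inp$eqtls)
  ed <- ns$pretrain_graph_edges(gp)
  key <- paste(ed$src, ed$dst)
  expect_true(all(paste(ed$dst, ed$src) %in% key))
})

test_that("isolated genes are retained and counted", {
  cres <- data.frame(chrom = "c1", start = 100, end = 200, id = "c1r")
  genes <- data.frame(gene_id = c("near", "far"), chrom = "c1",
                      tss = c(150, 900000), strand = "+")
  g <- build_cre_gene_graph(cres, genes, NULL, NULL)
  expect_equal(nrow(g$genes), 2L)
  expect_equal(attr(g$edges, "n_isolated_genes"), 1L)
})

test_that("evidence/truth overlap fractions are computed correctly", {
  inp <- tiny_graph_inputs()
  g <- build_cre_gene_graph(inp$cres, inp$genes, inp$contacts, inp$eqtls)
  cres <- g$cres
  ncre <- nrow(cres)
  # truth = a subset of the evidence edges
  sub <- g$edges[1:2, ]
  truth <- data.frame(chrom = "c1", start = cres$start[sub$src],
                      end = cres$end[sub$src],
                      gene_id = g$genes$gene_id[sub$dst - ncre],
                      cell_type = "T1")
  ov <- evidence_overlap_report(g, truth)
  expect_equal(ov$frac_truth_covered, 1)
  expect_equal(ov$frac_evidence_in_truth, 2 / nrow(g$edges))
  # disjoint truth
  far <- data.frame(chrom = "c1", start = 7e5, end = 7e5 + 100,
                    gene_id = "gA", cell_type = "T1")
  ov2 <- evidence_overlap_report(g, far)
  expect_equal(unlist(ov2), c(frac_truth_covered = 0,
                              frac_evidence_in_truth = 0))
})
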