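# Variant-to-CRE mapping, disease score summaries, marker analyses and the
# PWM scanner.

test_that("SNPs map to CREs under the GWAS p-value threshold", {
  cres <- data.frame(chrom = "c1", start = c(100, 500), end = c(200, 600),
                     id = c("a", "b"))
  snps <- data.frame(chrom = "c1", pos = c(150, 550, 150, 900),
                     rsid = paste0("rs", 1:4),
                     pvalue = c(1e-6, 1e-6, 1e-4, 1e-8))
  mp <- map_snps_to_cres(snps, cres)
  expect_equal(mp$rsid, c("rs1", "rs2"))      # rs3 fails p, rs4 outside
  expect_equal(mp$cre_id, c("a", "b"))
  # 8-SNP fixture vs hand count: positions tiling the first CRE
  snps2 <- data.frame(chrom = "c1", pos = seq(96, 208, by = 16),
                      rsid = paste0("s", 1:8), pvalue = 1e-7)
  mp2 <- map_snps_to_cres(snps2, cres)
  expect_equal(nrow(mp2), sum(snps2$pos >= 100 & snps2$pos < 200))
})

test_that("disease cell scores average the disease-linked columns", {
  sc <- regulation_scores_matrix(
    rbind(c(0.2, 0.4, 0.9), c(0, 0, 0)),
    data.frame(cre_id = c("a", "b", "c"), gene_id = c("g1", "g2", "g3")),
    c("x", "y"), c("A", "B"))
  expect_equal(disease_cell_scores(sc, "a::g1"),
               c(x = 0.2, y = 0))
  expect_equal(disease_cell_scores(sc, data.frame(cre_id = c("a", "c"),
                                                  gene_id = c("g1", "g3"))),
               c(x = mean(c(0.2, 0.9)), y = 0))
  expect_error(disease_cell_scores(sc, "zzz::g9"), "no disease edges")
})

test_that("Z-scaling per CRR uses the population SD across types", {
  m <- rbind(c(0, 2), c(3, 3))
  expect_warning(z <- scaled_crr_scores(m), "constant")
  expect_equal(z[1, ], c(-1, 1))            # population SD of (0,2) is 1
  expect_equal(z[2, ], c(0, 0))
  set.seed(18)
  m2 <- matrix(rnorm(12), 3, 4)
  z2 <- scaled_crr_scores(m2)
  for (i in 1:3) {
    expect_lt(abs(mean(z2[i, ])), 1e-9)
    expect_lt(abs(sqrt(mean((z2[i, ] - mean(z2[i, ]))^2)) - 1), 1e-9)
    expect_equal(z2[i, ], (m2[i, ] - mean(m2[i, ])) /
                   sqrt(mean((m2[i, ] - mean(m2[i, ]))^2)))
  }
})

test_that("disease CRR tables join SNPs with score columns", {
  sc <- regulation_scores_matrix(
    rbind(c(0.2, 0.4), c(0.6, 0.1), c(0.3, 0.2), c(0.1, 0.8)),
    data.frame(cre_id = c("a", "b"), gene_id = c("g1", "g2")),
    paste0("cell", 1:4), c("A", "A", "B", "B"))
  snp_cres <- data.frame(rsid = "rs1", chrom = "c1", pos = 150,
                         pvalue = 1e-7, cre_id = "a")
  tab <- disease_crr_table(sc, snp_cres)
  expect_equal(tab$edges$gene_id, "g1")
  expect_equal(unname(tab$per_type_means[1, ]),
               c(mean(c(0.2, 0.6)), mean(c(0.3, 0.1))))
  expect_equal(unname(tab$z_scores[1, ]), c(1, -1))
})

test_that("marker CRRs separate shifted types and skip degenerate cases", {
  set.seed(19)
  # CRR 1: type A shifted well away from B/C; CRR 2: identical everywhere
  n <- 8
  scores <- cbind(c(rnorm(n, 5, 0.01), rnorm(2 * n, 0, 0.01)),
                  rep(0.5, 3 * n))
  sc <- regulation_scores_matrix(
    tanh(scores),
    data.frame(cre_id = c("a", "b"), gene_id = c("g1", "g2")),
    paste0("cell", seq_len(3 * n)),
    rep(c("A", "B", "C"), each = n))
  mk <- marker_crrs(sc)
  row_a <- mk[mk$edge == "a::g1" & mk$cell_type == "A", ]
  expect_true(row_a$marker)
  expect_gt(row_a$fc, 1.5)
  expect_false(any(mk$edge == "b::g2"))     # FC undefined -> skipped
  # brute-force distance check for one (edge, type) pair
  v <- sc$scores[, 1]
  a <- v[1:n]; b <- v[-(1:n)]
  expect_equal(row_a$fc, mean(abs(outer(a, b, "-"))) /
                 mean(abs(outer(a, a, "-")[lower.tri(matrix(0, n, n))])))
})

test_that("permuted labels yield about the nominal false-positive rate", {
  set.seed(20)
  n_crr <- 40
  scores <- matrix(rnorm(30 * n_crr), 30, n_crr)
  sc <- regulation_scores_matrix(
    tanh(scores / 4),
    data.frame(cre_id = sprintf("c%02d", 1:n_crr), gene_id = "g"),
    paste0("cell", 1:30), sample(rep(c("A", "B", "C"), each = 10)))
  mk <- marker_crrs(sc)
  # treating pairwise distances as independent samples makes the test
  # anticonservative, so the raw rate runs somewhat above the nominal 5%;
  # it must still be far from pathological and marker calls must stay rare
  expect_gt(mean(mk$p < 0.05), 0.005)
  expect_lt(mean(mk$p < 0.05), 0.25)
  expect_lt(mean(mk$marker), 0.05)
})

test_that("marker genes require fold change and Wilcoxon significance", {
  set.seed(21)
  n <- 12
  x <- matrix(rpois(3 * n * 3, 5), 3 * n, 3)
  x[1:n, 1] <- rpois(n, 60)      # gene 1 exclusive to type A
  x[, 3] <- 7                    # flat gene
  rna <- cell_matrix(x, paste0("c", seq_len(3 * n)),
                     rep(c("A", "B", "C"), each = n),
                     c("g1", "g2", "g3"))
  mk <- marker_genes_wilcoxon(rna)
  expect_true(mk$marker[mk$gene_id == "g1" & mk$cell_type == "A"])
  expect_false(any(mk$marker[mk$gene_id == "g3"]))
  # p-values equal a direct wilcox.test call
  p_direct <- suppressWarnings(
    wilcox.test(x[1:n, 1], x[-(1:n), 1], alternative = "greater")$p.value)
  expect_equal(mk$p[mk$gene_id == "g1" & mk$cell_type == "A"], p_direct)
})

test_that("PWM scanning matches brute-force scoring on both strands", {
  pwm <- list(tf_name = "T1",
              matrix = matrix(c(8, 0, 0, 0,   # A
                                0, 8, 0, 0,   # C
                                0, 0, 8, 0,   # G
                                0, 0, 0, 8,   # T
                                8, 0, 0, 0,
                                0, 8, 0, 0), 4, 6,
                              dimnames = list(c("A", "C", "G", "T"), NULL)))
  # consensus ACGTAC embedded at 0-based position 10
  seqc <- paste0("GGGGGGGGGG", "ACGTAC", "GGGGGGGGGGGGGG")
  hits <- pwm_scan(seqc, pwm, rel_score_min = 0.8)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$pos, 10L)
  expect_equal(fwd$rel_score, 1)
  # anti-consensus scores 0 relative
  lo <- ns$.pwm_logodds(pwm$matrix)
  anti <- paste(c("T", "G", "C", "A", "T", "G"), collapse = "")
  all_hits <- pwm_scan(anti, pwm, rel_score_min = 0, p_max = 1.01)
  expect_equal(all_hits$rel_score[all_hits$strand == "+"], 0)
  # 30-bp fixture vs brute-force all-offset scoring oracle
  set.seed(22)
  s30 <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
  hits30 <- pwm_scan(s30, pwm, rel_score_min = 0, p_max = 1.01)
  chars <- strsplit(s30, "")[[1]]
  s_min <- sum(apply(lo, 2, min)); s_max <- sum(apply(lo, 2, max))
  for (st in 1:(30 - 6 + 1)) {
    sc <- sum(lo[cbind(match(chars[st:(st + 5)], c("A", "C", "G", "T")),
                       1:6)])
    rel <- (sc - s_min) / (s_max - s_min)
    got <- hits30$rel_score[hits30$strand == "+" & hits30$pos == st - 1]
    expect_equal(got, rel, tolerance = 1e-12)
  }
  # strand symmetry: forward hits on s equal reverse hits on revcomp(s)
  rc <- ns$.revcomp(s30)
  h_fwd <- pwm_scan(s30, pwm, rel_score_min = 0, p_max = 1.01)
  h_rc <- pwm_scan(rc, pwm, rel_score_min = 0, p_max = 1.01)
  f <- sort(h_fwd$rel_score[h_fwd$strand == "+"])
  r <- sort(h_rc$rel_score[h_rc$strand == "-"])
  expect_equal(f, r, tolerance = 1e-12)
  # sequence shorter than the motif -> empty
  expect_equal(nrow(pwm_scan("ACG", pwm)), 0L)
})

test_that("PWM p-values match the exact enumeration on a short motif", {
  pwm <- matrix(c(4, 0, 0, 0,
                  0, 2, 2, 0,
                  1, 1, 1, 1), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  lo <- ns$.pwm_logodds(pwm)
  pfun <- ns$.pwm_pvalue_fun(lo)
  # enumerate all 4^3 background words
  words <- expand.grid(b1 = 1:4, b2 = 1:4, b3 = 1:4)
  all_scores <- apply(words, 1, function(w) sum(lo[cbind(w, 1:3)]))
  for (q in quantile(all_scores, c(0.1, 0.5, 0.9))) {
    expect_equal(pfun(q), mean(all_scores >= q - 1e-9), tolerance = 1e-3)
  }
})
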