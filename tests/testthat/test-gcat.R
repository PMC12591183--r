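# Cis-regulation simulation model: gene-feature initialization, loss
# functions, splits, the causal-mask guarantee and training behavior.

test_that("gene features come from the nearest CRE with the tie rule", {
  cres <- data.frame(chrom = "c1", start = c(100, 900, 2000),
                     end = c(200, 1000, 2100), id = c("a", "b", "c"))
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "c1",
                      tss = c(150, 1500, 2050), strand = "+")
  # g1's TSS inside CRE a; g2 equidistant (550) from b and c midpoints ->
  # lower start coordinate wins; g3 inside c
  idx <- nearest_cre_index(cres, genes)
  expect_equal(idx, c(1L, 2L, 3L))
  acc <- c(5, 7, 9)
  expect_equal(init_gene_features(acc, cres, genes), c(5, 7, 9))
  # brute-force check on a random fixture
  set.seed(11)
  cres2 <- data.frame(chrom = "c1", start = sort(sample.int(1e5, 12)),
                      end = 0, id = paste0("r", 1:12))
  cres2$end <- cres2$start + 100L
  genes2 <- data.frame(gene_id = paste0("g", 1:5), chrom = "c1",
                       tss = sample.int(1e5, 5), strand = "+")
  idx2 <- nearest_cre_index(cres2, genes2)
  mid <- (cres2$start + cres2$end) / 2
  for (g in 1:5) {
    d <- abs(mid - genes2$tss[g])
    expect_equal(d[idx2[g]], min(d))
  }
  genes3 <- data.frame(gene_id = "gX", chrom = "c9", tss = 5, strand = "+")
  expect_error(nearest_cre_index(cres, genes3), "without CREs")
})

test_that("gene-vector standardization and softmax behave analytically", {
  expect_equal(normalize_gene_vector(rep(3, 5)), rep(0, 5))
  expect_equal(normalize_gene_vector(c(0, 2), epsilon = 0), c(-1, 1))
  # epsilon > 0 strictly shrinks magnitudes
  expect_true(all(abs(normalize_gene_vector(c(0, 2), 1e-3)) <
                    abs(normalize_gene_vector(c(0, 2), 0))))
  p <- expression_distribution(rep(1.3, 7))
  expect_equal(p, rep(1 / 7, 7))
  x <- c(0.3, -1, 2, 0.5)
  expect_equal(expression_distribution(x), expression_distribution(x + 5),
               tolerance = 1e-12)
  expect_equal(expression_distribution(x), exp(x) / sum(exp(x)),
               tolerance = 1e-12)
  expect_equal(sum(expression_distribution(rnorm(50))), 1, tolerance = 1e-12)
})

test_that("expression KL loss matches direct arithmetic and is nonnegative", {
  p <- c(0.2, 0.5, 0.3)
  expect_equal(kl_expression_loss(p, p), 0, tolerance = 1e-12)
  expect_equal(kl_expression_loss(c(0.5, 0.5), c(0.75, 0.25)),
               0.5 * log(0.5 / 0.75) + 0.5 * log(0.5 / 0.25),
               tolerance = 1e-9)
  set.seed(12)
  for (i in 1:20) {
    a <- expression_distribution(rnorm(6)); b <- expression_distribution(rnorm(6))
    expect_gte(kl_expression_loss(a, b), 0)
  }
  # zero predicted entries contribute nothing
  expect_equal(kl_expression_loss(c(0, 1), c(0.5, 0.5)), log(1 / 0.5))
  expect_error(kl_expression_loss(c(0.5, 0.5), c(1, 0, 0)), "length")
})

test_that("class-balanced cross-entropy matches its closed forms", {
  # perfect one-hot predictions
  y <- rbind(c(1, 0), c(0, 1))
  expect_equal(celltype_loss(y, c(1L, 2L), c(1L, 1L)), 0)
  # uniform predictions over C classes: mean over cells of (1/N_c) log C
  y2 <- matrix(1 / 3, 4, 3)
  counts <- c(2L, 1L, 1L)
  labels <- c(1L, 1L, 2L, 3L)
  expect_equal(celltype_loss(y2, labels, counts),
               mean(1 / counts[labels]) * log(3), tolerance = 1e-12)
  # doubling every class count halves the loss
  expect_equal(celltype_loss(y2, labels, 2L * counts),
               celltype_loss(y2, labels, counts) / 2, tolerance = 1e-12)
  expect_warning(celltype_loss(rbind(c(0, 1)), 1L, 1L), "clamping")
  # lambda combination
  expect_equal(total_loss(0.5, 0.25, lambda = 0), 0.5)
  expect_equal(total_loss(0.5, 0.25, lambda = 1), 0.75)
  expect_equal(total_loss(0.5, 0.25, lambda = 2), 1.0)
})

test_that("cell splits are stratified 50/10/40 and seed-dependent", {
  types <- rep(c("A", "B"), each = 50)
  sp <- split_cells(types, seed = 3)
  expect_length(sp$train, 50L)
  expect_length(sp$val, 10L)
  expect_length(sp$test, 40L)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:100)
  for (tp in c("A", "B")) {
    expect_equal(sum(types[sp$train] == tp), 25L)
    expect_equal(sum(types[sp$val] == tp), 5L)
  }
  # uneven types: proportions preserved within one cell
  types2 <- c(rep("A", 37), rep("B", 21))
  sp2 <- split_cells(types2, seed = 3)
  expect_lte(abs(sum(types2[sp2$train] == "A") - 0.5 * 37), 1)
  expect_false(identical(split_cells(types, seed = 4)$train, sp$train))
})

test_that("the causal mask blocks gradients from non-evidence CREs", {
  tt <- tiny_trained_model()
  sim <- tt$sim_data
  g <- tt$graph
  ncre <- sim$n_cre
  cell <- tt$split$test[1]
  for (gi in c(1L, 2L)) {
    grad <- feature_gradients(tt$model, sim, cell, gi)
    linked <- g$edges$src[g$edges$dst == ncre + gi]
    unlinked_cres <- setdiff(seq_len(ncre), linked)
    expect_true(all(grad[unlinked_cres] == 0))         # exactly zero
    # gene self-features and other genes: only the gene's own node passes
    other_genes <- setdiff(seq_len(sim$n_gene), gi)
    expect_true(all(grad[ncre + other_genes] == 0))
    if (length(linked) > 0) expect_gt(max(abs(grad[linked])), 0)
  }
})

test_that("the simulation forward matches a dense masked-attention oracle", {
  tt <- tiny_trained_model()
  sim <- tt$sim_data
  cfg <- tt$model$config
  n <- sim$n_cre + sim$n_gene
  cell <- tt$split$test[2]
  # package forward
  tape <- ns$ad_tape()
  pw <- ns$.wrap_params(tape, tt$model$params)
  fwd <- ns$.gcat_forward_tape(tape, pw, cfg, sim$features[cell, ], NULL,
                               sim$edges, n, sim$gene_idx)
  # dense oracle: H1 by hand, dense GAT on the masked adjacency
  H1 <- pmax(matrix(sim$features[cell, ], ncol = 1) %*%
               tt$model$params[["fe.W"]] +
               matrix(tt$model$params[["fe.b"]],
                      n, cfg$hidden_dim, byrow = TRUE), 0)
  adj <- matrix(0, n, n)
  adj[cbind(sim$edges$dst, sim$edges$src)] <- sim$edges$w
  gcat_params <- tt$model$params[grep("^gcat", names(tt$model$params))]
  attr(gcat_params, "meta") <- cfg$gcat_meta
  Hout <- dense_gat_oracle(H1, adj, gcat_params)
  u_gene <- rowMeans(Hout)[sim$gene_idx]
  expect_equal(as.numeric(ns$ad_value(fwd$u_gene)), u_gene,
               tolerance = 1e-8)
  expect_equal(as.numeric(ns$ad_value(fwd$u_pred)),
               expression_distribution(normalize_gene_vector(u_gene,
                                                             cfg$epsilon)),
               tolerance = 1e-8)
  expect_equal(sum(ns$ad_value(fwd$u_pred)), 1, tolerance = 1e-6)
  expect_lt(abs(mean(ns$ad_value(fwd$u_norm))), 1e-6)
})

test_that("perturbing a linked CRE changes its gene; unlinked does not", {
  tt <- tiny_trained_model()
  sim <- tt$sim_data
  cell <- tt$split$test[1]
  g <- tt$graph
  ncre <- sim$n_cre
  gi <- which(tabulate(g$edges$dst - ncre, sim$n_gene) > 0)[1]
  linked <- g$edges$src[g$edges$dst == ncre + gi][1]
  unlinked <- setdiff(seq_len(ncre), g$edges$src[g$edges$dst == ncre + gi])[1]
  base <- predict(tt$model, sim, cells = cell)$u_pred
  bump <- function(node) {
    sim2 <- sim
    sim2$features[cell, node] <- sim2$features[cell, node] + 1
    predict(tt$model, sim2, cells = cell)$u_pred
  }
  expect_gt(abs(bump(linked)[1, gi] - base[1, gi]), 0)
  # u_gene of gi is untouched by the unlinked CRE (softmax renormalizes all
  # entries, so compare the raw pooled outputs via gradients instead)
  grad <- feature_gradients(tt$model, sim, cell, gi)
  expect_equal(grad[unlinked], 0)
})

test_that("training improves test-cell KL and keeps the best-val checkpoint", {
  tt <- tiny_trained_model()
  sim <- tt$sim_data
  labels <- match(sim$cell_types, sim$type_levels)
  kl_of <- function(model) {
    pr <- predict(model, sim, cells = tt$split$test)
    mean(vapply(seq_along(tt$split$test), function(k) {
      kl_expression_loss(pr$u_pred[k, ],
                         sim$u_true[labels[tt$split$test[k]], ])
    }, 0))
  }
  untrained <- init_gcat(sim$n_gene, length(sim$type_levels), mode = "wop",
                         seed = 9)
  expect_lt(kl_of(tt$model), kl_of(untrained))
  # best-val selection: recorded best epoch has the minimum validation KL
  m <- tt$model$metrics
  expect_equal(m$epoch[which.min(m$val_kl)], tt$model$best_epoch)
  expect_lte(min(m$val_kl), m$val_kl[nrow(m)])
  # wop mode trained without any pretrained checkpoint
  expect_equal(tt$model$config$mode, "wop")
  expect_error(
    train_simulation(init_gcat(sim$n_gene, 3, mode = "full"), sim, tt$split),
    "require")
})
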