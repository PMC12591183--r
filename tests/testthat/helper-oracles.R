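# Shared fixtures and independent oracles used across test files.

ns <- asNamespace("screg")

# Dense brute-force GAT layer: materializes the full attention matrix.
# adj: n x n numeric edge-weight matrix (0 = no edge); params from gat_init().
dense_gat_oracle <- function(H, adj, params, negative_slope = 0.2) {
  meta <- attr(params, "meta")
  n <- nrow(H)
  heads_out <- vector("list", meta$heads)
  for (h in seq_len(meta$heads)) {
    W1 <- params[[sprintf("%s.W1.%d", meta$prefix, h)]]
    W2 <- params[[sprintf("%s.W2.%d", meta$prefix, h)]]
    a1 <- params[[sprintf("%s.a1.%d", meta$prefix, h)]]
    a2 <- params[[sprintf("%s.a2.%d", meta$prefix, h)]]
    HW1 <- H %*% W1
    HW2 <- H %*% W2
    logits <- matrix(-Inf, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] != 0) {
          z <- sum(a1 * HW2[i, ]) + sum(a2 * HW2[j, ])
          logits[i, j] <- if (z > 0) z else negative_slope * z
        }
      }
    }
    alpha <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- which(is.finite(logits[i, ]))
      e <- exp(logits[i, nb] - max(logits[i, nb]))
      alpha[i, nb] <- e / sum(e)
    }
    out <- matrix(0, n, ncol(W1))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] != 0) out[i, ] <- out[i, ] + adj[i, j] * alpha[i, j] * HW1[j, ]
      }
    }
    heads_out[[h]] <- out
  }
  if (meta$concat) do.call(cbind, heads_out)
  else Reduce(`+`, heads_out) / meta$heads
}

# Edge list (src -> dst receives) from a dense weight matrix adj[dst, src].
edges_from_adj <- function(adj) {
  idx <- which(adj != 0, arr.ind = TRUE)
  list(src = as.integer(idx[, 2L]), dst = as.integer(idx[, 1L]),
       w = adj[idx])
}

# Brute-force AUC by pair counting (ties count 1/2).
pair_count_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Small deterministic evidence-graph fixture used by graph and gcat tests:
# 6 CREs and 3 genes on one chromosome, with promoter, contact and eQTL
# evidence.
tiny_graph_inputs <- function() {
  cres <- data.frame(chrom = "c1",
                     start = c(500, 2000, 9000, 20000, 26000, 41000),
                     end = c(1000, 2500, 9500, 20500, 26500, 41500),
                     id = sprintf("cre%d", 1:6), stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "c1",
                      tss = c(800, 21000, 40000), strand = c("+", "-", "+"),
                      stringsAsFactors = FALSE)
  contacts <- data.frame(chrom1 = "c1", start1 = 8800, end1 = 9700,
                         chrom2 = "c1", start2 = 20400, end2 = 21500,
                         tissue = "t1", stringsAsFactors = FALSE)
  eqtls <- data.frame(snp_chrom = "c1", snp_pos = 26200, gene_id = "gC",
                      tissue = "t1", stringsAsFactors = FALSE)
  list(cres = cres, genes = genes, contacts = contacts, eqtls = eqtls)
}

# Small trained simulation setup shared by gcat/attribution tests.
# Cached so several test files reuse one short training run.
tiny_trained_cache <- new.env(parent = emptyenv())
tiny_trained_model <- function() {
  if (!is.null(tiny_trained_cache$res)) return(tiny_trained_cache$res)
  spec <- fixture_spec(n_cells_per_type = 10, n_cres = 40, n_genes = 8,
                       n_true_crrs = 12, n_decoy_edges = 16, seed = 21)
  fx <- generate_fixture(spec)
  atac <- filter_peaks_by_occurrence(fx$atac, 0.0001)
  genes <- fx$genes
  graph <- build_cre_gene_graph(fx$cres, genes, fx$contacts, fx$eqtls)
  profiles <- normalize_profiles(pseudobulk_profiles(fx$rna), genes$gene_id)
  sim_data <- build_sim_data(fx$atac, graph, profiles)
  split <- split_cells(sim_data$cell_types, seed = 4)
  model <- init_gcat(sim_data$n_gene, length(sim_data$type_levels),
                     mode = "wop", seed = 9)
  trained <- train_simulation(model, sim_data, split, epochs = 6, seed = 5)
  tiny_trained_cache$res <- list(fx = fx, graph = graph, sim_data = sim_data,
                                 split = split, model = trained)
  tiny_trained_cache$res
}
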