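# End-to-end orchestration: preprocess -> evidence graphs -> (optional)
# autoencoder pretraining -> simulation training -> attribution ->
# evaluation, with stage caching and a reproducibility manifest.

#' Default pipeline configuration
#'
#' Nested list of every tunable the pipeline exposes; unknown keys passed to
#' [run_pipeline()] are rejected up front.
#' @return named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    mode = "full",                       # full | posd | wop
    qc = list(low_pct = 1, high_pct = 99, min_peak_frac = 0.05),
    lsi = list(dims = 50, n_hvf = 50000, drop_first = FALSE),
    knn = list(k = 10, average = FALSE),
    markers = list(n_per_type = 300, mu = 1),
    split = list(fractions = c(0.5, 0.1, 0.4)),
    pretrain = list(epochs = 5, lr = 1e-4, weight_decay = 1e-4,
                    gamma = 2, mask_ratio = 0.5, dropout_p = 0.5),
    train = list(epochs = 50, lr = 5e-4, weight_decay = 1e-4,
                 lambda = 1, patience = 10, dropout_p = 0.5),
    attribution = list(steps = 64, target = "pooled", sd_scope = "per_cell"),
    evaluation = list(max_dist = 1e6, bins = c(0, 1e4, 5e4, 1e5, 3e5, 1e6)),
    hic_symmetric = TRUE
  )
}

# Merge a partial config over the defaults, rejecting unknown keys.
.merge_config <- function(config, defaults = default_config(), path = "") {
  if (is.null(config)) return(defaults)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .merge_config(config[[nm]], defaults[[nm]],
                                      paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- config[[nm]]
    }
  }
  defaults
}

#' Load a fixture directory written by [write_fixture()]
#' @param dir directory path.
#' @return list in the same shape as [generate_fixture()] output (without
#'   `planted`/`decoys`).
#' @export
load_fixture_dir <- function(dir) {
  pth <- function(...) file.path(dir, ...)
  genes <- read_gene_table(pth("genes.tsv"))
  atac <- read_cell_matrix(pth("atac.mtx"), pth("atac_peaks.bed"),
                           pth("atac_cells.tsv"), "mtx_triplet")
  rna <- read_cell_matrix(pth("rna.mtx"), pth("rna_genes.txt"),
                          pth("rna_cells.tsv"), "mtx_triplet")
  truth <- if (file.exists(pth("truth.tsv")))
    utils::read.delim(pth("truth.tsv"), stringsAsFactors = FALSE) else NULL
  list(atac = atac, rna = rna, genes = genes,
       cres = atac$feature_table,
       contacts = read_contacts_bedpe(pth("contacts.bedpe")),
       eqtls = read_eqtl_table(pth("eqtls.tsv"), genes),
       gwas = if (file.exists(pth("gwas.tsv"))) read_gwas_table(pth("gwas.tsv")),
       pwms = if (file.exists(pth("motifs.jaspar"))) read_jaspar_pwm(pth("motifs.jaspar")),
       truth = truth)
}

# Run one cached stage: load `file` if present, else compute, save, and
# record in the manifest.
.stage <- function(state, name, file, fun) {
  path <- file.path(state$out_dir, file)
  if (file.exists(path)) {
    state$artifacts[[name]] <- readRDS(path)
    state$manifest$stages[[name]] <- list(cached = TRUE, file = file)
  } else {
    value <- fun(state$artifacts)
    saveRDS(value, path)
    state$artifacts[[name]] <- value
    state$manifest$stages[[name]] <- list(cached = FALSE, file = file,
                                          completed = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  }
  state
}

#' Run the full inference pipeline
#'
#' Stages are cached as RDS files under `out_dir`; deleting a stage's file
#' forces only that stage (and none upstream) to recompute. A
#' `manifest.json` records the mode, seeds, configuration and per-stage
#' provenance, including which pretraining corpus was used.
#'
#' @param data fixture-shaped input bundle: a list with `atac`, `rna`,
#'   `genes`, `cres`, `contacts`, `eqtls` and optionally `truth` (see
#'   [generate_fixture()] / [load_fixture_dir()]), or a directory path.
#' @param out_dir output/cache directory.
#' @param config partial configuration merged over [default_config()].
#' @param atlas optional atlas bundle from [generate_atlas_fixture()]; the
#'   pretraining corpus for mode `"full"`.
#' @return list with the trained model, regulation scores, metric report
#'   (when truth is available) and the manifest.
#' @export
run_pipeline <- function(data, out_dir, config = list(), atlas = NULL) {
  cfg <- .merge_config(config)
  if (is.character(data)) data <- load_fixture_dir(data)
  if (!cfg$mode %in% c("full", "posd", "wop")) stop("mode must be full, posd or wop")
  if (cfg$mode == "full" && is.null(atlas))
    stop("mode 'full' needs an atlas pretraining corpus (or use 'posd'/'wop')")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(out_dir = out_dir, artifacts = list(data = data),
                manifest = list(mode = cfg$mode, seed = cfg$seed,
                                config = cfg, stages = list(),
                                pretrain_corpus = switch(cfg$mode,
                                  full = "atlas", posd = "study", wop = "none")))

  state <- .stage(state, "preprocess", "01_preprocess.rds", function(a) {
    atac <- filter_cells_by_peak_count(a$data$atac, cfg$qc$low_pct, cfg$qc$high_pct)
    atac <- filter_peaks_by_occurrence(atac, cfg$qc$min_peak_frac)
    dims <- min(cfg$lsi$dims, nrow(atac$values) - 1L, ncol(atac$values) - 1L)
    emb <- lsi_embed(atac, n_hvf = cfg$lsi$n_hvf, dims = dims)
    if (cfg$lsi$drop_first) emb$coords <- emb$coords[, -1L, drop = FALSE]
    agg <- aggregate_neighbors(atac, emb, k = cfg$knn$k,
                               average = cfg$knn$average)
    split <- split_cells(agg$cell_types, cfg$split$fractions, seed = cfg$seed)
    rna <- a$data$rna
    keep_rna <- which(rna$cell_ids %in% agg$cell_ids[c(split$train, split$val)])
    rna_tv <- subset_cells(rna, cells = keep_rna)
    markers <- select_marker_genes(rna_tv, n_per_type = cfg$markers$n_per_type,
                                   mu = cfg$markers$mu)
    profiles <- normalize_profiles(pseudobulk_profiles(rna_tv), markers)
    list(atac = agg, split = split, markers = markers, profiles = profiles)
  })

  state <- .stage(state, "graphs", "02_graphs.rds", function(a) {
    genes <- a$data$genes[a$data$genes$gene_id %in% a$preprocess$markers, ,
                          drop = FALSE]
    cres <- a$preprocess$atac$feature_table
    sim_graph <- build_cre_gene_graph(cres, genes, a$data$contacts,
                                      a$data$eqtls,
                                      hic_symmetric = cfg$hic_symmetric)
    pre_graph <- build_cre_cre_graph(cres, genes, a$data$contacts, a$data$eqtls)
    list(sim_graph = sim_graph, pre_graph = pre_graph, genes = genes)
  })

  if (cfg$mode != "wop") {
    state <- .stage(state, "pretrain", "03_pretrain.rds", function(a) {
      edges <- pretrain_graph_edges(a$graphs$pre_graph)
      corpus <- if (cfg$mode == "full") {
        do.call(rbind, lapply(atlas$tissues, function(tm) {
          fi <- match(a$graphs$pre_graph$cres$id, tm$feature_ids)
          log1p(as.matrix(tm$values[, fi, drop = FALSE]))
        }))
      } else {
        fi <- match(a$graphs$pre_graph$cres$id,
                    a$preprocess$atac$feature_ids)
        log1p(as.matrix(a$preprocess$atac$values[, fi, drop = FALSE]))
      }
      model <- init_ssgae(mask_ratio = cfg$pretrain$mask_ratio,
                          gamma = cfg$pretrain$gamma,
                          dropout_p = cfg$pretrain$dropout_p,
                          seed = cfg$seed)
      pretrain_ssgae(model, corpus, edges, epochs = cfg$pretrain$epochs,
                     lr = cfg$pretrain$lr,
                     weight_decay = cfg$pretrain$weight_decay,
                     seed = cfg$seed + 1L)
    })
  }

  state <- .stage(state, "train", "04_train.rds", function(a) {
    sim_data <- build_sim_data(a$preprocess$atac, a$graphs$sim_graph,
                               a$preprocess$profiles)
    model <- init_gcat(n_genes = sim_data$n_gene,
                       n_types = length(sim_data$type_levels),
                       mode = cfg$mode, lambda = cfg$train$lambda,
                       dropout_p = cfg$train$dropout_p, seed = cfg$seed + 2L)
    model <- train_simulation(model, sim_data, a$preprocess$split,
                              ssgae = a$pretrain, epochs = cfg$train$epochs,
                              lr = cfg$train$lr,
                              weight_decay = cfg$train$weight_decay,
                              seed = cfg$seed + 3L,
                              patience = cfg$train$patience)
    list(model = model, sim_data = sim_data)
  })

  state <- .stage(state, "attribute", "05_scores.rds", function(a) {
    scores <- attribute_test_set(a$train$model, a$train$sim_data,
                                 a$preprocess$split,
                                 n_steps = cfg$attribution$steps,
                                 target = cfg$attribution$target,
                                 sd_scope = cfg$attribution$sd_scope)
    write_regulation_matrix(scores, file.path(out_dir, "regulation_scores.tsv"))
    scores
  })

  report <- NULL
  if (!is.null(data$truth)) {
    state <- .stage(state, "evaluate", "06_metrics.rds", function(a) {
      labeled <- match_predictions_to_truth(a$attribute, a$data$truth,
                                            a$data$cres, a$graphs$genes,
                                            max_dist = cfg$evaluation$max_dist)
      list(report = metric_report(labeled), labeled = labeled,
           by_distance = stratify_by_distance(labeled, cfg$evaluation$bins))
    })
    report <- state$artifacts$evaluate
  }

  manifest <- state$manifest
  manifest$package_version <- as.character(utils::packageVersion("screg"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(model = state$artifacts$train$model,
       sim_data = state$artifacts$train$sim_data,
       split = state$artifacts$preprocess$split,
       scores = state$artifacts$attribute,
       evaluation = report,
       manifest = manifest)
}
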