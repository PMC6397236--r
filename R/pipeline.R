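pipeline_defaults <- function() {
  list(
    seed = 1,
    output_dir = "lncnet_out",
    force = FALSE,
    simulation = NULL,
    input = NULL,
    de = list(fc_threshold = 2, p_threshold = 0.05, use_adjusted = FALSE,
              exclude = character(0)),
    wgcna = list(n_top = 300, beta = "auto", min_module_size = 30,
                 cut_height = NULL),
    preservation = list(n_permutations = 100),
    hubs = list(tau = 0.02, top_k = 20, cor_threshold = 0.7,
                n_modules_of_interest = 3),
    enrichment = list(gmt = NULL, alpha = 0.05)
  )
}

normalize_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  cfg <- pipeline_defaults()
  for (nm in names(config)) {
    if (is.list(cfg[[nm]]) && is.list(config[[nm]])) {
      cfg[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      cfg[[nm]] <- config[[nm]]
    }
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks the structural invariants of a pipeline configuration without
#' running anything: exactly one data source (a `simulation` block or an
#' `input` block of file paths), referenced files exist, and stage
#' parameters are in range. An empty report means [run_pipeline()] will
#' accept the config.
#'
#' @param config Named list (or YAML file path) with optional blocks
#'   `simulation` (fields of [simulation_config()], plus optional
#'   `perturb_modules`), `input` (`matrix`, `metadata`, optional
#'   `annotation`, `test_matrix`, `test_metadata`), `de`, `wgcna`,
#'   `preservation`, `hubs`, `enrichment`, and scalars `seed`,
#'   `output_dir`, `force`. Omitted parameters take package defaults.
#' @return Character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  cfg <- tryCatch(normalize_pipeline_config(config),
                  error = function(e) conditionMessage(e))
  if (is.character(cfg)) return(cfg)
  v <- character(0)
  has_sim <- !is.null(cfg$simulation)
  has_input <- !is.null(cfg$input)
  if (has_sim == has_input)
    v <- c(v, "exactly one of 'simulation' and 'input' must be present")
  if (has_sim) {
    sim <- normalize_sim_block(cfg$simulation)
    perturb <- sim$perturb_modules
    sim$perturb_modules <- NULL
    sim$seed <- sim$seed %||% cfg$seed
    err <- tryCatch({do.call(simulation_config, sim); NULL},
                    error = function(e) conditionMessage(e))
    if (!is.null(err)) v <- c(v, paste("simulation:", err))
  }
  if (has_input) {
    for (f in c("matrix", "metadata")) {
      if (is.null(cfg$input[[f]]))
        v <- c(v, sprintf("input: missing required path '%s'", f))
    }
    for (f in intersect(names(cfg$input),
                        c("matrix", "metadata", "annotation",
                          "test_matrix", "test_metadata"))) {
      path <- cfg$input[[f]]
      if (!is.null(path) && !file.exists(path))
        v <- c(v, sprintf("input: file not found: %s (%s)", path, f))
    }
  }
  if (cfg$de$fc_threshold <= 0) v <- c(v, "de: fc_threshold must be > 0")
  if (cfg$de$p_threshold <= 0) v <- c(v, "de: p_threshold must be > 0")
  if (cfg$wgcna$n_top <= 0) v <- c(v, "wgcna: n_top must be > 0")
  if (!identical(cfg$wgcna$beta, "auto") && (!is.numeric(cfg$wgcna$beta) || cfg$wgcna$beta < 1))
    v <- c(v, "wgcna: beta must be \"auto\" or a number >= 1")
  if (cfg$wgcna$min_module_size < 1) v <- c(v, "wgcna: min_module_size must be >= 1")
  if (cfg$preservation$n_permutations < 20)
    v <- c(v, "preservation: n_permutations must be >= 20")
  if (cfg$hubs$tau <= 0 || cfg$hubs$tau > 1) v <- c(v, "hubs: tau must lie in (0, 1]")
  if (cfg$hubs$top_k < 1) v <- c(v, "hubs: top_k must be >= 1")
  if (cfg$hubs$cor_threshold <= 0 || cfg$hubs$cor_threshold > 1)
    v <- c(v, "hubs: cor_threshold must lie in (0, 1]")
  if (!is.null(cfg$enrichment$gmt) && !file.exists(cfg$enrichment$gmt))
    v <- c(v, sprintf("enrichment: file not found: %s", cfg$enrichment$gmt))
  if (cfg$enrichment$alpha <= 0 || cfg$enrichment$alpha > 1)
    v <- c(v, "enrichment: alpha must lie in (0, 1]")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    v <- c(v, "seed must be a single integer")
  v
}

## YAML represents vectors as lists; flatten the vector-valued fields of
## a simulation block before handing it to simulation_config().
normalize_sim_block <- function(sim) {
  for (f in c("module_sizes", "module_trait_cor", "batch_labels")) {
    if (!is.null(sim[[f]]) && is.list(sim[[f]])) sim[[f]] <- unlist(sim[[f]])
  }
  sim
}

## Per-stage sub-seed derived from the global seed so that changing one
## stage's parameters does not perturb upstream randomness.
stage_seed <- function(seed, idx) {
  (as.integer(seed) * 131L + idx * 7919L) %% 2147483587L
}

#' Run the full lncRNA co-expression pipeline
#'
#' Orchestrates all stages from one configuration: (1) data (simulation
#' with ground truth, or loading user files), (2) annotation
#' (reannotation and duplicate collapsing), (3) differential expression
#' (outlier flagging, batch removal, moderated tests per tissue, DEG/DEL
#' filtering and intersection, PCA), (4) co-expression network (variance
#' filter, soft threshold, TOM, modules, eigengenes, module-trait
#' statistics), (5) module preservation against the test dataset, (6) hub
#' genes in the disease-associated modules via the shortest-path-tree
#' centrality plus CNC network export, (7) enrichment and the terminal
#' key-lncRNA report (hub lncRNAs that are also DELs).
#'
#' Every stage writes its tables under `output_dir` (existing outputs are
#' not rewritten unless `force`), and a manifest of file checksums plus a
#' JSON-lines run log (versions, seed, parameters, stage events) are
#' produced. Fixed seed implies byte-identical numeric tables.
#'
#' @param config Pipeline configuration (named list or YAML path); see
#'   [validate_config()].
#' @param force Overwrite existing stage outputs (overrides the config
#'   field).
#' @return Invisibly, a list with `status` (0 on success), `manifest`
#'   (data frame file/md5), `key_lncrna`, and `results` (the in-memory
#'   stage objects).
#' @export
run_pipeline <- function(config, force = NULL) {
  cfg <- normalize_pipeline_config(config)
  violations <- validate_config(cfg)
  if (length(violations))
    stopf("invalid pipeline config:\n- %s", paste(violations, collapse = "\n- "))
  if (!is.null(force)) cfg$force <- isTRUE(force)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$output_dir, ...)

  log_lines <- character(0)
  log_event <- function(stage, event, ...) {
    rec <- c(list(stage = stage, event = event), list(...))
    log_lines <<- c(log_lines, jsonlite::toJSON(rec, auto_unbox = TRUE))
  }
  artifacts <- character(0)
  emit <- function(path, writer) {
    if (file.exists(path) && !cfg$force) {
      log_event("io", "kept_existing", file = basename(path))
    } else {
      writer(path)
      log_event("io", "wrote", file = basename(path))
    }
    artifacts <<- c(artifacts, path)
  }
  run_stage <- function(stage, expr) {
    log_event(stage, "start")
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      log_event(stage, "failed", message = conditionMessage(res))
      writeLines(log_lines, out("run_log.jsonl"))
      stopf("stage '%s' failed: %s", stage, conditionMessage(res))
    }
    log_event(stage, "done")
    res
  }

  log_event("pipeline", "config", seed = cfg$seed,
            lncnet_version = as.character(utils::packageVersion("lncnet")),
            r_version = paste(R.version$major, R.version$minor, sep = "."),
            parameters = cfg[c("de", "wgcna", "preservation", "hubs", "enrichment")])
  results <- list()

  ## -- stage 1: data --------------------------------------------------
  data_res <- run_stage("data", {
    if (!is.null(cfg$simulation)) {
      sim <- normalize_sim_block(cfg$simulation)
      perturb <- unlist(sim$perturb_modules) %||% character(0)
      sim$perturb_modules <- NULL
      sim$seed <- sim$seed %||% cfg$seed
      sc <- do.call(simulation_config, sim)
      pair <- generate_paired_datasets(sc, perturb_modules = perturb)
      emit(out("ground_truth.tsv"),
           function(p) write_ground_truth(pair$truth, p))
      list(dataset = pair$reference, test = pair$test, truth = pair$truth)
    } else {
      ds <- read_expression_matrix(cfg$input$matrix, cfg$input$metadata)
      test <- NULL
      if (!is.null(cfg$input$test_matrix))
        test <- read_expression_matrix(cfg$input$test_matrix,
                                       cfg$input$test_metadata %||% cfg$input$metadata)
      list(dataset = ds, test = test, truth = NULL)
    }
  })
  results$data <- data_res

  ## -- stage 2: annotation --------------------------------------------
  ann_res <- run_stage("annotate", {
    ds <- data_res$dataset
    test <- data_res$test
    if (!is.null(cfg$input$annotation)) {
      ann <- read_gene_annotation(cfg$input$annotation)
      ds <- reannotate(ds, ann)
      if (!is.null(test)) test <- reannotate(test, ann)
    }
    ds <- collapse_duplicates(ds)
    if (!is.null(test)) test <- collapse_duplicates(test)
    emit(out("expression_matrix.tsv"), function(p)
      write_expression_dataset(ds, p, out("sample_metadata.tsv"),
                               out("features.tsv")))
    artifacts <<- c(artifacts, out("sample_metadata.tsv"), out("features.tsv"))
    list(dataset = ds, test = test)
  })
  results$annotate <- ann_res
  ds <- ann_res$dataset

  ## -- stage 3: differential expression -------------------------------
  de_res <- run_stage("de", {
    outliers <- if (ncol(ds$values) >= 4) detect_outlier_samples(ds) else character(0)
    log_event("de", "outliers", samples = outliers)
    if (length(unique(ds$samples$batch)) > 1) ds <- remove_batch_effects(ds)
    sm <- ds$samples
    grp <- function(tissue, condition)
      sm$sample_id[sm$tissue == tissue & sm$condition == condition]
    tissues <- unique(sm$tissue)
    two_tissue <- all(c("glomeruli", "tubuli") %in% tissues) &&
      all(vapply(c("glomeruli", "tubuli"), function(t)
        min(length(grp(t, "diabetic")), length(grp(t, "control"))) >= 2, logical(1)))
    fd <- function(res) filter_degs(res, cfg$de$fc_threshold, cfg$de$p_threshold,
                                    cfg$de$use_adjusted)
    if (two_tissue) {
      de_t <- moderated_t_test(ds, grp("tubuli", "diabetic"), grp("tubuli", "control"),
                               fc_threshold = cfg$de$fc_threshold,
                               p_threshold = cfg$de$p_threshold)
      de_g <- moderated_t_test(ds, grp("glomeruli", "diabetic"), grp("glomeruli", "control"),
                               fc_threshold = cfg$de$fc_threshold,
                               p_threshold = cfg$de$p_threshold)
      degs_t <- fd(de_t); degs_g <- fd(de_g)
      inter <- intersect_degs(degs_t$gene, degs_g$gene, exclusion = cfg$de$exclude)
      emit(out("de_tubuli.tsv"), function(p) write_tsv_precise(de_t, p))
      emit(out("de_glomeruli.tsv"), function(p) write_tsv_precise(de_g, p))
      log_event("de", "venn", counts = as.list(inter$venn))
      degs <- inter$genes
    } else {
      dg <- moderated_t_test(ds, sm$sample_id[sm$condition == "diabetic"],
                             sm$sample_id[sm$condition == "control"],
                             fc_threshold = cfg$de$fc_threshold,
                             p_threshold = cfg$de$p_threshold)
      emit(out("de_all.tsv"), function(p) write_tsv_precise(dg, p))
      degs <- setdiff(fd(dg)$gene, cfg$de$exclude)
    }
    lnc <- ds$features$feature_id[ds$features$biotype == "lncRNA"]
    dels <- sort(intersect(degs, lnc))
    emit(out("degs.tsv"), function(p)
      write_tsv_precise(data.frame(gene = sort(degs)), p))
    emit(out("dels.tsv"), function(p)
      write_tsv_precise(data.frame(gene = dels), p))
    pca <- pca_coordinates(ds, k = min(3, ncol(ds$values), nrow(ds$values)))
    emit(out("pca.tsv"), function(p) write_tsv_precise(
      data.frame(sample_id = rownames(pca$coordinates), pca$coordinates), p))
    list(dataset = ds, degs = degs, dels = dels, outliers = outliers, pca = pca)
  })
  results$de <- de_res
  ds <- de_res$dataset

  ## -- stage 4: co-expression network ---------------------------------
  wg_res <- run_stage("wgcna", {
    n_top <- min(cfg$wgcna$n_top, nrow(ds$values))
    filt <- variance_filter(ds, n_top)
    S <- correlation_matrix(filt)
    if (identical(cfg$wgcna$beta, "auto")) {
      pick <- pick_soft_threshold(S)
      beta <- pick$beta
      emit(out("soft_threshold.tsv"), function(p) write_tsv_precise(pick$fit_table, p))
    } else {
      beta <- cfg$wgcna$beta
    }
    log_event("wgcna", "beta", beta = beta)
    a <- adjacency_matrix(S, beta)
    tom <- topological_overlap(a)
    colors <- detect_modules(1 - tom, cfg$wgcna$min_module_size, cfg$wgcna$cut_height)
    me <- module_eigengenes(filt, colors)
    traits <- data.frame(
      diabetic = as.numeric(filt$samples$condition == "diabetic"),
      glomeruli = as.numeric(filt$samples$tissue == "glomeruli"))
    traits <- traits[, vapply(traits, sd, numeric(1)) > 0, drop = FALSE]
    mt <- module_trait_correlation(me, traits)
    emit(out("module_colors.tsv"), function(p) write_tsv_precise(
      data.frame(gene = names(colors), color = unname(colors)), p))
    emit(out("eigengenes.tsv"), function(p) write_tsv_precise(
      data.frame(module = rownames(me), me, check.names = FALSE), p))
    emit(out("module_trait_cor.tsv"), function(p) write_tsv_precise(
      data.frame(module = rownames(mt$correlation),
                 setNames(as.data.frame(mt$correlation),
                          paste0("cor_", colnames(mt$correlation))),
                 setNames(as.data.frame(mt$p),
                          paste0("p_", colnames(mt$p)))), p))
    list(filtered = filt, S = S, beta = beta, adjacency = a, colors = colors,
         eigengenes = me, traits = traits, module_trait = mt)
  })
  results$wgcna <- wg_res

  ## -- stage 5: module preservation -----------------------------------
  pres_res <- run_stage("preserve", {
    test <- ann_res$test %||% ds
    shared <- intersect(names(wg_res$colors), rownames(test$values))
    pres <- module_preservation(wg_res$filtered, test,
                                wg_res$colors[shared], wg_res$beta,
                                n_permutations = cfg$preservation$n_permutations,
                                seed = stage_seed(cfg$seed, 5L))
    emit(out("preservation.tsv"), function(p) write_tsv_precise(pres, p))
    pres
  })
  results$preserve <- pres_res

  ## -- stage 6: hub genes ---------------------------------------------
  hub_res <- run_stage("hubs", {
    mt <- wg_res$module_trait
    if (!"diabetic" %in% colnames(mt$correlation))
      stopf("no disease trait available for module selection")
    ord <- order(-abs(mt$correlation[, "diabetic"]))
    interest <- rownames(mt$correlation)[head(ord, cfg$hubs$n_modules_of_interest)]
    log_event("hubs", "modules_of_interest", modules = interest)
    biotypes <- setNames(ds$features$biotype, ds$features$feature_id)
    per_module <- lapply(setNames(interest, interest), function(m) {
      genes <- names(wg_res$colors)[wg_res$colors == m]
      g <- build_module_graph(wg_res$adjacency, genes, cfg$hubs$tau, biotypes)
      hubs <- select_hubs(g, k = cfg$hubs$top_k)
      hubs$module <- m
      emit(out(sprintf("hubs_%s.tsv", m)), function(p) write_tsv_precise(hubs, p))
      net <- cnc_network(hubs, wg_res$S, cfg$hubs$cor_threshold, dels = de_res$dels)
      emit(out(sprintf("cnc_%s.graphml", m)), function(p) write_graphml(net, p))
      emit(out(sprintf("cnc_%s.sif", m)), function(p) write_sif(net, p))
      list(graph = g, hubs = hubs, net = net)
    })
    per_module
  })
  results$hubs <- hub_res

  ## -- stage 7: enrichment and key-lncRNA report ----------------------
  enr_res <- run_stage("enrich", {
    universe <- ds$features$feature_id
    enr <- NULL
    if (!is.null(cfg$enrichment$gmt) && length(de_res$degs)) {
      collection <- read_gmt(cfg$enrichment$gmt)
      enr <- enrich(de_res$degs, collection, universe,
                    alpha = cfg$enrichment$alpha)
      emit(out("enrichment.tsv"), function(p) write_tsv_precise(enr, p))
    }
    key <- sort(unique(as.character(unlist(
      lapply(hub_res, function(m) m$net$key_lncrna)))))
    emit(out("key_lncrnas.tsv"), function(p)
      write_tsv_precise(data.frame(gene = key, stringsAsFactors = FALSE), p))
    list(enrichment = enr, key_lncrna = key)
  })
  results$enrich <- enr_res

  manifest_files <- sort(unique(artifacts))
  manifest <- data.frame(file = basename(manifest_files),
                         md5 = unname(tools::md5sum(manifest_files)),
                         stringsAsFactors = FALSE)
  write_tsv_precise(manifest, out("manifest.tsv"))
  writeLines(log_lines, out("run_log.jsonl"))
  message(sprintf("pipeline complete: %d artifacts in %s; key lncRNAs: %s",
                  nrow(manifest), cfg$output_dir,
                  if (length(enr_res$key_lncrna))
                    paste(enr_res$key_lncrna, collapse = ", ") else "(none)"))
  invisible(list(status = 0L, manifest = manifest,
                 key_lncrna = enr_res$key_lncrna, results = results))
}

#' Bundled synthetic preset pipeline configuration
#'
#' Builds a ready-to-run configuration around [standard_preset()]: the
#' simulation block, a paired test dataset with no perturbed modules, and
#' a small GMT collection written to `output_dir` whose terms are the
#' planted modules plus background slices (so the enrichment stage has
#' something meaningful to find).
#'
#' @param output_dir Directory for pipeline outputs (created).
#' @param seed Global pipeline seed.
#' @param perturb_modules Planted modules to destroy in the test dataset.
#' @return A pipeline config list accepted by [run_pipeline()].
#' @export
preset_pipeline_config <- function(output_dir, seed = 1,
                                   perturb_modules = character(0)) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- standard_preset(seed = seed)
  layout <- sim_layout(sc)
  sets <- lapply(setNames(sprintf("M%d", 1:5), sprintf("PLANTED_M%d", 1:5)),
                 function(m) layout$gene_id[layout$module == m])
  bg <- layout$gene_id[layout$module == "none"]
  sets$BACKGROUND_A <- bg[seq_len(min(50, length(bg)))]
  sets$BACKGROUND_B <- rev(bg)[seq_len(min(50, length(bg)))]
  gmt_path <- file.path(output_dir, "planted_sets.gmt")
  write_gmt(sets, gmt_path)
  list(seed = seed,
       output_dir = output_dir,
       simulation = c(unclass(sc),
                      list(perturb_modules = as.list(perturb_modules))),
       wgcna = list(n_top = 350, beta = 6),
       enrichment = list(gmt = gmt_path))
}
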