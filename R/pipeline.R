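# Pipeline orchestration: simulate -> extract -> analyze -> cluster under a
# single configuration and master seed, with a JSON run manifest (config
# snapshot, output paths, md5 checksums) for reproducibility.

config_error <- function(msg, keys = NULL) {
  stop(structure(class = c("grainpheno_config_error", "error", "condition"),
                 list(message = paste0(msg,
                        if (length(keys)) paste0(" [keys: ",
                                                 paste(keys, collapse = ", "), "]")),
                      call = NULL, keys = keys)))
}

dependency_error <- function(msg) {
  stop(structure(class = c("grainpheno_dependency_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Read and validate a pipeline configuration
#'
#' A configuration is a JSON file (or a list) whose top level holds
#' [study_config()] arguments (`years` is required), an optional
#' `germination` block of [germination_link()] arguments, and an optional
#' `analysis` block (`n_rep`, `k_clusters`).
#'
#' @param config path to a JSON file or a list.
#' @return List with `study` (a `study_config`), `germination` (a
#'   `germination_link`), `analysis` settings, and the raw input.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) config_error("config file not found", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) config_error("config must be a list or JSON path")
  if (is.null(config$years)) config_error("missing required key", "years")
  study_args <- config[intersect(names(config), names(formals(study_config)))]
  study <- tryCatch(do.call(study_config, study_args),
                    error = function(e) config_error(conditionMessage(e)))
  germ_args <- if (is.list(config$germination)) {
    config$germination[intersect(names(config$germination),
                                 names(formals(germination_link)))]
  } else list()
  germ <- do.call(germination_link, germ_args)
  analysis <- list(n_rep = 2000, k_clusters = 3)
  if (is.list(config$analysis))
    analysis[names(config$analysis)] <- config$analysis
  list(study = study, germination = germ, analysis = analysis, raw = config)
}

stage_paths <- function(outdir) {
  list(design = file.path(outdir, "design.csv"),
       ground_truth = file.path(outdir, "ground_truth.csv"),
       germination = file.path(outdir, "germination.csv"),
       traits = file.path(outdir, "traits.csv"),
       rejected = file.path(outdir, "rejected.csv"),
       trend = file.path(outdir, "trend.csv"),
       anova = file.path(outdir, "anova.csv"),
       germination_cor = file.path(outdir, "germination_cor.csv"),
       trait_tree = file.path(outdir, "trait_tree.nwk"),
       genotype_tree = file.path(outdir, "genotype_tree.nwk"),
       clusters = file.path(outdir, "clusters.csv"),
       lda_color = file.path(outdir, "lda_color.csv"),
       lda_shape = file.path(outdir, "lda_shape.csv"),
       summary = file.path(outdir, "summary.json"),
       manifest = file.path(outdir, "run_manifest.json"))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order under one master seed:
#'
#' - `simulate`: synthetic study images + design, ground-truth and
#'   germination tables;
#' - `extract`: per-seed trait table from the images (chart correction,
#'   segmentation, contours, 55 descriptors);
#' - `analyze`: per-trait one-way ANOVAs (genotype, year), year-encoding
#'   trend correlations with the randomization envelope rule, germination
#'   correlation analysis;
#' - `cluster`: UPGMA trees of traits and of genotype means (Newick),
#'   k-cluster assignments, LDA biplots for color and size/shape traits.
#'
#' Later stages read earlier stages' CSV outputs from `outdir`, so partial
#' reruns reproduce identical results from cached tables.
#'
#' @param config JSON path or list, see [read_pipeline_config()].
#' @param outdir output directory.
#' @param stages subset of simulate/extract/analyze/cluster, or `"all"`.
#' @param seed master seed overriding the config's.
#' @param verbose log per-stage progress and timing.
#' @return Invisibly, the run manifest (also written as JSON): config
#'   snapshot, seed, per-stage output paths and md5 checksums.
#' @export
run_pipeline <- function(config, outdir, stages = "all", seed = NULL,
                         verbose = FALSE) {
  cfg <- read_pipeline_config(config)
  if (!is.null(seed)) cfg$study$seed <- as.integer(seed)
  all_stages <- c("simulate", "extract", "analyze", "cluster")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) config_error("unknown stage(s)", bad)
  stages <- all_stages[all_stages %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- stage_paths(outdir)
  manifest <- list(seed = cfg$study$seed, config = cfg$raw,
                   stages = list(), outputs = list())
  log <- function(...) if (verbose) message(sprintf(...))

  for (st in stages) {
    t0 <- Sys.time()
    done <- switch(st,
      simulate = {
        study <- generate_study(cfg$study, outdir)
        germ <- generate_germination(study$design, study$ground_truth,
                                     cfg$germination, seed = cfg$study$seed)
        utils::write.csv(germ, paths$germination, row.names = FALSE)
        c(paths$design, paths$ground_truth, paths$germination)
      },
      extract = {
        if (!file.exists(paths$design))
          dependency_error("extract requires design.csv (run simulate first)")
        design <- utils::read.csv(paths$design)
        if (!all(file.exists(design$image_path)))
          dependency_error("extract: design references missing image files")
        tt <- compute_trait_table(design, cfg$study$chart,
                                  seed = cfg$study$seed, verbose = verbose)
        utils::write.csv(tt, paths$traits, row.names = FALSE)
        c(paths$traits)
      },
      analyze = {
        if (!file.exists(paths$traits))
          dependency_error("analyze requires traits.csv (run extract first)")
        tt <- utils::read.csv(paths$traits)
        traits <- intersect(trait_names(), names(tt))
        trend <- year_trend_analysis(tt, traits, n_rep = cfg$analysis$n_rep,
                                     seed = cfg$study$seed)
        utils::write.csv(trend, paths$trend, row.names = FALSE)
        an <- do.call(rbind, lapply(traits, function(tr) {
          rbind(
            data.frame(trait = tr, factor = "genotype",
                       as.data.frame(one_way_anova(tt[[tr]], tt$genotype_id)[
                         c("F", "df_between", "df_within", "p")])),
            data.frame(trait = tr, factor = "year",
                       as.data.frame(one_way_anova(tt[[tr]], tt$year)[
                         c("F", "df_between", "df_within", "p")])))
        }))
        utils::write.csv(an, paths$anova, row.names = FALSE)
        outp <- c(paths$trend, paths$anova)
        if (file.exists(paths$germination)) {
          germ <- utils::read.csv(paths$germination)
          ga <- germination_analysis(germ, tt, traits,
                                     n_rep = cfg$analysis$n_rep,
                                     seed = cfg$study$seed)
          utils::write.csv(ga$correlations, paths$germination_cor,
                           row.names = FALSE)
          outp <- c(outp, paths$germination_cor)
        }
        outp
      },
      cluster = {
        if (!file.exists(paths$traits))
          dependency_error("cluster requires traits.csv (run extract first)")
        tt <- utils::read.csv(paths$traits)
        traits <- intersect(trait_names(), names(tt))
        # traits as items: Euclidean distance between standardized columns
        zt <- standardize(as.matrix(tt[traits]))
        tr_tree <- upgma_tree(t(zt), standardize_cols = FALSE)
        writeLines(tr_tree$newick, paths$trait_tree)
        gm <- genotype_trait_means(tt, traits)
        g_tree <- upgma_tree(gm)
        writeLines(g_tree$newick, paths$genotype_tree)
        k <- min(cfg$analysis$k_clusters, nrow(gm))
        cl <- cut_clusters(g_tree, k)
        utils::write.csv(data.frame(genotype_id = names(cl), cluster = cl),
                         paths$clusters, row.names = FALSE)
        outp <- c(paths$trait_tree, paths$genotype_tree, paths$clusters)
        seed_cl <- cl[tt$genotype_id]
        shape_cols <- intersect(c("sL", "sW", "sA", "sCi", "sRo", "sRu", "sSo"),
                                traits)
        color_cols <- setdiff(traits, shape_cols)
        if (k >= 2 && all(table(seed_cl) >= 2)) {
          for (set in list(list(color_cols, paths$lda_color),
                           list(shape_cols, paths$lda_shape))) {
            lb <- lda_biplot(as.matrix(tt[set[[1]]]), seed_cl)
            utils::write.csv(
              data.frame(genotype_id = tt$genotype_id, cluster = seed_cl,
                         lb$scores[, 1:min(2, ncol(lb$scores)), drop = FALSE]),
              set[[2]], row.names = FALSE)
            outp <- c(outp, set[[2]])
          }
        }
        outp
      })
    manifest$stages[[st]] <- list(
      outputs = done,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    log("stage %s done in %.1fs", st,
        manifest$stages[[st]]$seconds)
  }

  # summary of headline quantities for downstream assertions
  summary <- list()
  if (file.exists(paths$trend)) {
    trend <- utils::read.csv(paths$trend)
    yr <- trend[trend$scheme == "YearRank", ]
    for (tr in intersect(c("Lab_ma", "HSV_mH", "HSV_mV", "Lab_mL"), yr$trait))
      summary[[paste0("trend_r_", tr)]] <- yr$r[yr$trait == tr]
    summary$n_significant_trends <- sum(yr$significant, na.rm = TRUE)
  }
  if (file.exists(paths$germination_cor)) {
    gc <- utils::read.csv(paths$germination_cor)
    i <- which.min(gc$r)
    summary$germination_most_negative_trait <- gc$trait[i]
    summary$germination_most_negative_r <- gc$r[i]
  }
  if (length(summary))
    jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                         digits = NA)

  files <- unlist(lapply(manifest$stages, `[[`, "outputs"))
  files <- files[file.exists(files)]
  manifest$outputs <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
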