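#' Assemble a pipeline configuration
#'
#' Settings default to the values the analysis was designed around: 30-s
#' recordings, 5-ms autocorrelogram bins up to 1 s with a 960-1000 ms tail
#' window, a 3-split coarse tree, and the 12-split train/validation
#' protocol. A configuration can also be read from a YAML or JSON file.
#'
#' @param ... Overrides of the default fields (`seed`, `duration`,
#'   `simulate`, `n_per_group`, `input`, `model_selection`, `n_splits`,
#'   `train_counts`, `val_counts`, `max_splits`).
#' @param file Optional YAML (`.yml`/`.yaml`, needs the yaml package) or
#'   JSON configuration file; `...` overrides file values.
#' @return Named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- list(seed = 1, duration = 30, simulate = TRUE,
              n_per_group = c(control = 33, ataxia = 24, dystonia = 24,
                              tremor = 24),
              input = NULL, model_selection = TRUE, n_splits = 12,
              train_counts = c(control = 25, ataxia = 20, dystonia = 20,
                               tremor = 20),
              val_counts = c(control = 8, ataxia = 4, dystonia = 4,
                             tremor = 4),
              max_splits = 3)
  if (!is.null(file)) {
    loaded <- if (grepl("\\.ya?ml$", file)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the yaml package")
      yaml::read_yaml(file)
    } else jsonlite::read_json(file, simplifyVector = TRUE)
    for (k in names(loaded)) cfg[[k]] <- if (k %in%
      c("n_per_group", "train_counts", "val_counts"))
      unlist(loaded[[k]]) else loaded[[k]]
  }
  dots <- list(...)
  for (k in names(dots)) cfg[[k]] <- dots[[k]]
  class(cfg) <- "pipeline_config"
  cfg
}

.write_with_header <- function(df, path, cfg) {
  hdr <- c(sprintf("# spikesig pipeline output"),
           sprintf("# seed: %s", cfg$seed),
           sprintf("# duration: %s", cfg$duration),
           sprintf("# simulate: %s", cfg$simulate),
           sprintf("# max_splits: %s", cfg$max_splits))
  con <- file(path, "w")
  writeLines(hdr, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  path
}

#' Run the full featurize / train / classify / report pipeline
#'
#' Stages: (1) obtain spike trains, either simulated archetypal cohorts or
#' a spike table on disk; (2) featurize; (3) fit the signature classifier
#' (12-split model selection by default); (4) classify the cohort; (5)
#' write the report tables (signature proportions and diagonal enrichment
#' tests). Everything is deterministic given the configuration, and every
#' output carries the governing settings in a comment header.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the fitted model, feature table, cohort
#'   summary and output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempdir()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  require_30s <- isTRUE(all.equal(config$duration, 30))
  if (!require_30s)
    warning("recording duration is ", config$duration,
            " s, not 30 s: parameter estimates are duration-sensitive")

  cohort <- stage("input", {
    if (isTRUE(config$simulate)) {
      generate_archetypal_cohort(config$n_per_group, seed = config$seed,
                                 duration = config$duration)$cohort
    } else {
      if (is.null(config$input)) stop("no input path configured")
      read_spike_trains(config$input, duration = config$duration)
    }
  })

  features <- stage("featurize", featurize_cohort(cohort,
                                                  require_30s = require_30s))
  feat_path <- file.path(out_dir, "feature_table.csv")
  tmp <- features
  for (j in feature_names())
    tmp[[j]] <- format(tmp[[j]], digits = 15, trim = TRUE, scientific = TRUE)
  .write_with_header(tmp, feat_path, config)

  model <- stage("train", {
    if (isTRUE(config$model_selection)) {
      rep <- run_model_selection(features, n_splits = config$n_splits,
                                 seed = config$seed,
                                 train_counts = config$train_counts,
                                 val_counts = config$val_counts,
                                 max_splits = config$max_splits)
      .write_with_header(rep$summary,
                         file.path(out_dir, "validation_report.csv"), config)
      rep$selected_tree
    } else {
      train_coarse_tree(features[, intersect(feature_names(),
                                             names(features))],
                        features$group_label,
                        max_splits = config$max_splits)
    }
  })
  model_path <- file.path(out_dir, "model.json")
  write_tree_json(model, model_path)

  summary <- stage("classify", classify_cohort(model, features))
  prop <- proportion_table(summary)
  .write_with_header(data.frame(origin = rownames(summary$counts),
                                as.data.frame.matrix(summary$counts)),
                     file.path(out_dir, "cohort_summary.csv"), config)
  .write_with_header(data.frame(origin = rownames(prop),
                                as.data.frame.matrix(round(prop, 6))),
                     file.path(out_dir, "signature_proportions.csv"), config)

  report <- stage("report", {
    rows <- lapply(intersect(rownames(summary$counts), signature_levels()),
                   function(g) {
                     if (!g %in% colnames(summary$counts)) return(NULL)
                     e <- enrichment_chi_square(summary, g, g)
                     data.frame(origin = g, signature = g,
                                chi2 = e$chi2, p_value = e$p.value)
                   })
    do.call(rbind, rows)
  })
  if (!is.null(report))
    .write_with_header(report, file.path(out_dir, "enrichment_tests.csv"),
                       config)

  invisible(list(model = model, features = features, summary = summary,
                 proportions = prop, report = report,
                 paths = list(features = feat_path, model = model_path,
                              out_dir = out_dir)))
}
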