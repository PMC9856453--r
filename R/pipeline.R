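#' Pipeline configuration
#'
#' Bundles every tunable parameter of the end-to-end workflow (simulate ->
#' QC -> normalize -> batch-correct -> aggregate -> screen -> embed ->
#' classify -> omics) with its default. Unknown fields are rejected, so
#' configs stay forward-compatible with typos caught early.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    # simulation
    sim = list(),                       # overrides passed to sim_config()
    # QC
    qc_min_cells_per_well = 500,
    qc_min_cells_per_image = 30,
    blocklist = character(),
    # normalization
    control_concentration = 0,
    per_plate = TRUE,
    mad_scale = FALSE,
    # batch correction
    batch_level = "image",              # "cell" or "image"
    combat_shrink = TRUE,
    # screen
    dose_scale = "log",
    alpha = 0.05,
    # multivariate
    umap_neighbors = 200,
    run_umap = FALSE,
    splsda_K = 2,
    splsda_eta = 0.5,
    binarize_threshold = 1.25,
    # omics
    omics_n_lipids = 73,
    omics_n_metabolites = 63,
    omics_group = "AMP",
    omics_reference = "control",
    omics_p_thresh = 0.05,
    omics_fc_thresh = 2,
    omics_top_n = 25,
    # output
    out_dir = NULL
  )
  overrides <- list(...)
  validate_config(overrides, defaults = defaults)
  cfg <- modifyList(defaults, overrides)
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list, checks every key against the
#' known fields and every value against its expected type, and returns
#' the completed configuration (defaults filled in). All problems are
#' reported together.
#'
#' @param x Path to a YAML file, or a named list of overrides.
#' @param defaults Internal.
#' @return A `pipeline_config`, or an error listing every offending
#'   field.
#' @export
validate_config <- function(x, defaults = NULL) {
  external <- is.null(defaults)
  if (external) defaults <- unclass(pipeline_config())
  overrides <- if (is.character(x) && length(x) == 1) {
    yaml::read_yaml(x) %||% list()
  } else {
    as.list(x)
  }
  errors <- character()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown field(s): ", paste(unknown, collapse = ", ")))
  }
  numeric_fields <- c("seed", "qc_min_cells_per_well", "qc_min_cells_per_image",
                      "control_concentration", "alpha", "umap_neighbors",
                      "splsda_K", "splsda_eta", "binarize_threshold",
                      "omics_n_lipids", "omics_n_metabolites",
                      "omics_p_thresh", "omics_fc_thresh", "omics_top_n")
  for (f in intersect(names(overrides), numeric_fields)) {
    v <- overrides[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      errors <- c(errors, paste0("field '", f, "' must be a single number"))
    }
  }
  flag_fields <- c("per_plate", "mad_scale", "combat_shrink", "run_umap")
  for (f in intersect(names(overrides), flag_fields)) {
    if (!is.logical(overrides[[f]]) || length(overrides[[f]]) != 1) {
      errors <- c(errors, paste0("field '", f, "' must be TRUE or FALSE"))
    }
  }
  if ("batch_level" %in% names(overrides) &&
      !identical(overrides$batch_level, "cell") &&
      !identical(overrides$batch_level, "image")) {
    errors <- c(errors, "field 'batch_level' must be \"cell\" or \"image\"")
  }
  if (length(errors)) {
    abort(paste0("invalid configuration:\n  ",
                 paste(errors, collapse = "\n  ")))
  }
  if (external) {
    structure(modifyList(defaults, overrides), class = "pipeline_config")
  } else {
    invisible(TRUE)
  }
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes the stages in fixed order — simulate, QC, normalize,
#' batch-correct, aggregate (image/well/treatment), ANCOVA screen,
#' optional UMAP embedding, sparse PLS-DA cross-validation, and the omics
#' arm on a simulated analyte table — recording per-stage row/feature
#' counts and timings. A stage failure is recorded and the dependent
#' stages are skipped. All randomness flows from the single root seed.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_run`: list with `report` (per-stage tibble),
#'   `results` (named list of stage outputs) and `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list()
  results <- list()
  failed <- FALSE

  run_stage <- function(name, rows_in, fun) {
    if (failed) {
      report[[name]] <<- tibble(stage = name, status = "skipped",
                                rows_in = NA_integer_, rows_out = NA_integer_,
                                features_out = NA_integer_, seconds = NA_real_,
                                error = NA_character_)
      return(NULL)
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    secs <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failed <<- TRUE
      report[[name]] <<- tibble(stage = name, status = "error",
                                rows_in = rows_in, rows_out = NA_integer_,
                                features_out = NA_integer_, seconds = secs,
                                error = conditionMessage(res))
      return(NULL)
    }
    rows_out <- if (inherits(res, "data.frame")) nrow(res) else NA_integer_
    feats <- if (inherits(res, "profile_frame")) n_features(res) else NA_integer_
    report[[name]] <<- tibble(stage = name, status = "ok",
                              rows_in = rows_in, rows_out = rows_out,
                              features_out = feats, seconds = secs,
                              error = NA_character_)
    res
  }

  sim_args <- modifyList(list(seed = config$seed), config$sim)
  sim <- run_stage("simulate", NA_integer_, function() {
    do.call(sim_config, sim_args) %>% generate_experiment()
  })
  if (!is.null(sim)) results$truth <- sim$truth

  qc <- run_stage("qc", if (is.null(sim)) NA_integer_ else nrow(sim$cells), function() {
    sim$cells %>%
      qc_filter(config$qc_min_cells_per_well, config$qc_min_cells_per_image) %>%
      drop_cells_and_features(config$blocklist)
  })

  normed <- run_stage("normalize", if (is.null(qc)) NA_integer_ else nrow(qc), function() {
    normalize_to_control(qc, config$control_concentration,
                         per_plate = config$per_plate,
                         mad_scale = config$mad_scale)
  })

  if (identical(config$batch_level, "cell")) {
    corrected_cells <- run_stage("batch_correct",
                                 if (is.null(normed)) NA_integer_ else nrow(normed),
                                 function() combat_correct(normed, shrink = config$combat_shrink))
    images <- run_stage("aggregate",
                        if (is.null(corrected_cells)) NA_integer_ else nrow(corrected_cells),
                        function() aggregate_images(corrected_cells))
  } else {
    images_raw <- run_stage("aggregate",
                            if (is.null(normed)) NA_integer_ else nrow(normed),
                            function() aggregate_images(normed))
    images <- run_stage("batch_correct",
                        if (is.null(images_raw)) NA_integer_ else nrow(images_raw),
                        function() combat_correct(images_raw, shrink = config$combat_shrink))
  }
  if (!is.null(images)) {
    results$images <- images
    results$wells <- aggregate_wells(images)
    results$treatments <- aggregate_treatment(results$wells)
  }

  screen <- run_stage("screen", if (is.null(images)) NA_integer_ else nrow(images), function() {
    ancova_screen(images, dose_scale = config$dose_scale, alpha = config$alpha)
  })
  if (!is.null(screen)) {
    results$screen <- screen
    results$screen_summary <- summarize_screen(screen)
  }

  if (isTRUE(config$run_umap)) {
    emb <- run_stage("embed", if (is.null(images)) NA_integer_ else nrow(images), function() {
      umap_embed(images, n_neighbors = config$umap_neighbors,
                 seed = config$seed + 1L)
    })
    if (!is.null(emb)) results$embedding <- emb
  }

  cv <- run_stage("classify", if (is.null(images)) NA_integer_ else nrow(images), function() {
    crossvalidate_leave_one_plate(images, K = config$splsda_K,
                                  eta = config$splsda_eta,
                                  threshold = config$binarize_threshold)
  })
  if (!is.null(cv)) results$classification <- cv

  omics <- run_stage("omics", NA_integer_, function() {
    lipids <- generate_analyte_table(n_analytes = config$omics_n_lipids,
                                     seed = config$seed + 2L)
    at <- anova_tukey(lipids)
    volcano <- volcano_classify(lipids, group = config$omics_group,
                                reference = config$omics_reference,
                                p_thresh = config$omics_p_thresh,
                                fc_thresh = config$omics_fc_thresh)
    list(table = lipids, anova = at, volcano = volcano,
         heatmap = cluster_heatmap(lipids, at, top_n = config$omics_top_n))
  })
  if (!is.null(omics)) results$omics <- omics

  report_tbl <- dplyr::bind_rows(report)
  run <- structure(list(report = report_tbl, results = results,
                        config = config), class = "pipeline_run")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(run, config$out_dir)
  run
}

write_pipeline_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- run$results
  if (!is.null(res$images)) {
    write_profiles(res$images, file.path(out_dir, "profiles_image.csv"))
  }
  if (!is.null(res$treatments)) {
    write_profiles(res$treatments, file.path(out_dir, "profiles_treatment.csv"))
  }
  if (!is.null(res$screen)) {
    readr::write_csv(as_tibble(res$screen), file.path(out_dir, "screen.csv"))
  }
  if (!is.null(res$classification)) {
    jsonlite::write_json(
      list(runs = tidy(res$classification), summary = glance(res$classification)),
      file.path(out_dir, "classification.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  readr::write_csv(run$report, file.path(out_dir, "run_report.csv"))
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run:\n")
  print(x$report)
  invisible(x)
}
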