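#' Default pipeline configuration
#'
#' One flat configuration driving every stage. The defaults are the
#' reference parameters of the method: edit weights 1.1/1.1/1.9 with
#' association threshold 3, graph filters (min 10 members, edge distance at
#' most 8, active in more than 60% of time points), ML active fraction 0.95,
#' top-50 subsets, committee of 10, noise grid 0 to 0.25.
#'
#' @param ... Named overrides of the defaults (unknown names are an error).
#' @return A named list of class `ca_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    clones = NULL,            # path to a clone table TSV (NULL -> simulate)
    metadata = NULL,          # path to a metadata TSV (NULL -> simulate)
    db = NULL,                # optional public sequence table TSV
    db_seq_col = "cdr3",
    deletion = 1.1, insertion = 1.1, substitution = 1.9, lambda = 3,
    strategy = "first_fit",
    min_members = 10, max_edge_distance = 8, min_timepoint_fraction = 0.6,
    active_fraction = 0.95, top_k = 50, dims = 3:8, ensemble_size = 10,
    noise_amplitudes = seq(0, 0.25, by = 0.05), normalize = FALSE,
    sim = list(),             # sim_config() overrides when simulating
    seed = 42)
  overrides <- list(...)
  if (length(overrides) > 0 &&
      (is.null(names(overrides)) || any(names(overrides) == ""))) {
    abort("all configuration overrides must be named.")
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  structure(modifyList(defaults, overrides), class = "ca_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys matching [pipeline_config()] arguments; unknown keys are an
#' error naming the field.
#'
#' @param path YAML file path.
#' @return A `ca_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$dims)) vals$dims <- as.integer(unlist(vals$dims))
  if (!is.null(vals$noise_amplitudes)) {
    vals$noise_amplitudes <- as.numeric(unlist(vals$noise_amplitudes))
  }
  do.call(pipeline_config, vals)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

.file_digest <- function(paths) {
  ok <- file.exists(paths)
  out <- rep(NA_character_, length(paths))
  out[ok] <- unname(tools::md5sum(paths[ok]))
  setNames(out, basename(paths))
}

#' Run the full Clone-Attractor pipeline
#'
#' Executes cluster -> network -> classify (and match-db when a database is
#' configured) in order, writing every stage's tables plus a JSON run
#' manifest (tool version, configuration hash, input digests, seed,
#' per-stage wall-clock, output inventory with digests) to `out_dir`. When
#' no clone table is configured, the synthetic generator provides the input
#' repertoire. With `resume = TRUE`, stages whose outputs already exist are
#' reloaded instead of recomputed.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param out_dir Output directory (created if needed).
#' @param resume Reuse existing stage outputs found in `out_dir`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, resume = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "ca_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  manifest <- list(
    tool = "cloneattractor",
    version = as.character(utils::packageVersion("cloneattractor")),
    config = unclass(config), config_hash = hash, seed = config$seed,
    inputs = list(), stages = list(), outputs = character(0),
    status = "running")
  weights <- edit_weights(config$deletion, config$insertion,
                          config$substitution, config$lambda)
  filters <- graph_filters(config$min_members, config$max_edge_distance,
                           config$min_timepoint_fraction)
  mlcfg <- ml_config(
    active_fraction = config$active_fraction, top_k = config$top_k,
    dims = config$dims, ensemble_size = config$ensemble_size,
    noise_amplitudes = config$noise_amplitudes,
    normalize = config$normalize, seed = config$seed)
  paths <- list(
    clones = file.path(out_dir, "clones.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    attractors = file.path(out_dir, "attractors.tsv"),
    activity = file.path(out_dir, "activity.tsv"),
    measures = file.path(out_dir, "measures.tsv"),
    summary = file.path(out_dir, "measure_summary.tsv"),
    powerlaw = file.path(out_dir, "powerlaw.tsv"),
    ml = file.path(out_dir, "ml_summary.tsv"),
    sel1 = file.path(out_dir, "selected_features_stage1.tsv"),
    sel2 = file.path(out_dir, "selected_features_stage2.tsv"),
    roc = file.path(out_dir, "roc_points.tsv"),
    matches = file.path(out_dir, "db_matches.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  result <- list(config = config)
  finish_stage <- local({
    t0 <- Sys.time()
    function(name) {
      t1 <- Sys.time()
      manifest$stages[[name]] <<- round(as.numeric(t1 - t0, units = "secs"), 3)
      t0 <<- t1
    }
  })
  fail <- function(stage, e) {
    manifest$status <- paste0("failed at stage: ", stage)
    manifest$error <- conditionMessage(e)
    manifest$outputs <- as.list(.file_digest(unlist(paths)))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    abort(sprintf("pipeline failed at stage %s: %s", stage,
                  conditionMessage(e)), parent = e)
  }

  # --- input stage: read or simulate --------------------------------------
  tryCatch({
    if (is.null(config$clones)) {
      sim <- simulate_repertoire(do.call(sim_config, config$sim),
                                 seed = config$seed)
      clones <- validate_clone_table(sim$clones)
      metadata <- validate_sample_metadata(sim$metadata)
      result$simulation <- sim
      .write_tsv_commented(clones, paths$clones, "clone table", hash)
      .write_tsv_commented(metadata, paths$metadata, "metadata", hash)
    } else {
      clones <- read_clone_table(
        config$clones,
        dialect = clone_dialect(count = "count"))
      metadata <- read_sample_metadata(config$metadata)
      manifest$inputs <- as.list(.file_digest(
        c(config$clones, config$metadata)))
    }
    result$clones <- clones
    result$metadata <- metadata
    finish_stage("input")
  }, error = function(e) fail("input", e))

  # --- cluster ------------------------------------------------------------
  tryCatch({
    if (resume && file.exists(paths$attractors) && file.exists(paths$activity)) {
      inform("resuming: attractors and activity loaded from disk")
      prev <- read_attractor_table(paths$attractors)
      aset <- .new_attractor_set(
        prev$attractors, prev$members,
        log = tibble(order = integer(), junction_aa = character(),
                     ca_id = integer(), distance = numeric(),
                     founded = logical()),
        weights = weights, strategy = config$strategy)
      activity <- read_activity_matrix(paths$activity)
    } else {
      aset <- cluster_repertoire(clones, weights, strategy = config$strategy)
      activity <- attractor_activity(aset, clones)
      write_attractor_table(aset, paths$attractors, hash)
      write_activity_matrix(activity, paths$activity, hash)
    }
    if (config$lambda <= min(weights$deletion, weights$insertion,
                             weights$substitution)) {
      warn("lambda admits no edit: every unique sequence is its own cluster")
    }
    result$attractors <- aset
    result$activity <- activity
    finish_stage("cluster")
  }, error = function(e) fail("cluster", e))

  # --- network ------------------------------------------------------------
  tryCatch({
    fit <- tryCatch(powerlaw_fit(result$attractors$attractors$size),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      .write_tsv_commented(glance(fit), paths$powerlaw, "power-law fit", hash)
      result$powerlaw <- fit
    }
    graphs <- build_graphs(result$attractors, result$activity, weights,
                           filters)
    measures <- measure_table(graphs)
    .write_tsv_commented(measures, paths$measures, "graph measures", hash)
    .write_tsv_commented(measure_summary(measures), paths$summary,
                         "per-sample measure summary", hash)
    result$graphs <- graphs
    result$measures <- measures
    finish_stage("network")
  }, error = function(e) fail("network", e))

  # --- classify -----------------------------------------------------------
  tryCatch({
    ts <- two_stage_classify(result$activity, result$metadata, mlcfg)
    .write_tsv_commented(glance(ts), paths$ml, "two-stage summary", hash)
    .write_tsv_commented(
      tibble(feature = ts$stage1$selected_features), paths$sel1,
      "stage-1 selected features", hash)
    if (!is.null(ts$stage2)) {
      .write_tsv_commented(
        tibble(feature = ts$stage2$selected_features), paths$sel2,
        "stage-2 selected features", hash)
    }
    roc_pts <- bind_rows(
      mutate(ts$stage1$roc$curves, stage = 1L),
      if (!is.null(ts$stage2)) mutate(ts$stage2$roc$curves, stage = 2L))
    .write_tsv_commented(roc_pts, paths$roc, "ROC points", hash)
    result$classification <- ts
    finish_stage("classify")
  }, error = function(e) fail("classify", e))

  # --- match-db (optional) ------------------------------------------------
  if (!is.null(config$db)) {
    tryCatch({
      db <- .read_tsv_quiet(config$db)
      kept <- filter_attractors(result$attractors, result$activity, filters)
      m <- match_public(result$attractors, db, seq_col = config$db_seq_col,
                        ca_ids = kept$ca_id)
      .write_tsv_commented(m$hits, paths$matches, "database matches", hash)
      result$db_match <- m
      finish_stage("match_db")
    }, error = function(e) fail("match_db", e))
  }

  manifest$status <- "ok"
  manifest$outputs <- as.list(.file_digest(unlist(paths)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  result$manifest <- manifest
  invisible(result)
}
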