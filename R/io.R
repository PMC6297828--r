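#' Column-name mapping for clone tables
#'
#' Defaults follow the AIRR Rearrangement convention (`junction_aa`,
#' `duplicate_count`) with `sample_id` / `time_point` sidecar columns, so
#' MiXCR/AIRR-style exports load without renaming. Override any entry to
#' adapt to other dialects.
#'
#' @param junction_aa,count,sample_id,time_point Column names in the file.
#' @return A named list of class `clone_dialect`.
#' @export
clone_dialect <- function(junction_aa = "junction_aa",
                          count = "duplicate_count",
                          sample_id = "sample_id",
                          time_point = "time_point") {
  structure(list(junction_aa = junction_aa, count = count,
                 sample_id = sample_id, time_point = time_point),
            class = "clone_dialect")
}

.read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

#' Read and validate a clone table
#'
#' Loads a tab-separated table of observed CDR3 clones (one row per clone per
#' sample per time point), validates sequences against the 20-letter
#' amino-acid alphabet, drops zero-count rows with a warning, and sums
#' duplicate (sequence, sample, time point) rows into a single record.
#'
#' @param path Path to a TSV file. Lines starting with `#` are ignored.
#' @param dialect A [clone_dialect()] mapping file columns to fields.
#' @return A tibble with columns `junction_aa`, `count`, `sample_id`,
#'   `time_point`, one row per unique (sequence, sample, time point).
#' @export
read_clone_table <- function(path, dialect = clone_dialect()) {
  if (!file.exists(path)) abort(paste0("clone table not found: ", path))
  raw <- .read_tsv_quiet(path)
  need <- unlist(dialect)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("clone table is missing mapped column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl <- tibble(
    junction_aa = as.character(raw[[dialect$junction_aa]]),
    count = raw[[dialect$count]],
    sample_id = as.character(raw[[dialect$sample_id]]),
    time_point = raw[[dialect$time_point]])
  validate_clone_table(tbl, n_read = nrow(raw))
}

#' Validate an in-memory clone table
#'
#' Applies the same contract as [read_clone_table()] to a data frame already
#' in canonical column layout: amino-acid validation, zero-count dropping,
#' duplicate aggregation, integer time points.
#'
#' @param clones Data frame with columns `junction_aa`, `count`, `sample_id`,
#'   `time_point`.
#' @param n_read Number of raw rows (for the load log); defaults to
#'   `nrow(clones)`.
#' @return A validated, aggregated tibble.
#' @export
validate_clone_table <- function(clones, n_read = nrow(clones)) {
  need <- c("junction_aa", "count", "sample_id", "time_point")
  missing_cols <- setdiff(need, names(clones))
  if (length(missing_cols) > 0) {
    abort(paste0("clone table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl <- as_tibble(clones)[need]
  bad <- which(!.is_valid_aa(tbl$junction_aa))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid amino-acid sequence at row %d: \"%s\"",
      bad[1], tbl$junction_aa[bad[1]]))
  }
  if (any(is.na(tbl$count)) || any(tbl$count < 0)) {
    abort("`count` must be non-negative and non-missing.")
  }
  if (any(tbl$count != floor(tbl$count))) {
    abort("`count` must be a whole number.")
  }
  if (any(is.na(tbl$time_point)) || any(tbl$time_point != floor(tbl$time_point)) ||
      any(tbl$time_point < 1)) {
    abort("`time_point` must be a positive integer index.")
  }
  tbl$time_point <- as.integer(tbl$time_point)
  n_zero <- sum(tbl$count == 0)
  if (n_zero > 0) {
    warn(sprintf("dropped %d zero-count clone row(s)", n_zero))
    tbl <- filter(tbl, .data$count > 0)
  }
  n_before <- nrow(tbl)
  tbl <- tbl |>
    group_by(.data$junction_aa, .data$sample_id, .data$time_point) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    select("junction_aa", "count", "sample_id", "time_point") |>
    arrange(.data$sample_id, .data$time_point, .data$junction_aa)
  inform(sprintf(
    "clone table: %d rows read, %d dropped (zero count), %d merged, %d records retained",
    n_read, n_zero, n_before - nrow(tbl), nrow(tbl)))
  tbl
}

.phenotype_levels <- c("healthy", "pre_cancer", "cancer")
.group_levels <- c("control", "transgenic")

#' Read and validate sample metadata
#'
#' One row per (sample, time point) with the sample's group
#' (`control`/`transgenic`) and the phenotype state at that time point
#' (`healthy`/`pre_cancer`/`cancer`). Control samples must be healthy at
#' every time point; within a transgenic sample the phenotype must progress
#' monotonically healthy -> pre_cancer -> cancer with no reversal.
#'
#' @param path Path to a TSV file with columns `sample_id`, `time_point`,
#'   `group`, `phenotype`.
#' @return A validated tibble with those four columns.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("metadata not found: ", path))
  raw <- .read_tsv_quiet(path)
  validate_sample_metadata(raw)
}

#' Validate in-memory sample metadata
#'
#' @param meta Data frame with columns `sample_id`, `time_point`, `group`,
#'   `phenotype`.
#' @return A validated tibble.
#' @rdname read_sample_metadata
#' @export
validate_sample_metadata <- function(meta) {
  need <- c("sample_id", "time_point", "group", "phenotype")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl <- as_tibble(meta)[need]
  tbl$sample_id <- as.character(tbl$sample_id)
  tbl$time_point <- as.integer(tbl$time_point)
  if (!all(tbl$group %in% .group_levels)) {
    abort("`group` must be one of: control, transgenic")
  }
  if (!all(tbl$phenotype %in% .phenotype_levels)) {
    abort("`phenotype` must be one of: healthy, pre_cancer, cancer")
  }
  if (anyDuplicated(tbl[c("sample_id", "time_point")]) > 0) {
    abort("metadata must have one row per (sample_id, time_point)")
  }
  by_sample <- split(tbl[order(tbl$time_point), ], tbl$sample_id[order(tbl$time_point)])
  for (s in names(by_sample)) {
    rows <- by_sample[[s]]
    grp <- unique(rows$group)
    if (length(grp) != 1) {
      abort(sprintf("sample %s has inconsistent group labels", s))
    }
    stage <- match(rows$phenotype, .phenotype_levels)
    if (grp == "control" && any(stage != 1)) {
      abort(sprintf("control sample %s must be healthy at every time point", s))
    }
    if (any(diff(stage) < 0)) {
      abort(sprintf(
        "sample %s: phenotype reverses over time (%s)", s,
        paste(rows$phenotype, collapse = " -> ")))
    }
  }
  arrange(tbl, .data$sample_id, .data$time_point)
}

.output_header <- function(kind, config_hash = NULL) {
  ver <- as.character(utils::packageVersion("cloneattractor"))
  c(sprintf("# cloneattractor v%s :: %s", ver, kind),
    if (!is.null(config_hash)) sprintf("# config_hash: %s", config_hash))
}

.write_tsv_commented <- function(tbl, path, kind, config_hash = NULL) {
  writeLines(.output_header(kind, config_hash), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Write / read an attractor table
#'
#' Serializes the member-level view of an [attractor set][cluster_repertoire]
#' (one row per member sequence: `ca_id`, `representative`, `junction_aa`,
#' `count`) as TSV with a `#`-prefixed comment header. The reader
#' reconstructs the attractor tibble; writer/reader form a round-trip
#' identity on the member table.
#'
#' @param aset A `ca_attractor_set` from [cluster_repertoire()].
#' @param path Output path.
#' @param config_hash Optional configuration digest recorded in the header.
#' @return `write_attractor_table()` returns `path` invisibly;
#'   `read_attractor_table()` returns a list with `members` (tibble) and
#'   `attractors` (tibble of `ca_id`, `representative`, `size`,
#'   `total_count`).
#' @export
write_attractor_table <- function(aset, path, config_hash = NULL) {
  members <- if (inherits(aset, "ca_attractor_set")) aset$members else as_tibble(aset)
  need <- c("ca_id", "representative", "junction_aa", "count")
  stopifnot(all(need %in% names(members)))
  .write_tsv_commented(members[need], path, "attractor table", config_hash)
}

#' @rdname write_attractor_table
#' @export
read_attractor_table <- function(path) {
  members <- .read_tsv_quiet(
    path, col_types = readr::cols(
      ca_id = readr::col_integer(), representative = readr::col_character(),
      junction_aa = readr::col_character(), count = readr::col_double()))
  attractors <- members |>
    group_by(.data$ca_id, .data$representative) |>
    summarise(size = n(), total_count = sum(.data$count), .groups = "drop") |>
    arrange(.data$ca_id)
  list(members = members, attractors = attractors)
}

#' Write / read an activity matrix
#'
#' The activity matrix holds one amplitude per (attractor, sample, time
#' point); a combination absent from the data is inactivity and is written
#' as an explicit 0, never as a missing value. Stored long-format TSV
#' (`ca_id`, `sample_id`, `time_point`, `amplitude`).
#'
#' @param activity Activity tibble from [attractor_activity()].
#' @param path Output path.
#' @param config_hash Optional configuration digest recorded in the header.
#' @return The path (write) or the activity tibble (read).
#' @export
write_activity_matrix <- function(activity, path, config_hash = NULL) {
  need <- c("ca_id", "sample_id", "time_point", "amplitude")
  stopifnot(all(need %in% names(activity)))
  .write_tsv_commented(as_tibble(activity)[need], path, "activity matrix",
                       config_hash)
}

#' @rdname write_activity_matrix
#' @export
read_activity_matrix <- function(path) {
  .read_tsv_quiet(
    path, col_types = readr::cols(
      ca_id = readr::col_integer(), sample_id = readr::col_character(),
      time_point = readr::col_integer(), amplitude = readr::col_double()))
}
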