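#' Match attractors against a public TCR sequence table
#'
#' For every database sequence, computes the minimum edit distance to any
#' attractor representative and buckets hits at distance 0 (identical to a
#' representative) and distance 1 (one edit away). Distance-1 hits are
#' additionally checked for identity with a member of the matched attractor
#' — a database sequence that is not itself a representative may still be an
#' observed member. Ties (several representatives at the same minimal
#' distance) are all reported. Database annotation columns are passed
#' through untouched.
#'
#' The default metric counts edit operations (`"unit_edit"`: any single
#' insertion, deletion or substitution is distance 1), which is how
#' near-identity to curated sequences is usually stated; `"weighted"` uses
#' the package's weighted scale instead, with buckets d = 0 and
#' d <= substitution cost.
#'
#' @param aset A `ca_attractor_set` (typically restricted to the filtered
#'   attractors via `ca_ids`).
#' @param db A data frame of database sequences; `seq_col` names the
#'   CDR3 amino-acid column. Invalid sequences are dropped with a warning.
#' @param seq_col Name of the sequence column in `db` (default `"cdr3"`).
#' @param metric `"unit_edit"` (default) or `"weighted"`.
#' @param ca_ids Optional vector of attractor ids to match against (e.g.
#'   `filter_attractors(...)$ca_id`); default all.
#' @param weights [edit_weights()] used when `metric = "weighted"`.
#' @return An object of class `ca_match`: `hits` (tibble: db row, sequence,
#'   `ca_id`, `distance`, `member_identity`, annotations) and a `summary`
#'   tibble (`n_db`, `n_distance0`, `n_distance1`, `n_member_identity`).
#' @export
match_public <- function(aset, db, seq_col = "cdr3",
                         metric = c("unit_edit", "weighted"),
                         ca_ids = NULL, weights = edit_weights()) {
  stopifnot(inherits(aset, "ca_attractor_set"))
  metric <- match.arg(metric)
  if (!seq_col %in% names(db)) {
    abort(sprintf("database has no column \"%s\"", seq_col))
  }
  db <- as_tibble(db)
  db$.db_row <- seq_len(nrow(db))
  valid <- .is_valid_aa(db[[seq_col]])
  if (any(!valid)) {
    warn(sprintf("dropped %d database row(s) with invalid sequences",
                 sum(!valid)))
    db <- db[valid, ]
  }
  attractors <- aset$attractors
  members <- aset$members
  if (!is.null(ca_ids)) {
    attractors <- filter(attractors, .data$ca_id %in% ca_ids)
    members <- filter(members, .data$ca_id %in% ca_ids)
  }
  empty_summary <- tibble(n_db = nrow(db), n_distance0 = 0L,
                          n_distance1 = 0L, n_member_identity = 0L)
  if (nrow(db) == 0 || nrow(attractors) == 0) {
    return(structure(list(hits = tibble(), summary = empty_summary,
                          metric = metric),
                     class = "ca_match"))
  }

  if (metric == "unit_edit") {
    w <- edit_weights(1, 1, 1, lambda = 1)
    bucket1 <- 1
  } else {
    w <- weights
    bucket1 <- w$substitution  # one operation of any kind on this scale
  }
  d <- .wl_cross_cpp(db[[seq_col]], attractors$representative,
                     w$deletion, w$insertion, w$substitution)
  dmin <- apply(d, 1, min)
  hit_rows <- which(dmin <= bucket1 + .wl_tol)
  hits <- purrr::map(hit_rows, function(i) {
    js <- which(d[i, ] <= dmin[i] + .wl_tol)  # report all equidistant ties
    tibble(.db_row = db$.db_row[i],
           db_sequence = db[[seq_col]][i],
           ca_id = attractors$ca_id[js],
           distance = dmin[i])
  }) |> bind_rows()
  if (nrow(hits) > 0) {
    member_key <- paste(members$ca_id, members$junction_aa)
    hits$member_identity <- hits$distance > .wl_tol &
      paste(hits$ca_id, hits$db_sequence) %in% member_key
    anno <- db[setdiff(names(db), seq_col)]
    hits <- left_join(hits, anno, by = ".db_row")
  } else {
    hits$member_identity <- logical(0)
  }
  by_db <- if (nrow(hits) > 0) distinct(hits, .data$.db_row, .data$distance,
                                        .data$member_identity) else hits
  n0 <- if (nrow(by_db) > 0) length(unique(by_db$.db_row[by_db$distance <= .wl_tol])) else 0L
  n1 <- if (nrow(by_db) > 0) length(unique(by_db$.db_row[by_db$distance > .wl_tol])) else 0L
  nm <- if (nrow(hits) > 0)
    length(unique(hits$.db_row[hits$member_identity])) else 0L
  structure(
    list(hits = hits,
         summary = tibble(n_db = nrow(db), n_distance0 = n0,
                          n_distance1 = n1, n_member_identity = nm),
         metric = metric),
    class = "ca_match")
}

#' @export
print.ca_match <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<ca_match> (%s metric) %d db sequences: %d at distance 0, %d at distance 1 (%d of those identical to a member)\n",
    x$metric, s$n_db, s$n_distance0, s$n_distance1, s$n_member_identity))
  invisible(x)
}

#' @export
#' @method tidy ca_match
tidy.ca_match <- function(x, ...) x$hits

#' @export
#' @method glance ca_match
glance.ca_match <- function(x, ...) x$summary
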