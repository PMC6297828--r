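#' Greedy Clone-Attractor clustering of a repertoire
#'
#' Partitions the unique CDR3 sequences of a repertoire into Clone-Attractors
#' (CAs) in a single greedy pass, in the style of UCLUST-like representative
#' clustering. Sequences are processed sorted by ascending length (ties:
#' lexicographic). Each sequence is compared to the representatives of the
#' clusters created so far, in creation order:
#'
#' * `strategy = "first_fit"` (default): the sequence joins the first cluster
#'   whose representative lies within `weights$lambda` ("winner takes all");
#' * `strategy = "nearest_fit"`: it joins the closest such cluster (ties go
#'   to the earliest-created cluster).
#'
#' If no representative is within `lambda`, the sequence founds a new cluster
#' with itself as representative. After every association the cluster
#' representative is refreshed to the medoid: the member minimizing the sum
#' of weighted distances to all other members (ties: shorter sequence, then
#' lexicographic). The pass is fully deterministic for a given input multiset.
#'
#' @param clones A clone table (tibble with at least `junction_aa` and
#'   `count`; extra columns such as `sample_id`/`time_point` are allowed and
#'   ignored here) or a character vector of sequences (counts taken as 1).
#' @param weights An [edit_weights()] object; `weights$lambda` is the
#'   association threshold.
#' @param strategy `"first_fit"` or `"nearest_fit"` (see Details).
#' @return An object of class `ca_attractor_set`: a list with
#'   * `attractors`: tibble `ca_id`, `representative`, `size` (number of
#'     member sequences), `total_count`;
#'   * `members`: tibble `ca_id`, `representative`, `junction_aa`, `count`;
#'   * `association_log`: tibble in processing order (`order`, `junction_aa`,
#'     `ca_id`, `distance`, `founded`), where `distance` is the distance to
#'     the then-current representative at the moment of association;
#'   * `weights`, `strategy`.
#' @examples
#' cluster_repertoire(c("CASSPGTDTQYF", "CASSPLTDTQYF", "CASSPQTDTQYF"))
#' @export
cluster_repertoire <- function(clones, weights = edit_weights(),
                               strategy = c("first_fit", "nearest_fit")) {
  .check_weights(weights)
  strategy <- match.arg(strategy)
  if (is.character(clones)) {
    clones <- tibble(junction_aa = clones, count = 1)
  }
  stopifnot(all(c("junction_aa", "count") %in% names(clones)))
  uniq <- as_tibble(clones) |>
    group_by(.data$junction_aa) |>
    summarise(count = sum(.data$count), .groups = "drop")
  if (nrow(uniq) == 0) {
    return(.new_attractor_set(
      attractors = tibble(ca_id = integer(), representative = character(),
                          size = integer(), total_count = numeric()),
      members = tibble(ca_id = integer(), representative = character(),
                       junction_aa = character(), count = numeric()),
      log = tibble(order = integer(), junction_aa = character(),
                   ca_id = integer(), distance = numeric(),
                   founded = logical()),
      weights = weights, strategy = strategy))
  }
  .check_aa(uniq$junction_aa, "clone table")
  ord <- order(nchar(uniq$junction_aa), uniq$junction_aa, method = "radix")
  uniq <- uniq[ord, ]

  res <- .greedy_cluster_cpp(uniq$junction_aa, weights$deletion,
                             weights$insertion, weights$substitution,
                             weights$lambda, strategy == "nearest_fit")
  assignment <- res$assignment
  reps <- uniq$junction_aa[res$rep_index]

  members <- tibble(
    ca_id = assignment,
    representative = reps[assignment],
    junction_aa = uniq$junction_aa,
    count = uniq$count) |>
    arrange(.data$ca_id, .data$junction_aa)
  attractors <- members |>
    group_by(.data$ca_id, .data$representative) |>
    summarise(size = n(), total_count = sum(.data$count), .groups = "drop") |>
    arrange(.data$ca_id)
  assoc_log <- tibble(
    order = seq_len(nrow(uniq)),
    junction_aa = uniq$junction_aa,
    ca_id = assignment,
    distance = res$assoc_distance,
    founded = res$assoc_distance == 0 & !duplicated(assignment))

  .new_attractor_set(attractors, members, assoc_log, weights, strategy)
}

.new_attractor_set <- function(attractors, members, log, weights, strategy) {
  structure(
    list(attractors = attractors, members = members, association_log = log,
         weights = weights, strategy = strategy),
    class = "ca_attractor_set")
}

#' @export
print.ca_attractor_set <- function(x, ...) {
  cat(sprintf(
    "<ca_attractor_set> %d attractors over %d unique sequences (strategy %s, lambda %g)\n",
    nrow(x$attractors), nrow(x$members), x$strategy, x$weights$lambda))
  cat("Largest attractors:\n")
  print(head(arrange(x$attractors, dplyr::desc(.data$size)), 5))
  invisible(x)
}

#' @export
#' @method tidy ca_attractor_set
tidy.ca_attractor_set <- function(x, ...) x$attractors

#' @export
#' @method glance ca_attractor_set
glance.ca_attractor_set <- function(x, ...) {
  tibble(
    n_attractors = nrow(x$attractors),
    n_sequences = nrow(x$members),
    total_count = sum(x$members$count),
    max_size = if (nrow(x$attractors)) max(x$attractors$size) else NA_integer_,
    lambda = x$weights$lambda,
    strategy = x$strategy)
}

#' Medoid representative of a set of member sequences
#'
#' Returns the member minimizing the summed weighted edit distance to all
#' other members; ties are broken by shorter length, then lexicographic
#' order. This is the representative-update rule applied after every
#' association during [cluster_repertoire()], exposed for inspection.
#'
#' @param members Character vector of member sequences (non-empty).
#' @param weights An [edit_weights()] object.
#' @return A single sequence, the medoid.
#' @export
update_representative <- function(members, weights = edit_weights()) {
  .check_weights(weights)
  if (length(members) == 0) abort("`members` must be non-empty.")
  .check_aa(members, "members")
  if (length(members) == 1) return(members)
  d <- .wl_cross(members, members, weights)
  sums <- rowSums(d)
  ord <- order(sums, nchar(members), members, method = "radix")
  members[ord[1]]
}

#' Clone-Attractor activity matrix
#'
#' The amplitude of a Clone-Attractor in a (sample, time point) is the sum of
#' its member sequences' counts observed there. Combinations where no member
#' was observed get amplitude 0 (inactivity), never a missing value, over the
#' complete grid of attractors x observed (sample, time point) columns.
#'
#' @param aset A `ca_attractor_set` from [cluster_repertoire()].
#' @param clones The clone table whose sequences were clustered (every
#'   sequence must belong to an attractor).
#' @return A tibble `ca_id`, `sample_id`, `time_point`, `amplitude` covering
#'   the full grid.
#' @export
attractor_activity <- function(aset, clones) {
  stopifnot(inherits(aset, "ca_attractor_set"))
  need <- c("junction_aa", "count", "sample_id", "time_point")
  stopifnot(all(need %in% names(clones)))
  clones <- as_tibble(clones)
  lookup <- aset$members[c("junction_aa", "ca_id")]
  joined <- left_join(clones, lookup, by = "junction_aa")
  if (any(is.na(joined$ca_id))) {
    abort(sprintf(
      "%d clone record(s) are not members of any attractor (e.g. \"%s\"); cluster the same clone table first.",
      sum(is.na(joined$ca_id)), joined$junction_aa[which(is.na(joined$ca_id))[1]]))
  }
  observed <- joined |>
    group_by(.data$ca_id, .data$sample_id, .data$time_point) |>
    summarise(amplitude = sum(.data$count), .groups = "drop")
  grid <- tidyr::expand_grid(
    ca_id = aset$attractors$ca_id,
    distinct(clones, .data$sample_id, .data$time_point))
  grid |>
    left_join(observed, by = c("ca_id", "sample_id", "time_point")) |>
    mutate(amplitude = dplyr::coalesce(.data$amplitude, 0)) |>
    arrange(.data$ca_id, .data$sample_id, .data$time_point)
}
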