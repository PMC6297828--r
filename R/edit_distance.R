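#' Edit-operation weights for CDR3 comparison
#'
#' Container for the weighted Levenshtein costs used throughout the package:
#' cluster association, repertoire-graph edges, and (optionally) database
#' matching. The defaults (deletion = insertion = 1.1, substitution = 1.9,
#' association threshold lambda = 3) are chosen so that a sequence may join a
#' cluster when it differs from the representative by at most two
#' insertions/deletions (cost 2.2), or by one substitution plus at most one
#' indel (cost 3.0); two substitutions (cost 3.8) are already too far.
#'
#' @param deletion,insertion,substitution Positive per-operation costs.
#' @param lambda Positive association threshold on the weighted scale.
#' @param allow_asymmetric If `FALSE` (default), `deletion != insertion` is an
#'   error, since the resulting distance would not be symmetric. Set to `TRUE`
#'   to proceed anyway with a warning.
#'
#' @return An object of class `edit_weights`.
#' @examples
#' w <- edit_weights()
#' weighted_levenshtein("CASS", "CAS", w) # one deletion -> 1.1
#' @export
edit_weights <- function(deletion = 1.1, insertion = 1.1, substitution = 1.9,
                         lambda = 3, allow_asymmetric = FALSE) {
  vals <- c(deletion = deletion, insertion = insertion,
            substitution = substitution)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All edit weights must be positive and finite.")
  }
  if (!is.finite(lambda) || lambda < 0) {
    abort("`lambda` must be non-negative and finite.")
  }
  if (lambda < min(vals) && lambda > 0) {
    warn("`lambda` admits no single edit: only identical sequences associate.")
  }
  if (deletion != insertion) {
    if (!allow_asymmetric) {
      abort(paste0(
        "deletion (", deletion, ") != insertion (", insertion, ") makes the ",
        "distance asymmetric; set `allow_asymmetric = TRUE` to override."))
    }
    warn("deletion != insertion: the edit distance is not symmetric.")
  }
  structure(
    list(deletion = deletion, insertion = insertion,
         substitution = substitution, lambda = lambda),
    class = "edit_weights")
}

#' @export
print.edit_weights <- function(x, ...) {
  cat(sprintf(
    "<edit_weights> deletion=%g insertion=%g substitution=%g lambda=%g\n",
    x$deletion, x$insertion, x$substitution, x$lambda))
  invisible(x)
}

.check_weights <- function(weights) {
  if (!inherits(weights, "edit_weights")) {
    abort("`weights` must be created with `edit_weights()`.")
  }
  weights
}

.check_aa <- function(x, arg = "sequence") {
  bad <- which(!.is_valid_aa(x))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s contains %d invalid amino-acid string(s) (first at position %d: \"%s\"); expected non-empty uppercase strings over ACDEFGHIKLMNPQRSTVWY.",
      arg, length(bad), bad[1], as.character(x[bad[1]])))
  }
  invisible(x)
}

#' Weighted Levenshtein distance between CDR3 amino-acid sequences
#'
#' Minimal total cost of insertions, deletions and substitutions transforming
#' `a` into `b`, each operation carrying its own cost (Wagner-Fischer dynamic
#' programming; no transposition operation). Vectorized over pairs; `a` and
#' `b` are recycled to a common length.
#'
#' With symmetric indel costs the function is a metric: symmetric, zero only
#' on identical strings, and satisfying the triangle inequality.
#'
#' @param a,b Character vectors of uppercase amino-acid sequences. The empty
#'   string is permitted and costs `nchar(x) * insertion` to reach.
#' @param weights An [edit_weights()] object.
#' @return Numeric vector of distances.
#' @examples
#' weighted_levenshtein("CASSPGTDTQYF", "CASSPLTDTQYF") # one substitution
#' @export
weighted_levenshtein <- function(a, b, weights = edit_weights()) {
  .check_weights(weights)
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  ok <- (.is_valid_aa(a) | a == "") & (.is_valid_aa(b) | b == "")
  if (!all(ok)) {
    abort(sprintf("invalid amino-acid string at position %d", which(!ok)[1]))
  }
  .wl_pairwise_cpp(a, b, weights$deletion, weights$insertion,
                   weights$substitution)
}

#' Weighted Levenshtein distance with an early-exit cutoff
#'
#' Computes the same distance as [weighted_levenshtein()] but abandons the
#' dynamic program as soon as the distance provably exceeds `cutoff`,
#' returning `Inf` for such pairs. Exact whenever the true distance is at
#' most `cutoff`; used for cluster association and neighbour scans where only
#' near pairs matter.
#'
#' @inheritParams weighted_levenshtein
#' @param cutoff Positive cutoff on the weighted scale.
#' @return Numeric vector: the distance where it is `<= cutoff`, `Inf`
#'   elsewhere.
#' @export
distance_within <- function(a, b, weights = edit_weights(), cutoff) {
  .check_weights(weights)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    abort("`cutoff` must be a single positive number.")
  }
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  d <- .wl_bounded_cpp(a, b, weights$deletion, weights$insertion,
                       weights$substitution, cutoff)
  d[d < 0] <- Inf
  d
}

# All-pairs rep-to-rep distances as a dense matrix (small inputs only).
.wl_cross <- function(a, b, weights) {
  .wl_cross_cpp(a, b, weights$deletion, weights$insertion,
                weights$substitution)
}
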