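#' Configuration of the two-stage classification pipeline
#'
#' @param active_fraction A feature (attractor) is kept when it is active
#'   (amplitude > 0) in strictly more than this fraction of data points
#'   (default 0.95).
#' @param top_k Number of top-scoring feature subsets retained per dimension
#'   during forward selection (default 50).
#' @param dims Candidate model dimensions compared by noise-averaged AUC
#'   (default `3:8`); forward selection always starts from pairs.
#' @param ensemble_size Number of machines in the committee (default 10).
#' @param kernel Kernel of the soft-margin machine; `"gaussian"` (radial
#'   basis) is the only supported value.
#' @param noise_amplitudes Multiplicative noise standard deviations used for
#'   robustness evaluation (default `seq(0, 0.25, by = 0.05)`).
#' @param seed Integer seed controlling every stochastic step.
#' @param cost Soft-margin penalty C of the machine (default 1).
#' @param gamma Kernel width parameter; `NULL` (default) uses the median
#'   heuristic on the (scaled) training features.
#' @param normalize If `TRUE`, convert each data point's amplitudes to
#'   relative abundances before classification; default `FALSE` (raw
#'   amplitudes).
#' @param activity_scope `"point"` (default): `active_fraction` is evaluated
#'   over (sample, time point) data points; `"sample"`: over samples, a
#'   feature counting as active in a sample when active at any of its time
#'   points.
#' @param loocv_unit `"point"` (default) leaves out one (sample, time point)
#'   at a time; `"sample"` leaves out all points of one sample at a time
#'   (avoids leakage across a subject's time points).
#' @return An object of class `ml_config`.
#' @export
ml_config <- function(active_fraction = 0.95, top_k = 50, dims = 3:8,
                      ensemble_size = 10, kernel = "gaussian",
                      noise_amplitudes = seq(0, 0.25, by = 0.05),
                      seed = 1, cost = 1, gamma = NULL, normalize = FALSE,
                      activity_scope = c("point", "sample"),
                      loocv_unit = c("point", "sample")) {
  if (active_fraction <= 0 || active_fraction > 1) {
    abort("`active_fraction` must be in (0, 1].")
  }
  if (ensemble_size < 1) abort("`ensemble_size` must be >= 1.")
  if (any(noise_amplitudes < 0)) abort("`noise_amplitudes` must be >= 0.")
  if (!identical(kernel, "gaussian")) {
    abort("only the gaussian (radial) kernel is supported.")
  }
  structure(
    list(active_fraction = active_fraction, top_k = top_k,
         dims = sort(unique(as.integer(dims))),
         ensemble_size = as.integer(ensemble_size), kernel = kernel,
         noise_amplitudes = noise_amplitudes, seed = as.integer(seed),
         cost = cost, gamma = gamma,
         normalize = isTRUE(normalize),
         activity_scope = match.arg(activity_scope),
         loocv_unit = match.arg(loocv_unit)),
    class = "ml_config")
}

.meta_cols <- c("sample_id", "time_point", "label")

#' Build the (data point x attractor) feature matrix
#'
#' Rows are (sample, time point) data points, columns are attractor
#' amplitudes (named `ca_<id>`), plus a `label` column. Stage 1
#' (`stage = "group"`) labels every point by its sample's group
#' (control/transgenic); stage 2 (`stage = "phenotype"`) keeps only
#' transgenic points whose phenotype is pre_cancer or cancer and labels them
#' by phenotype. Inactivity is encoded as amplitude 0 — the matrix has no
#' missing values.
#'
#' @param activity Activity tibble from [attractor_activity()].
#' @param metadata Validated metadata tibble (see [read_sample_metadata()]).
#' @param stage `"group"` or `"phenotype"`.
#' @return A tibble `sample_id`, `time_point`, `label` (factor, positive
#'   class last), then one `ca_*` column per attractor.
#' @export
feature_matrix <- function(activity, metadata, stage = c("group", "phenotype")) {
  stage <- match.arg(stage)
  wide <- activity |>
    mutate(feature = paste0("ca_", .data$ca_id)) |>
    select("sample_id", "time_point", "feature", "amplitude") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "amplitude",
                       values_fill = 0)
  joined <- inner_join(wide, metadata, by = c("sample_id", "time_point"))
  if (nrow(joined) < nrow(wide)) {
    warn(sprintf("%d data point(s) without metadata were dropped",
                 nrow(wide) - nrow(joined)))
  }
  if (stage == "group") {
    joined$label <- factor(joined$group, levels = .group_levels)
  } else {
    joined <- filter(joined, .data$group == "transgenic",
                     .data$phenotype %in% c("pre_cancer", "cancer"))
    joined$label <- factor(joined$phenotype,
                           levels = c("pre_cancer", "cancer"))
  }
  ca_cols <- grep("^ca_", names(joined), value = TRUE)
  out <- joined[c(.meta_cols, ca_cols)]
  arrange(out, .data$sample_id, .data$time_point)
}

.feature_cols <- function(features) {
  grep("^ca_", names(features), value = TRUE)
}

.feature_x <- function(features, cols = .feature_cols(features),
                       normalize = FALSE) {
  x <- as.matrix(features[cols])
  storage.mode(x) <- "double"
  if (normalize) {
    tot <- rowSums(as.matrix(features[.feature_cols(features)]))
    tot[tot == 0] <- 1
    x <- x / tot
  }
  x
}

#' Keep only features active across (almost) all data points
#'
#' Retains attractor columns whose amplitude is positive in strictly more
#' than `active_fraction` of the rows (or of the samples, under
#' `activity_scope = "sample"`), and logs the resulting dimensionality.
#'
#' @param features Feature tibble from [feature_matrix()].
#' @param config An [ml_config()].
#' @return The feature tibble restricted to the retained columns.
#' @export
active_feature_filter <- function(features, config = ml_config()) {
  cols <- .feature_cols(features)
  if (length(cols) == 0) abort("no feature columns (ca_*) present.")
  if (config$activity_scope == "point") {
    frac <- colMeans(as.matrix(features[cols]) > 0)
  } else {
    by_sample <- features |>
      group_by(.data$sample_id) |>
      summarise(across(dplyr::all_of(cols), ~ any(.x > 0)), .groups = "drop")
    frac <- colMeans(as.matrix(by_sample[cols]))
  }
  keep <- cols[frac > config$active_fraction]
  if (length(keep) == 0) {
    abort(sprintf(
      "no feature is active in more than %.0f%% of data points; lower `active_fraction`.",
      100 * config$active_fraction))
  }
  inform(sprintf("active-feature filter: %d of %d attractors retained",
                 length(keep), length(cols)))
  features[c(.meta_cols, keep)]
}

.median_heuristic_gamma <- function(x) {
  xs <- scale(x)
  xs[is.nan(xs)] <- 0
  n <- nrow(xs)
  if (n > 200) xs <- xs[seq(1, n, length.out = 200), , drop = FALSE]
  med <- median(stats::dist(xs))
  if (!is.finite(med) || med <= 0) return(1 / ncol(x))
  1 / (2 * med^2)
}

.balanced_weights <- function(y) {
  tb <- table(y)
  setNames(as.numeric(sum(tb) / (length(tb) * tb)), names(tb))
}

# Soft-margin gaussian-kernel machine. Classes are inversely weighted by
# frequency: the study design is imbalanced (fewer control than transgenic
# points) and unweighted margins would bias every fold toward the majority.
.fit_svm <- function(x, y, config, gamma = NULL, ...) {
  gamma <- gamma %||% config$gamma %||% .median_heuristic_gamma(x)
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             gamma = gamma, cost = config$cost, scale = TRUE,
             class.weights = .balanced_weights(y), ...)
}

#' Leave-one-out cross-validated accuracy of a kernel machine
#'
#' Fraction of data points correctly classified when each point (or each
#' sample, under `loocv_unit = "sample"`) is held out once; the classifier
#' is a soft-margin support-vector machine with gaussian kernel
#' (median-heuristic bandwidth unless `config$gamma` is set).
#'
#' @param features Feature tibble (all `ca_*` columns are used).
#' @param config An [ml_config()].
#' @return A number in `[0, 1]`.
#' @export
loocv_score <- function(features, config = ml_config()) {
  y <- features$label
  if (length(unique(y)) < 2) {
    abort("LOOCV needs both classes present.")
  }
  x <- .feature_x(features, normalize = config$normalize)
  .loocv_score_xy(x, y, features$sample_id, config)
}

.loocv_score_xy <- function(x, y, sample_id, config) {
  gamma <- config$gamma %||% .median_heuristic_gamma(x)
  if (config$loocv_unit == "point") {
    m <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    gamma = gamma, cost = config$cost, scale = TRUE,
                    class.weights = .balanced_weights(y), cross = nrow(x))
    return(m$tot.accuracy / 100)
  }
  samples <- unique(sample_id)
  correct <- 0
  for (s in samples) {
    hold <- sample_id == s
    if (length(unique(y[!hold])) < 2) {
      abort("leave-one-sample-out fold with a single training class.")
    }
    m <- e1071::svm(x[!hold, , drop = FALSE], y[!hold],
                    type = "C-classification", kernel = "radial",
                    gamma = gamma, cost = config$cost, scale = TRUE,
                    class.weights = .balanced_weights(y[!hold]))
    correct <- correct + sum(predict(m, x[hold, , drop = FALSE]) == y[hold])
  }
  correct / length(y)
}

#' Forward feature selection with LOOCV ranking
#'
#' Bottom-up subset search: all feature pairs are scored by LOOCV accuracy
#' and the best `top_k` retained; each retained d-subset is then extended by
#' every unused feature, extensions are deduplicated as sets, scored, and
#' the best `top_k` kept — repeated until the best score stops improving
#' (by more than 1e-6) or the upper dimension bound `max(config$dims)` is
#' reached. Ties are broken by score (descending), then by the
#' lexicographic order of the sorted feature names.
#'
#' @param features Feature tibble (after [active_feature_filter()]); must
#'   have at least 2 feature columns and fewer than 100 (pairs must be
#'   enumerable).
#' @param config An [ml_config()].
#' @return A tibble `dim`, `rank`, `score`, `features` (list column of
#'   feature-name vectors), of class `ca_selection`.
#' @export
forward_selection <- function(features, config = ml_config()) {
  cols <- .feature_cols(features)
  if (length(cols) < 2) abort("forward selection needs at least 2 features.")
  if (length(cols) >= 100) {
    abort("too many features for pair enumeration; tighten the active filter.")
  }
  y <- features$label
  if (length(unique(y)) < 2) abort("forward selection needs both classes.")
  xall <- .feature_x(features, normalize = config$normalize)
  colnames(xall) <- cols
  sample_id <- features$sample_id

  score_subset <- function(subset) {
    .loocv_score_xy(xall[, subset, drop = FALSE], y, sample_id, config)
  }
  rank_candidates <- function(cand_list) {
    scores <- purrr::map_dbl(cand_list, score_subset)
    keys <- purrr::map_chr(cand_list, paste, collapse = "|")
    ord <- order(-scores, keys, method = "radix")
    keep <- ord[seq_len(min(config$top_k, length(ord)))]
    list(subsets = cand_list[keep], scores = scores[keep])
  }

  pairs <- combn(cols, 2, simplify = FALSE)
  pairs <- purrr::map(pairs, sort)
  level <- rank_candidates(pairs)
  out <- list(tibble(
    dim = 2L, rank = seq_along(level$scores), score = level$scores,
    features = level$subsets))
  best_prev <- level$scores[1]
  d <- 2L
  max_dim <- min(max(config$dims), length(cols))
  while (d < max_dim) {
    cand <- purrr::map(level$subsets, function(s) {
      purrr::map(setdiff(cols, s), function(f) sort(c(s, f)))
    })
    cand <- purrr::flatten(cand)
    keys <- purrr::map_chr(cand, paste, collapse = "|")
    cand <- cand[!duplicated(keys)]
    level <- rank_candidates(cand)
    d <- d + 1L
    out[[length(out) + 1]] <- tibble(
      dim = d, rank = seq_along(level$scores), score = level$scores,
      features = level$subsets)
    if (level$scores[1] <= best_prev + 1e-6) break
    best_prev <- level$scores[1]
  }
  res <- bind_rows(out)
  class(res) <- c("ca_selection", class(res))
  res
}

#' Train a committee of kernel machines on ranked feature subsets
#'
#' The i-th machine is trained on the i-th ranked subset at the requested
#' dimension; the ensemble output for a data point is the mean of the
#' machines' continuous outputs, each calibrated to `[0, 1]` by a logistic
#' link on the SVM decision value (oriented so that larger means more
#' likely the positive class, the last factor level of the labels).
#'
#' @param features Feature tibble used for training.
#' @param selection Output of [forward_selection()].
#' @param dim Model dimension to use (must be present in `selection`).
#' @param config An [ml_config()]. If fewer than `ensemble_size` subsets are
#'   available at `dim`, all are used with a warning.
#' @return An object of class `ca_ensemble`.
#' @export
train_ensemble <- function(features, selection, dim, config = ml_config()) {
  sel <- filter(selection, .data$dim == !!dim)
  if (nrow(sel) == 0) abort(sprintf("no subsets of dimension %d in `selection`.", dim))
  m <- config$ensemble_size
  if (nrow(sel) < m) {
    warn(sprintf("only %d subsets available at dim %d (requested %d machines)",
                 nrow(sel), dim, m))
    m <- nrow(sel)
  }
  subsets <- sel$features[seq_len(m)]
  y <- features$label
  positive <- levels(y)[nlevels(y)]
  xall <- .feature_x(features, normalize = config$normalize)
  colnames(xall) <- .feature_cols(features)
  machines <- purrr::map(subsets, function(s) {
    .fit_svm(xall[, s, drop = FALSE], y, config)
  })
  structure(
    list(machines = machines, subsets = subsets, positive = positive,
         levels = levels(y), dim = as.integer(dim), config = config,
         normalize = config$normalize),
    class = "ca_ensemble")
}

#' @export
print.ca_ensemble <- function(x, ...) {
  cat(sprintf(
    "<ca_ensemble> %d gaussian-kernel machines on %d-feature subsets; positive class: %s\n",
    length(x$machines), x$dim, x$positive))
  invisible(x)
}

#' @export
#' @method tidy ca_ensemble
tidy.ca_ensemble <- function(x, ...) {
  tibble(machine = seq_along(x$machines),
         features = purrr::map_chr(x$subsets, paste, collapse = ","))
}

.machine_score <- function(machine, x, positive) {
  p <- predict(machine, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  # libsvm labels the decision column "A/B": positive values favor class A
  fav <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  s <- if (identical(fav, positive)) 1 else -1
  stats::plogis(s * dv[, 1])
}

#' Ensemble score for new data points
#'
#' Mean of the committee members' calibrated outputs; values near 1 favor
#' the positive class.
#'
#' @param ensemble A `ca_ensemble`.
#' @param features Feature tibble containing at least the columns the
#'   machines were trained on.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
ensemble_score <- function(ensemble, features) {
  cols <- .feature_cols(features)
  xall <- .feature_x(features, normalize = ensemble$normalize)
  colnames(xall) <- cols
  scores <- purrr::map(seq_along(ensemble$machines), function(i) {
    s <- ensemble$subsets[[i]]
    .machine_score(ensemble$machines[[i]], xall[, s, drop = FALSE],
                   ensemble$positive)
  })
  Reduce(`+`, scores) / length(scores)
}

#' Multiplicative gaussian perturbation of a feature matrix
#'
#' Each feature value x is replaced by `x * (1 + v)` with
#' `v ~ N(0, sigma^2)` drawn independently per entry; with `sigma = 0` the
#' data are returned unchanged. Reproducible for a given seed.
#'
#' @param features Feature tibble (only `ca_*` columns are perturbed).
#' @param sigma Noise amplitude (standard deviation of v), `>= 0`.
#' @param seed Integer seed.
#' @return The feature tibble with perturbed feature columns.
#' @export
perturb <- function(features, sigma, seed = 1) {
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (sigma == 0) return(features)
  cols <- .feature_cols(features)
  x <- as.matrix(features[cols])
  noise <- .with_seed(seed, matrix(rnorm(length(x), 0, sigma), nrow(x)))
  features[cols] <- as_tibble(x * (1 + noise), .name_repair = "minimal")
  features
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

#' Noise-robustness ROC evaluation of an ensemble
#'
#' For each noise amplitude sigma in `config$noise_amplitudes`, the
#' evaluation features are perturbed (see [perturb()]) while the machines
#' stay trained on clean data (test-time robustness), the committee scored,
#' and an ROC curve with trapezoidal AUC computed over score thresholds.
#' The noise-averaged AUC is the plain mean over the sigma grid.
#'
#' With the default `holdout = "sample"`, scores are cross-validated: the
#' committee's machines are refit with each sample's data points held out in
#' turn, and a point is always scored by machines that never saw its sample
#' — guarding both against resubstitution optimism and against leakage
#' across a subject's time points. `holdout = "none"` scores the ensemble's
#' own machines on the (perturbed) training data.
#'
#' @param ensemble A `ca_ensemble`.
#' @param features Evaluation feature tibble with `label`.
#' @param config An [ml_config()]; `config$seed` (offset per sigma) makes the
#'   perturbations reproducible.
#' @param operating_fpr If not `NULL`, report the (fpr, tpr) point of the
#'   worst-noise curve at this false-positive rate.
#' @param holdout `"sample"` (default, cross-validated scores) or `"none"`.
#' @return An object of class `ca_roc`: tibbles `auc` (per sigma) and
#'   `curves` (per sigma: fpr, tpr), `mean_auc`, `dim`, and optionally
#'   `operating_point`.
#' @export
evaluate_roc <- function(ensemble, features, config = ml_config(),
                         operating_fpr = NULL,
                         holdout = c("sample", "none")) {
  holdout <- match.arg(holdout)
  y <- features$label
  if (length(unique(y)) < 2) abort("ROC evaluation needs both classes.")
  resp <- as.integer(y == ensemble$positive)
  sigmas <- config$noise_amplitudes
  cols <- .feature_cols(features)
  noisy <- purrr::imap(sigmas, function(sg, k) {
    perturb(features, sg, seed = config$seed + 1000L * k)
  })

  if (holdout == "none") {
    score_mat <- vapply(noisy, function(nf) ensemble_score(ensemble, nf),
                        numeric(nrow(features)))
  } else {
    x_clean <- .feature_x(features, normalize = ensemble$normalize)
    colnames(x_clean) <- cols
    x_noisy <- purrr::map(noisy, function(nf) {
      xn <- .feature_x(nf, normalize = ensemble$normalize)
      colnames(xn) <- cols
      xn
    })
    score_mat <- matrix(0, nrow(features), length(sigmas))
    folds <- unique(features$sample_id)
    for (sub in ensemble$subsets) {
      for (f in folds) {
        hold <- features$sample_id == f
        if (length(unique(y[!hold])) < 2) {
          abort("a leave-one-sample-out fold has a single training class.")
        }
        m <- .fit_svm(x_clean[!hold, sub, drop = FALSE], y[!hold],
                      ensemble$config)
        for (k in seq_along(sigmas)) {
          score_mat[hold, k] <- score_mat[hold, k] +
            .machine_score(m, x_noisy[[k]][hold, sub, drop = FALSE],
                           ensemble$positive)
        }
      }
    }
    score_mat <- score_mat / length(ensemble$subsets)
  }

  per_sigma <- purrr::map(seq_along(sigmas), function(k) {
    r <- pROC::roc(response = resp, predictor = score_mat[, k],
                   levels = c(0, 1), direction = "<", quiet = TRUE)
    curve <- tibble(sigma = sigmas[k],
                    fpr = rev(1 - r$specificities),
                    tpr = rev(r$sensitivities))
    list(auc = as.numeric(pROC::auc(r)), curve = curve)
  })
  auc_tbl <- tibble(sigma = sigmas,
                    auc = purrr::map_dbl(per_sigma, "auc"))
  curves <- bind_rows(purrr::map(per_sigma, "curve"))
  out <- list(auc = auc_tbl, curves = curves,
              mean_auc = mean(auc_tbl$auc), dim = ensemble$dim,
              holdout = holdout)
  if (!is.null(operating_fpr)) {
    worst <- filter(curves, .data$sigma == max(sigmas),
                    .data$fpr <= operating_fpr + 1e-12)
    out$operating_point <- if (nrow(worst) == 0) c(fpr = 0, tpr = 0) else
      c(fpr = max(worst$fpr), tpr = max(worst$tpr[worst$fpr == max(worst$fpr)]))
  }
  structure(out, class = "ca_roc")
}

#' @export
print.ca_roc <- function(x, ...) {
  cat(sprintf("<ca_roc> dim = %d, noise-averaged AUC = %.3f\n",
              x$dim, x$mean_auc))
  print(x$auc)
  invisible(x)
}

#' @export
#' @method tidy ca_roc
tidy.ca_roc <- function(x, ...) x$curves

#' @export
#' @method glance ca_roc
glance.ca_roc <- function(x, ...) {
  tibble(dim = x$dim, mean_auc = x$mean_auc,
         auc_sigma0 = x$auc$auc[x$auc$sigma == min(x$auc$sigma)][1])
}

#' Two-stage Clone-Attractor classification
#'
#' Runs the full pipeline twice: stage 1 separates control from transgenic
#' over all data points; stage 2 separates pre-cancer from cancer within the
#' transgenic points. Each stage applies the active-feature filter, forward
#' selection, trains one committee per candidate dimension, and selects the
#' dimension with the highest noise-averaged AUC (ties go to the smaller
#' dimension). The two selected feature lists and their Jaccard overlap are
#' reported.
#'
#' @param activity Activity tibble from [attractor_activity()].
#' @param metadata Validated metadata tibble.
#' @param config An [ml_config()].
#' @return An object of class `ca_two_stage`: per stage the selection table,
#'   the chosen ensemble and its `ca_roc`, plus `feature_overlap` (Jaccard
#'   index of the two stages' ensemble feature lists).
#' @export
two_stage_classify <- function(activity, metadata, config = ml_config()) {
  metadata <- validate_sample_metadata(metadata)
  stage1 <- .run_stage(activity, metadata, "group", config)
  stage2 <- tryCatch(
    .run_stage(activity, metadata, "phenotype", config),
    error = function(e) {
      warn(paste0("stage 2 skipped: ", conditionMessage(e)))
      NULL
    })
  overlap <- if (!is.null(stage2)) {
    f1 <- unique(unlist(stage1$ensemble$subsets))
    f2 <- unique(unlist(stage2$ensemble$subsets))
    length(intersect(f1, f2)) / length(union(f1, f2))
  } else NA_real_
  structure(list(stage1 = stage1, stage2 = stage2,
                 feature_overlap = overlap, config = config),
            class = "ca_two_stage")
}

.run_stage <- function(activity, metadata, stage, config) {
  feats <- feature_matrix(activity, metadata, stage = stage)
  if (nlevels(droplevels(feats$label)) < 2) {
    abort(sprintf("stage '%s' has a single class; cannot train.", stage))
  }
  feats <- active_feature_filter(feats, config)
  selection <- forward_selection(feats, config)
  dims_avail <- intersect(config$dims, unique(selection$dim))
  if (length(dims_avail) == 0) dims_avail <- max(selection$dim)
  fits <- purrr::map(dims_avail, function(d) {
    ens <- train_ensemble(feats, selection, d, config)
    roc <- evaluate_roc(ens, feats, config)
    list(ensemble = ens, roc = roc)
  })
  mean_aucs <- purrr::map_dbl(fits, ~ .x$roc$mean_auc)
  # ties (within 1e-9) go to the smaller dimension; dims_avail is sorted
  best <- which(mean_aucs >= max(mean_aucs) - 1e-9)[1]
  chosen <- fits[[best]]
  list(stage = stage, features = feats, selection = selection,
       dims = tibble(dim = dims_avail, mean_auc = mean_aucs),
       chosen_dim = dims_avail[best],
       ensemble = chosen$ensemble, roc = chosen$roc,
       selected_features = unique(unlist(chosen$ensemble$subsets)))
}

#' @export
print.ca_two_stage <- function(x, ...) {
  cat("<ca_two_stage>\n")
  cat(sprintf("  stage 1 (control vs transgenic): dim = %d, noise-averaged AUC = %.3f\n",
              x$stage1$chosen_dim, x$stage1$roc$mean_auc))
  if (!is.null(x$stage2)) {
    cat(sprintf("  stage 2 (pre-cancer vs cancer):  dim = %d, noise-averaged AUC = %.3f\n",
                x$stage2$chosen_dim, x$stage2$roc$mean_auc))
    cat(sprintf("  feature overlap (Jaccard): %.2f\n", x$feature_overlap))
  } else {
    cat("  stage 2: skipped\n")
  }
  invisible(x)
}

#' @export
#' @method glance ca_two_stage
glance.ca_two_stage <- function(x, ...) {
  tibble(
    stage1_dim = x$stage1$chosen_dim,
    stage1_mean_auc = x$stage1$roc$mean_auc,
    stage2_dim = if (!is.null(x$stage2)) x$stage2$chosen_dim else NA_integer_,
    stage2_mean_auc = if (!is.null(x$stage2)) x$stage2$roc$mean_auc else NA_real_,
    feature_overlap = x$feature_overlap)
}
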