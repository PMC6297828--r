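# Shared fixtures. The default benchmark (study design: 5 control + 10
# transgenic samples, 8 time points) is expensive enough to cache across
# test files; everything is rebuilt from a fixed seed, never stored on disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# Default-config benchmark run through clustering and activity.
default_run <- function(seed = 101) {
  cached(paste0("run_", seed), {
    sim <- simulate_repertoire(sim_config(), seed = seed)
    aset <- suppressMessages(cluster_repertoire(sim$clones))
    activity <- attractor_activity(aset, sim$clones)
    list(sim = sim, aset = aset, activity = activity)
  })
}

# A small, quick ML configuration used where the classifier mechanics --
# not the full search budget -- are under test.
quick_ml_config <- function(...) {
  ml_config(dims = 2:3, top_k = 10, ensemble_size = 5, ...)
}

# Minimal valid metadata for hand-built activity fixtures.
tiny_metadata <- function(n_control = 1, n_transgenic = 1, n_tp = 2) {
  samples <- c(sprintf("C%d", seq_len(n_control)),
               sprintf("T%d", seq_len(n_transgenic)))
  groups <- rep(c("control", "transgenic"), c(n_control, n_transgenic))
  purrr::map2_dfr(samples, groups, function(s, g) {
    tibble::tibble(
      sample_id = s, time_point = seq_len(n_tp), group = g,
      phenotype = if (g == "control") "healthy" else
        c(rep("healthy", max(0, n_tp - 2)),
          "pre_cancer", "cancer")[seq_len(n_tp)])
  })
}

# Attractor set assembled directly from a member table (internal helper
# reused on purpose: these fixtures test downstream modules, not clustering).
manual_aset <- function(members) {
  attractors <- members |>
    dplyr::group_by(ca_id, representative) |>
    dplyr::summarise(size = dplyr::n(), total_count = sum(count),
                     .groups = "drop")
  cloneattractor:::.new_attractor_set(
    attractors, members,
    log = tibble::tibble(order = integer(), junction_aa = character(),
                         ca_id = integer(), distance = numeric(),
                         founded = logical()),
    weights = edit_weights(), strategy = "first_fit")
}

# Feature tibble with two planted informative columns among log-normal
# noise columns. The signal is complementary: ca_1 is elevated in one half
# of the transgenic points and ca_2 in the other half, so either feature
# alone is only partly discriminative while the pair separates the classes.
planted_features <- function(n_per_class = 20, n_noise = 18, effect = 6,
                             seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  label <- factor(rep(c("control", "transgenic"), each = n_per_class),
                  levels = c("control", "transgenic"))
  x <- matrix(rlnorm(n * (n_noise + 2), meanlog = 3, sdlog = 0.4),
              nrow = n)
  tg <- which(label == "transgenic")
  first_half <- tg[seq_len(ceiling(length(tg) / 2))]
  second_half <- setdiff(tg, first_half)
  x[first_half, 1] <- x[first_half, 1] * effect
  x[second_half, 2] <- x[second_half, 2] * effect
  colnames(x) <- paste0("ca_", seq_len(ncol(x)))
  ids <- c(rep(c("C1", "C2"), length.out = n_per_class),
           rep(c("T1", "T2"), length.out = n_per_class))
  dplyr::bind_cols(
    tibble::tibble(
      sample_id = ids,
      time_point = as.integer(stats::ave(seq_along(ids), ids,
                                         FUN = seq_along)),
      label = label),
    tibble::as_tibble(x))
}
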