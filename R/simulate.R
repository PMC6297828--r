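#' Configuration of the synthetic longitudinal repertoire generator
#'
#' The generator emulates the statistical structure the Clone-Attractor
#' method assumes: attractor sizes drawn from a truncated discrete power law
#' (exponent `alpha`, default 3); members within the association radius
#' (weighted edit cost at most `member_edit_budget`) of their attractor
#' seed; per-(sample, time point) amplitudes from a log-normal model; a
#' control group whose large ("hub") attractors dilute over time against a
#' transgenic group whose hubs persist; and planted discriminative
#' attractors whose amplitudes are multiplied by an effect size in
#' transgenic (stage 1) or cancer-labelled (stage 2) data points.
#'
#' Hub attractors are laid out as a chain in sequence space (consecutive hub
#' seeds differ by 3 substitutions, weighted distance 5.7), so that the
#' per-sample repertoire graphs have edges between neighbouring hubs
#' (5.7 <= 8) but not across the chain, while members of different hubs can
#' never fall within the association radius of a foreign representative.
#'
#' @param n_attractors Number of attractors (default 3000).
#' @param alpha Power-law exponent for attractor sizes (default 3).
#' @param size_range Integer `(k_min, k_max)` truncation of the size law
#'   (default `c(1, 1000)`).
#' @param member_edit_budget Maximum weighted edit cost of a member from its
#'   seed (default 3, the association threshold).
#' @param n_control,n_transgenic Sample counts (defaults 5, 10).
#' @param n_timepoints Time points per sample (default 8).
#' @param amplitude_meanlog,amplitude_sdlog Log-normal member count model
#'   (defaults `log(20)`, 0.6 for hub members; small attractors use
#'   `log(5)`).
#' @param dilution_rate Per-time-step retention of dynamic hub activity in
#'   the control group (default 0.7; 1 disables dilution).
#' @param persistence Per-time-step retention of hub activity in the
#'   transgenic group (default 1: hubs persist).
#' @param hub_min_size Size from which an attractor counts as a hub
#'   (default 10, matching the graph filter).
#' @param persistent_hub_fraction Fraction of non-planted hubs that persist
#'   in both groups (default 0.25); the rest dilute in controls.
#' @param small_presence Per-(sample, time point) activity probability of
#'   non-hub attractors (default 0.3).
#' @param member_detection Probability that a member is observed when its
#'   attractor is active (default 0.7 for hubs, 0.9 for small attractors).
#' @param n_signal_cas_stage1,n_signal_cas_stage2 Numbers of planted
#'   discriminative attractors (defaults 4, 4); planted attractors are the
#'   largest ones and are always active.
#' @param effect_size Multiplicative amplitude increase of stage-1 planted
#'   attractors in transgenic points (default 4).
#' @param effect_size_stage2 Same for stage-2 planted attractors in
#'   cancer-labelled points (default 2, weaker than stage 1).
#' @param seed Integer seed (default 42).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_attractors = 3000, alpha = 3,
                       size_range = c(1, 1000), member_edit_budget = 3,
                       n_control = 5, n_transgenic = 10, n_timepoints = 8,
                       amplitude_meanlog = log(20), amplitude_sdlog = 0.6,
                       dilution_rate = 0.7, persistence = 1,
                       hub_min_size = 10, persistent_hub_fraction = 0.25,
                       small_presence = 0.3,
                       member_detection = 0.7,
                       n_signal_cas_stage1 = 4, n_signal_cas_stage2 = 4,
                       effect_size = 4, effect_size_stage2 = 2,
                       seed = 42) {
  if (n_attractors < 1 || n_control < 1 || n_transgenic < 1 ||
      n_timepoints < 2) {
    abort("counts must be positive (and `n_timepoints` >= 2).")
  }
  if (alpha <= 1) abort("`alpha` must be > 1.")
  if (size_range[1] < 1 || size_range[2] < size_range[1]) {
    abort("invalid `size_range`.")
  }
  if (effect_size < 1 || effect_size_stage2 < 1) {
    abort("effect sizes must be >= 1 (1 = no planted signal).")
  }
  if (dilution_rate <= 0 || dilution_rate > 1 ||
      persistence <= 0 || persistence > 1) {
    abort("`dilution_rate` and `persistence` must be in (0, 1].")
  }
  structure(as.list(environment()), class = "sim_config")
}

# sample sizes from P(K) proportional to K^-alpha on k_min..k_max
.rpowerlaw <- function(n, alpha, k_min, k_max) {
  k <- k_min:k_max
  sample(k, n, replace = TRUE, prob = k^(-alpha))
}

.random_middle <- function(len) {
  paste(sample(.aa_alphabet, len, replace = TRUE), collapse = "")
}

.random_cdr3 <- function(n) {
  lens <- sample(10:17, n, replace = TRUE)
  vapply(lens, function(l) paste0("CASS", .random_middle(l - 5), "F"),
         character(1))
}

# k substitutions at distinct interior positions (scaffold edges kept)
.substitute_k <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(5:(length(ch) - 1), k)
  for (p in pos) ch[p] <- sample(setdiff(.aa_alphabet, ch[p]), 1)
  paste(ch, collapse = "")
}

# One member variant of a seed, within the default lambda-ball: a single
# substitution, one insertion, two insertions, or one substitution plus one
# insertion (substitution-dominant mix: single-residue changes are the
# typical near-neighbour relation among similar CDR3s). The construction
# keeps the seed strictly first in the clustering's (length, lexicographic)
# processing order — indels are insertions, and a pure substitution replaces
# a residue by a lexicographically larger one — so the seed founds its
# cluster and the ground-truth partition aligns with the association radius.
.mutate_member <- function(s) {
  kind <- sample(c("sub", "ins", "ins2", "sub_ins"), 1,
                 prob = c(0.65, 0.25, 0.05, 0.05))
  out <- s
  if (kind %in% c("sub", "sub_ins")) {
    ch <- strsplit(out, "")[[1]]
    cand <- which(ch[5:(length(ch) - 1)] < "Y") + 4L
    if (length(cand) == 0) {
      kind <- if (kind == "sub") "ins" else "sub_ins"  # fall back to insertion(s)
    } else {
      p <- if (length(cand) == 1) cand else sample(cand, 1)
      repl <- .aa_alphabet[.aa_alphabet > ch[p]]
      ch[p] <- if (length(repl) == 1) repl else sample(repl, 1)
      out <- paste(ch, collapse = "")
    }
  }
  n_ins <- switch(kind, ins = 1, ins2 = 2, sub_ins = 1, 0)
  for (i in seq_len(n_ins)) {
    ch <- strsplit(out, "")[[1]]
    p <- sample(5:length(ch), 1)
    ch <- append(ch, sample(.aa_alphabet, 1), after = p - 1)
    out <- paste(ch, collapse = "")
  }
  out
}

#' Generate a synthetic longitudinal clone table
#'
#' Draws attractor sizes from the truncated power law, builds seed sequences
#' (hub seeds chained in sequence space, see [sim_config()]), mutates each
#' seed into its members within the association radius, assigns per-(sample,
#' time point) activity and log-normal member counts with control-group
#' dilution and planted effect sizes, and labels transgenic phenotypes
#' healthy -> pre_cancer -> cancer with a per-mouse onset time. Every member
#' is observed in at least one data point, so clustering the emitted clone
#' table sees the complete membership. Fully reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of class `ca_simulation`:
#'   * `clones`: clone table tibble (`junction_aa`, `count`, `sample_id`,
#'     `time_point`);
#'   * `metadata`: sample metadata tibble;
#'   * `truth`: list with `members` (tibble `junction_aa`, `ca_id`, `is_seed`),
#'     `attractors` (tibble `ca_id`, `seed_sequence`, `size`, `tier`,
#'     `planted_stage`), and the planted id vectors
#'     `signal_stage1`/`signal_stage2`;
#'   * `config`.
#' @export
simulate_repertoire <- function(config = sim_config(), seed = config$seed) {
  .with_seed(seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  n_ca <- cfg$n_attractors
  sizes <- .rpowerlaw(n_ca, cfg$alpha, cfg$size_range[1], cfg$size_range[2])
  if (sum(sizes) > 5e6) abort("size_range/n_attractors combination infeasible.")

  n_planted <- cfg$n_signal_cas_stage1 + cfg$n_signal_cas_stage2
  if (n_planted > n_ca) abort("more planted attractors than attractors.")
  by_size <- order(sizes, decreasing = TRUE)
  planted1 <- by_size[seq_len(cfg$n_signal_cas_stage1)]
  planted2 <- by_size[cfg$n_signal_cas_stage1 + seq_len(cfg$n_signal_cas_stage2)]
  hubs <- union(which(sizes >= cfg$hub_min_size), c(planted1, planted2))

  # tier: planted and a fixed fraction of remaining hubs persist in both
  # groups; the rest of the hubs dilute in controls; non-hubs are sporadic
  tier <- rep("small", n_ca)
  tier[hubs] <- "dynamic"
  other_hubs <- setdiff(hubs, c(planted1, planted2))
  n_persist <- round(cfg$persistent_hub_fraction * length(other_hubs))
  if (n_persist > 0) {
    tier[sample(other_hubs, n_persist)] <- "persistent"
  }
  tier[planted1] <- "persistent"
  tier[planted2] <- "persistent"

  # seeds: hubs form a chain (3 substitutions per step); others are random
  seeds <- character(n_ca)
  chain <- sample(hubs)
  seeds[chain[1]] <- paste0("CASS", .random_middle(8), "F")
  if (length(chain) > 1) {
    for (i in 2:length(chain)) {
      seeds[chain[i]] <- .substitute_k(seeds[chain[i - 1]], 3)
    }
  }
  rest <- setdiff(seq_len(n_ca), hubs)
  seeds[rest] <- .random_cdr3(length(rest))

  # members: the seed plus size-1 variants within the lambda-ball, globally
  # unique across the whole repertoire
  taken <- new.env(hash = TRUE, size = 4L * sum(sizes))
  for (s in seeds) assign(s, TRUE, envir = taken)
  member_seq <- vector("list", n_ca)
  for (a in seq_len(n_ca)) {
    mem <- seeds[a]
    need <- sizes[a] - 1
    tries <- 0
    while (need > 0 && tries < 50 * sizes[a]) {
      cand <- .mutate_member(seeds[a])
      tries <- tries + 1
      if (!exists(cand, envir = taken, inherits = FALSE)) {
        assign(cand, TRUE, envir = taken)
        mem <- c(mem, cand)
        need <- need - 1
      }
    }
    member_seq[[a]] <- mem
  }
  sizes <- lengths(member_seq)  # actual sizes after uniqueness

  # samples, time points, phenotypes
  samples <- c(sprintf("C%02d", seq_len(cfg$n_control)),
               sprintf("T%02d", seq_len(cfg$n_transgenic)))
  groups <- rep(c("control", "transgenic"),
                c(cfg$n_control, cfg$n_transgenic))
  tps <- seq_len(cfg$n_timepoints)
  onset <- sample(3:(cfg$n_timepoints - 1), cfg$n_transgenic, replace = TRUE)
  metadata <- purrr::map2(samples, groups, function(s, g) {
    ph <- if (g == "control") rep("healthy", length(tps)) else {
      o <- onset[match(s, samples) - cfg$n_control]
      ifelse(tps < o, "healthy", ifelse(tps == o, "pre_cancer", "cancer"))
    }
    tibble(sample_id = s, time_point = tps, group = g, phenotype = ph)
  }) |> bind_rows()

  points <- metadata[c("sample_id", "time_point", "group", "phenotype")]
  n_pt <- nrow(points)

  # per-attractor presence probability at each data point
  presence <- matrix(cfg$small_presence, n_ca, n_pt)
  t_idx <- points$time_point
  is_ctrl <- points$group == "control"
  for (a in hubs) {
    p <- numeric(n_pt)
    p[!is_ctrl] <- cfg$persistence^(t_idx[!is_ctrl] - 1)
    p[is_ctrl] <- if (tier[a] == "persistent") 1 else
      cfg$dilution_rate^(t_idx[is_ctrl] - 1)
    if (tier[a] == "persistent") p[!is_ctrl] <- 1
    presence[a, ] <- p
  }

  # multiplicative planted effects per attractor x point
  effect <- matrix(1, n_ca, n_pt)
  effect[planted1, !is_ctrl] <- cfg$effect_size
  effect[planted2, points$phenotype == "cancer"] <- cfg$effect_size_stage2

  active <- matrix(runif(n_ca * n_pt) < presence, n_ca, n_pt)

  # member-level observations, vectorized over (member, active point)
  member_tbl <- tibble(
    junction_aa = unlist(member_seq),
    ca_id = rep(seq_len(n_ca), sizes))
  is_hub_ca <- seq_len(n_ca) %in% hubs
  detect_p <- ifelse(is_hub_ca, cfg$member_detection, 0.9)
  meanlog <- ifelse(is_hub_ca, cfg$amplitude_meanlog, log(5))

  obs <- vector("list", n_pt)
  for (j in seq_len(n_pt)) {
    on <- which(active[member_tbl$ca_id, j])
    if (length(on) == 0) next
    det <- on[runif(length(on)) < detect_p[member_tbl$ca_id[on]]]
    if (length(det) == 0) next
    ca <- member_tbl$ca_id[det]
    cnt <- pmax(1, round(
      rlnorm(length(det), meanlog[ca], cfg$amplitude_sdlog) * effect[ca, j]))
    obs[[j]] <- tibble(
      junction_aa = member_tbl$junction_aa[det], count = cnt,
      sample_id = points$sample_id[j], time_point = points$time_point[j])
  }
  clones <- bind_rows(obs)

  # every member must be observed somewhere: give unseen members one count
  # at a random point where their attractor is active (or any point)
  unseen <- setdiff(member_tbl$junction_aa, clones$junction_aa)
  if (length(unseen) > 0) {
    ca <- member_tbl$ca_id[match(unseen, member_tbl$junction_aa)]
    home <- vapply(ca, function(a) {
      onj <- which(active[a, ])
      if (length(onj) == 0) sample.int(n_pt, 1) else
        onj[sample.int(length(onj), 1)]
    }, integer(1))
    clones <- bind_rows(clones, tibble(
      junction_aa = unseen, count = 1,
      sample_id = points$sample_id[home],
      time_point = points$time_point[home]))
  }
  clones <- arrange(clones, .data$sample_id, .data$time_point,
                    .data$junction_aa)

  planted_stage <- rep(NA_integer_, n_ca)
  planted_stage[planted1] <- 1L
  planted_stage[planted2] <- 2L
  truth <- list(
    members = mutate(member_tbl,
                     is_seed = .data$junction_aa %in% seeds),
    attractors = tibble(ca_id = seq_len(n_ca), seed_sequence = seeds,
                        size = sizes, tier = tier,
                        planted_stage = planted_stage),
    signal_stage1 = planted1, signal_stage2 = planted2)

  structure(list(clones = clones, metadata = metadata, truth = truth,
                 config = cfg),
            class = "ca_simulation")
}

#' @export
print.ca_simulation <- function(x, ...) {
  cat(sprintf(
    "<ca_simulation> %d clone records, %d true attractors (%d unique sequences), %d samples x %d time points\n",
    nrow(x$clones), nrow(x$truth$attractors), nrow(x$truth$members),
    length(unique(x$metadata$sample_id)), x$config$n_timepoints))
  invisible(x)
}

#' Standard benchmark bundle
#'
#' Emits the default synthetic benchmark (the study design: 5 control + 10
#' transgenic samples over 8 time points) together with a "null" variant in
#' which both planted effect sizes are 1, for false-positive checks. Both
#' variants share the given seed.
#'
#' @param config Base [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list with elements `default` and `null`, each a `ca_simulation`.
#' @export
benchmark_suite <- function(config = sim_config(), seed = config$seed) {
  null_cfg <- config
  null_cfg$effect_size <- 1
  null_cfg$effect_size_stage2 <- 1
  list(default = simulate_repertoire(config, seed = seed),
       null = simulate_repertoire(null_cfg, seed = seed))
}
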