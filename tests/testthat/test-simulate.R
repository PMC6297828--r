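test_that("generation is reproducible and respects the configuration", {
  cfg <- sim_config(n_attractors = 150, size_range = c(1, 50))
  s1 <- simulate_repertoire(cfg, seed = 9)
  s2 <- simulate_repertoire(cfg, seed = 9)
  expect_identical(s1$clones, s2$clones)
  expect_identical(s1$truth$attractors, s2$truth$attractors)
  s3 <- simulate_repertoire(cfg, seed = 10)
  expect_false(identical(s1$clones, s3$clones))

  expect_equal(nrow(s1$truth$attractors), 150)
  expect_equal(sort(unique(s1$metadata$sample_id)),
               sort(unique(s1$clones$sample_id)))
  expect_silent(validate_sample_metadata(s1$metadata))
})

test_that("every member lies within the association radius of its seed", {
  sim <- simulate_repertoire(sim_config(n_attractors = 200,
                                        size_range = c(1, 100)), seed = 3)
  joined <- dplyr::left_join(
    sim$truth$members,
    dplyr::select(sim$truth$attractors, ca_id, seed_sequence),
    by = "ca_id")
  d <- distance_within(joined$junction_aa, joined$seed_sequence, cutoff = 3)
  expect_true(all(is.finite(d)))
  expect_true(all(d <= 3 + 1e-9))
  # member sequences are globally unique and include every seed
  expect_equal(anyDuplicated(joined$junction_aa), 0)
  expect_true(all(sim$truth$attractors$seed_sequence %in%
                    joined$junction_aa))
})

test_that("every member sequence is observed in the emitted clone table", {
  sim <- simulate_repertoire(sim_config(n_attractors = 200,
                                        size_range = c(1, 100)), seed = 5)
  expect_setequal(unique(sim$clones$junction_aa),
                  sim$truth$members$junction_aa)
  expect_true(all(sim$clones$count >= 1))
})

test_that("drawn attractor sizes follow the configured power law", {
  sim <- simulate_repertoire(sim_config(n_attractors = 2000), seed = 13)
  fit <- powerlaw_fit(sim$truth$attractors$size)
  expect_lt(abs(fit$alpha - 3), 0.3)
})

test_that("planted attractors are the largest and always active", {
  run <- default_run()
  truth <- run$sim$truth
  planted <- truth$attractors[!is.na(truth$attractors$planted_stage), ]
  expect_equal(nrow(planted), 8)
  others <- truth$attractors$size[is.na(truth$attractors$planted_stage)]
  expect_gte(min(planted$size), max(others) - 1)
  # planted attractors appear in (nearly) every (sample, time point)
  act <- dplyr::filter(run$activity, ca_id %in% with(
    dplyr::inner_join(run$aset$members,
                      dplyr::select(truth$members, junction_aa,
                                    true_ca = ca_id),
                      by = "junction_aa"),
    unique(ca_id[true_ca %in% truth$signal_stage1])))
  frac_active <- mean(act$amplitude > 0)
  expect_gt(frac_active, 0.95)
})

test_that("the benchmark bundle carries a matching null variant", {
  bench <- benchmark_suite(sim_config(n_attractors = 120), seed = 21)
  expect_named(bench, c("default", "null"))
  expect_equal(bench$null$config$effect_size, 1)
  expect_equal(bench$null$config$effect_size_stage2, 1)
  expect_equal(bench$default$config$effect_size, sim_config()$effect_size)
  # same seed, same attractor scaffold in both variants
  expect_equal(bench$default$truth$attractors$seed_sequence,
               bench$null$truth$attractors$seed_sequence)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(alpha = 1), "alpha")
  expect_error(sim_config(n_timepoints = 1), "positive")
  expect_error(sim_config(effect_size = 0.5), "effect")
  expect_error(sim_config(size_range = c(5, 2)), "size_range")
  expect_error(
    simulate_repertoire(sim_config(n_attractors = 10,
                                   n_signal_cas_stage1 = 8,
                                   n_signal_cas_stage2 = 8)),
    "planted")
})
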