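test_that("near-identical CDR3s collapse into one attractor", {
  trio <- c("CASSPGTDTQYF", "CASSPLTDTQYF", "CASSPQTDTQYF")
  # every pair differs by 1-2 substitutions; each joining distance is one
  # substitution from the current representative (1.9 <= 3)
  aset <- cluster_repertoire(trio)
  expect_equal(nrow(aset$attractors), 1)
  expect_equal(aset$attractors$size, 3)
  joined <- aset$association_log[!aset$association_log$founded, ]
  expect_true(all(joined$distance <= 3 + 1e-9))
  expect_equal(joined$distance, rep(1.9, 2))
})

test_that("sequences two substitutions apart found separate attractors", {
  expect_equal(
    weighted_levenshtein("CASSLAGEQYF", "CASSLNYEQYF"), 3.8)
  aset <- cluster_repertoire(c("CASSLAGEQYF", "CASSLNYEQYF"))
  expect_equal(nrow(aset$attractors), 2)
  expect_true(all(aset$attractors$size == 1))
})

test_that("a single sequence yields a singleton attractor; empty input an empty set", {
  aset <- cluster_repertoire("CASSLGGYEQYF")
  expect_equal(nrow(aset$attractors), 1)
  expect_equal(aset$attractors$representative, "CASSLGGYEQYF")
  empty <- cluster_repertoire(character(0))
  expect_equal(nrow(empty$attractors), 0)
  expect_equal(nrow(empty$members), 0)
})

test_that("clustering partitions the unique sequences and conserves counts", {
  set.seed(11)
  clones <- tibble::tibble(
    junction_aa = unique(random_aa(1000, 8, 16)),
    count = sample(1:50, length(junction_aa), replace = TRUE))
  aset <- cluster_repertoire(clones)
  expect_equal(sum(aset$attractors$size), nrow(clones))
  expect_equal(anyDuplicated(aset$members$junction_aa), 0)
  expect_setequal(aset$members$junction_aa, clones$junction_aa)
  expect_equal(sum(aset$members$count), sum(clones$count))
  # representative is always a member
  rep_in <- dplyr::inner_join(
    aset$attractors, aset$members,
    by = c("ca_id", "representative" = "junction_aa"))
  expect_equal(nrow(rep_in), nrow(aset$attractors))
})

test_that("clustering is deterministic and nearest-fit never exceeds first-fit", {
  set.seed(5)
  for (i in 1:10) {
    seqs <- random_aa(40, 6, 12)
    clones <- tibble::tibble(junction_aa = unique(seqs), count = 1)
    a1 <- cluster_repertoire(clones)
    a2 <- cluster_repertoire(clones[sample(nrow(clones)), ])
    expect_identical(a1$attractors, a2$attractors)
    near <- cluster_repertoire(clones, strategy = "nearest_fit")
    expect_lte(nrow(near$attractors), nrow(a1$attractors))
  }
})

test_that("the number of attractors is non-increasing in lambda", {
  run <- default_run()
  seqs <- tibble::tibble(
    junction_aa = unique(run$sim$clones$junction_aa), count = 1)
  counts <- vapply(c(0, 1.5, 3, 6), function(lam) {
    w <- suppressWarnings(edit_weights(lambda = lam))
    nrow(cluster_repertoire(seqs, w)$attractors)
  }, numeric(1))
  expect_equal(counts[1], nrow(seqs))  # lambda 0: every sequence its own
  expect_true(all(diff(counts) <= 0))
})

test_that("the representative is the medoid with documented tie-breaks", {
  expect_equal(update_representative("CASSF"), "CASSF")
  # distance sums: AAAA 1.9+3.8, AAAC 1.9+1.9, AACC 3.8+1.9 -> AAAC
  expect_equal(update_representative(c("AAAA", "AAAC", "AACC")), "AAAC")
  # tie between two members: lexicographically smaller wins
  expect_equal(update_representative(c("AADD", "AACC")), "AACC")
  # shorter member preferred on tied sums
  expect_equal(update_representative(c("CASSAF", "CASSAAF")), "CASSAF")
})

test_that("every association in the log was within lambda of a representative", {
  run <- default_run()
  log <- run$aset$association_log
  expect_true(all(log$distance[!log$founded] <= 3 + 1e-9))
  expect_true(all(log$distance[log$founded] == 0))
  expect_equal(sum(log$founded), nrow(run$aset$attractors))
})

test_that("activity amplitudes sum member counts and conserve column totals", {
  clones <- tibble::tibble(
    junction_aa = c("CASSAAF", "CASSAGF", "CASSAAF", "CAWWWWWWF"),
    count = c(3, 4, 6, 10),
    sample_id = c("A", "A", "B", "B"),
    time_point = c(1L, 1L, 2L, 2L))
  aset <- cluster_repertoire(clones)
  act <- attractor_activity(aset, clones)
  ca1 <- aset$members$ca_id[aset$members$junction_aa == "CASSAAF"]
  expect_equal(act$amplitude[act$ca_id == ca1 & act$sample_id == "A"], 7)
  totals <- act |>
    dplyr::group_by(sample_id, time_point) |>
    dplyr::summarise(amplitude = sum(amplitude), .groups = "drop")
  raw <- clones |>
    dplyr::group_by(sample_id, time_point) |>
    dplyr::summarise(amplitude = sum(count), .groups = "drop")
  expect_equal(totals, raw)
  stray <- dplyr::bind_rows(
    clones, tibble::tibble(junction_aa = "CLLLLLLLLF", count = 1,
                           sample_id = "A", time_point = 1L))
  expect_error(attractor_activity(aset, stray), "not members")
})

test_that("tidy and glance summarise an attractor set", {
  aset <- cluster_repertoire(c("CASSPGTDTQYF", "CASSPLTDTQYF"))
  expect_equal(tidy(aset), aset$attractors)
  g <- glance(aset)
  expect_equal(g$n_attractors, 1)
  expect_equal(g$n_sequences, 2)
  expect_equal(g$strategy, "first_fit")
})
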