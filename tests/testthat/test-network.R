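# Hand-built attractor set: representatives engineered so pairwise distances
# are 1.9 (edge), 7.6 (edge), 9.5 (no edge at the default cutoff 8).
three_node_fixture <- function() {
  reps <- c("CASSAAAAAF", "CASSAAAACF", "CASSCCCCCF")
  members <- purrr::map_dfr(seq_along(reps), function(i) {
    tibble::tibble(ca_id = i, representative = reps[i],
                   junction_aa = reps[i], count = 1)
  })
  # inflate sizes past the min_members filter without adding sequences
  aset <- manual_aset(members)
  aset$attractors$size <- 12L
  aset
}

test_that("graph edges follow the representative distance cutoff", {
  aset <- three_node_fixture()
  d <- weighted_levenshtein(
    c("CASSAAAAAF", "CASSAAAAAF", "CASSAAAACF"),
    c("CASSAAAACF", "CASSCCCCCF", "CASSCCCCCF"))
  expect_equal(d, c(1.9, 9.5, 7.6))
  activity <- tidyr::expand_grid(
    ca_id = 1:3, sample_id = "A", time_point = 1:2) |>
    dplyr::mutate(amplitude = ifelse(ca_id == 3 & time_point == 2, 0, 5))
  kept <- filter_attractors(aset, activity,
                            graph_filters(min_timepoint_fraction = 0.4))
  g1 <- build_graph(kept, activity, "A", 1)
  expect_equal(igraph::vcount(g1), 3)
  expect_equal(igraph::ecount(g1), 2)  # the 9.5 pair is dropped
  # amplitude 0 excludes a node from that time point's graph
  g2 <- build_graph(kept, activity, "A", 2)
  expect_equal(igraph::vcount(g2), 2)
  # identical activity -> identical graph
  g1b <- build_graph(kept, activity, "A", 1)
  expect_true(igraph::identical_graphs(g1, g1b))
})

test_that("attractor filtering applies size and time-point thresholds", {
  members <- purrr::map_dfr(1:3, function(i) {
    tibble::tibble(ca_id = i, representative = sprintf("CASSAA%dF", 0),
                   junction_aa = "CASSAAF", count = 1)
  })
  aset <- manual_aset(members)
  aset$attractors$size <- c(9L, 10L, 50L)
  # 8 time points; attractor 2 active in 5 (62.5% > 60%), attractor 3 in 4 (50%)
  activity <- tidyr::expand_grid(ca_id = 1:3, sample_id = "A",
                                 time_point = 1:8) |>
    dplyr::mutate(amplitude = dplyr::case_when(
      ca_id == 1 ~ 1,
      ca_id == 2 & time_point <= 5 ~ 1,
      ca_id == 3 & time_point <= 4 ~ 1,
      TRUE ~ 0))
  kept <- filter_attractors(aset, activity)
  expect_equal(kept$ca_id, 2L)          # size 9 and 50%-active both removed
  expect_equal(kept$n_timepoints_active, 5L)
})

test_that("MTI matches hand-derived values on canonical graphs", {
  expect_equal(mti(igraph::make_empty_graph(0, directed = FALSE)), 0)
  expect_equal(mti(igraph::make_empty_graph(1, directed = FALSE)), 0)
  expect_equal(mti(igraph::make_full_graph(2)), 4)
  path3 <- igraph::make_graph(~ a - b, b - c)
  expect_equal(mti(path3), 16)
  # disconnected graph: per-component evaluation, unreachable pairs ignored
  two_edges <- igraph::make_graph(~ a - b, c - d)
  expect_equal(mti(two_edges), 8)
})

test_that("MTI decreases with branchness: complete > path > star on n = 6", {
  # a star is the most branched of the three shapes, a path the least
  # branched sparse one; the dense complete graph tops both
  n <- 6
  vals <- c(complete = mti(igraph::make_full_graph(n)),
            star = mti(igraph::make_star(n, mode = "undirected")),
            path = mti(igraph::make_ring(n, circular = FALSE)))
  oracle <- c(oracle_mti(igraph::make_full_graph(n)),
              oracle_mti(igraph::make_star(n, mode = "undirected")),
              oracle_mti(igraph::make_ring(n, circular = FALSE)))
  expect_equal(unname(vals), oracle)
  expect_true(vals["complete"] > vals["path"])
  expect_true(vals["path"] > vals["star"])
})

test_that("MTI and BWC agree with brute-force oracles on random graphs", {
  set.seed(99)
  for (i in 1:40) {
    g <- random_small_graph(sample(2:8, 1), p = runif(1, 0.2, 0.8))
    expect_equal(mti(g), oracle_mti(g))
    expect_equal(unname(bwc(g)), oracle_betweenness(g))
  }
})

test_that("BWC reproduces exact values on canonical graphs", {
  expect_equal(unname(bwc(igraph::make_full_graph(4))), rep(0, 4))
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  expect_equal(unname(bwc(star)), c(3, 0, 0, 0))
  path3 <- igraph::make_graph(~ a - b, b - c)
  expect_equal(unname(bwc(path3)), c(0, 1, 0))
})

test_that("sBWC pools betweenness across graphs and sums above the median", {
  graphs <- tibble::tibble(
    sample_id = c("A", "B"), time_point = 1L,
    n_nodes = c(3L, 3L), n_edges = c(3L, 2L),
    graph = list(igraph::make_full_graph(3),
                 igraph::make_graph(~ a - b, b - c)))
  s <- sbwc(graphs)
  # pooled values {0,0,0, 0,1,0}: median 0; only the path centre exceeds it
  expect_equal(attr(s, "th"), 0)
  expect_equal(s$sbwc, c(0, 1))
  # all values equal -> nothing strictly above the median
  eq <- tibble::tibble(sample_id = "A", time_point = 1:2,
                       graph = list(igraph::make_full_graph(4),
                                    igraph::make_full_graph(3)))
  expect_equal(sbwc(eq)$sbwc, c(0, 0))
})

test_that("measure summaries are per sample across its own time points", {
  measures <- tibble::tibble(
    sample_id = c("A", "A", "B"),
    time_point = c(1L, 2L, 1L),
    n_nodes = 3L, n_edges = 2L,
    mti = c(10, 20, 7), sbwc = c(1, 3, 0))
  expect_warning(s <- measure_summary(measures), "single time point")
  expect_equal(s$mti_median[s$sample_id == "A"], 15)  # midpoint of two points
  expect_equal(s$sbwc_median[s$sample_id == "A"], 2)
  expect_equal(s$mti_sd[s$sample_id == "B"], 0)
})

test_that("graph export round-trips node and edge counts", {
  aset <- three_node_fixture()
  activity <- tidyr::expand_grid(ca_id = 1:3, sample_id = "A",
                                 time_point = 1L) |>
    dplyr::mutate(amplitude = 5)
  kept <- filter_attractors(aset, activity,
                            graph_filters(min_timepoint_fraction = 0.4))
  g <- build_graph(kept, activity, "A", 1)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  expect_equal(igraph::ecount(back), igraph::ecount(g))

  gexf <- withr::local_tempfile(fileext = ".gexf")
  export_graph(g, gexf, "gexf")
  doc <- xml2::read_xml(gexf)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='node']")),
               igraph::vcount(g))
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='edge']")),
               igraph::ecount(g))
  expect_error(export_graph(g, gexf, "dot"), "arg")
})

test_that("power-law fit recovers an exact K^-2 input within 0.1", {
  k <- 1:100
  sizes <- rep(k, times = round(1e5 * k^-2))
  fit <- powerlaw_fit(sizes)
  expect_lt(abs(fit$alpha - 2), 0.1)
  expect_gt(fit$r_squared, 0.99)
  expect_error(powerlaw_fit(rep(5L, 100)), "distinct")
  expect_error(powerlaw_fit(c(1, 2, 3)), "distinct")
  expect_error(powerlaw_fit(c(0, 1, 2)), "positive")
})

test_that("sBWC group ordering on the benchmark is robust to the threshold quantile", {
  run <- default_run()
  graphs <- build_graphs(run$aset, run$activity)
  groups <- dplyr::distinct(run$sim$metadata, sample_id, group)
  for (q in c(0.4, 0.5, 0.6)) {
    s <- sbwc(graphs, probs = q) |>
      dplyr::left_join(groups, by = "sample_id") |>
      dplyr::filter(time_point >= 6) |>
      dplyr::group_by(group) |>
      dplyr::summarise(sbwc = mean(sbwc), .groups = "drop")
    expect_gt(s$sbwc[s$group == "transgenic"], s$sbwc[s$group == "control"])
  }
})
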