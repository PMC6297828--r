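test_that("multiplicative perturbation matches its analytic moments", {
  feats <- planted_features(n_per_class = 2, n_noise = 0)
  expect_identical(perturb(feats, 0), feats)

  one <- tibble::tibble(sample_id = "A", time_point = 1L,
                        label = factor("x"), ca_1 = 1)
  draws25 <- vapply(1:10000, function(i) perturb(one, 0.25, seed = i)$ca_1,
                    numeric(1))
  expect_lt(abs(mean(draws25) - 1), 0.01)   # mean preserved
  draws10 <- vapply(1:10000, function(i) perturb(one, 0.10, seed = i)$ca_1,
                    numeric(1))
  expect_lt(abs(sd(draws10) - 0.10), 0.005) # CV equals sigma
  # reproducible for a fixed seed, and the RNG state is left untouched
  set.seed(123); before <- runif(1)
  p1 <- perturb(feats, 0.2, seed = 9)
  p2 <- perturb(feats, 0.2, seed = 9)
  expect_identical(p1, p2)
  set.seed(123)
  expect_identical(runif(1), before)
})

test_that("LOOCV separates well-separated classes and not permuted labels", {
  set.seed(4)
  n <- 20
  x <- rbind(matrix(rnorm(2 * n), n, 2),
             matrix(rnorm(2 * n, mean = 10), n, 2))
  feats <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = rep(c("a", "b", "c", "d"), each = n / 2),
      time_point = rep(1:(n / 2), 4),
      label = factor(rep(c("control", "transgenic"), each = n),
                     levels = c("control", "transgenic"))),
    tibble::as_tibble(`colnames<-`(x, c("ca_1", "ca_2"))))
  expect_gte(loocv_score(feats), 0.95)

  null_scores <- vapply(1:20, function(i) {
    shuffled <- feats
    shuffled$label <- sample(shuffled$label)
    loocv_score(shuffled)
  }, numeric(1))
  expect_lt(abs(mean(null_scores) - 0.5), 0.15)

  # boundary: one point per class is defined, not a crash
  two <- feats[c(1, 2 * n), ]
  expect_true(loocv_score(two) >= 0 && loocv_score(two) <= 1)
  # single-class input errors
  expect_error(loocv_score(feats[1:n, ]), "both classes")
})

test_that("sample-level LOOCV holds out whole samples", {
  feats <- planted_features(n_per_class = 10, n_noise = 2, effect = 8)
  s <- loocv_score(feats, quick_ml_config(loocv_unit = "sample"))
  expect_gte(s, 0.9)
})

test_that("active-feature filter keeps features above the strict fraction", {
  n <- 73
  feats <- tibble::tibble(
    sample_id = "A", time_point = seq_len(n),
    label = factor(rep(c("control", "transgenic"), length.out = n)),
    ca_1 = c(rep(1, 70), rep(0, 3)),   # 70/73 = 95.9% > 95% -> kept
    ca_2 = c(rep(1, 69), rep(0, 4)),   # 69/73 = 94.5% -> dropped
    ca_3 = 0)                          # never active -> dropped
  kept <- suppressMessages(active_feature_filter(feats, ml_config()))
  expect_equal(grep("^ca_", names(kept), value = TRUE), "ca_1")
  feats_none <- dplyr::select(feats, -ca_1)
  expect_error(suppressMessages(active_feature_filter(feats_none)), "lower")
})

test_that("forward selection finds the planted pair and deduplicates subsets", {
  feats <- planted_features(n_per_class = 20, n_noise = 10, effect = 8,
                            seed = 2)
  cfg <- quick_ml_config()
  expect_gte(loocv_score(feats[c(.meta <- c("sample_id", "time_point",
                                            "label"), "ca_1", "ca_2")],
                         cfg), 0.9)
  sel <- forward_selection(feats, cfg)
  top_pair <- sel$features[sel$dim == 2 & sel$rank == 1][[1]]
  expect_setequal(top_pair, c("ca_1", "ca_2"))
  # extensions are deduplicated as sets
  for (d in unique(sel$dim)) {
    keys <- vapply(sel$features[sel$dim == d], paste, collapse = "|",
                   FUN.VALUE = character(1))
    expect_equal(anyDuplicated(keys), 0)
  }
  # top_k larger than the candidate count retains everything
  small <- feats[c("sample_id", "time_point", "label",
                   "ca_1", "ca_2", "ca_3")]
  sel_all <- forward_selection(small, ml_config(top_k = 50, dims = 2))
  expect_equal(sum(sel_all$dim == 2), 3)  # all 3 pairs of 3 features
  expect_error(forward_selection(feats["label"], cfg), "at least 2 features")
})

test_that("the ensemble mean reduces to a single machine when degenerate", {
  feats <- planted_features(n_per_class = 10, n_noise = 2, effect = 6)
  sel <- tibble::tibble(
    dim = 2L, rank = 1:3, score = 1,
    features = list(c("ca_1", "ca_2"), c("ca_1", "ca_2"), c("ca_1", "ca_2")))
  one <- train_ensemble(feats, sel[1, ], 2, ml_config(ensemble_size = 1))
  expect_length(one$machines, 1)
  expect_warning(
    three <- train_ensemble(feats, sel, 2, ml_config(ensemble_size = 5)),
    "3 subsets")
  expect_equal(ensemble_score(three, feats), ensemble_score(one, feats),
               tolerance = 1e-10)
})

test_that("ensemble averaging does not increase bootstrap variance", {
  feats <- planted_features(n_per_class = 15, n_noise = 6, effect = 4,
                            seed = 3)
  cfg <- ml_config(ensemble_size = 5)
  subsets <- list(c("ca_1", "ca_3"), c("ca_2", "ca_4"), c("ca_1", "ca_5"),
                  c("ca_2", "ca_6"), c("ca_1", "ca_2"))
  sel <- tibble::tibble(dim = 2L, rank = 1:5, score = 1, features = subsets)
  set.seed(31)
  B <- 15
  ens_scores <- matrix(0, nrow(feats), B)
  machine_scores <- array(0, c(nrow(feats), B, length(subsets)))
  for (b in seq_len(B)) {
    idx <- c(sample(which(feats$label == "control"), replace = TRUE),
             sample(which(feats$label == "transgenic"), replace = TRUE))
    ens <- train_ensemble(feats[idx, ], sel, 2, cfg)
    ens_scores[, b] <- ensemble_score(ens, feats)
    for (m in seq_along(subsets)) {
      solo <- ens; solo$machines <- ens$machines[m]; solo$subsets <- ens$subsets[m]
      machine_scores[, , m][, b] <- ensemble_score(solo, feats)
    }
  }
  var_ens <- mean(apply(ens_scores, 1, var))
  var_solo <- mean(apply(machine_scores, c(1, 3), var))
  expect_lte(var_ens, var_solo + 1e-12)
})

test_that("ROC evaluation: perfect and random scorers behave as expected", {
  feats <- planted_features(n_per_class = 15, n_noise = 2, effect = 10,
                            seed = 5)
  cfg <- ml_config(ensemble_size = 1, noise_amplitudes = c(0, 0.1))
  sel <- tibble::tibble(dim = 2L, rank = 1L, score = 1,
                        features = list(c("ca_1", "ca_2")))
  ens <- train_ensemble(feats, sel, 2, cfg)
  r <- evaluate_roc(ens, feats, cfg, holdout = "none")
  expect_equal(r$auc$auc[r$auc$sigma == 0], 1)
  # noise-averaged AUC is the plain mean over the sigma grid
  expect_equal(r$mean_auc, mean(r$auc$auc))
  # curves are monotone in fpr/tpr
  expect_true(all(diff(r$curves$fpr[r$curves$sigma == 0]) >= 0))
  expect_true(all(diff(r$curves$tpr[r$curves$sigma == 0]) >= 0))

  # pure-noise features: cross-validated AUC hovers around chance
  aucs <- vapply(1:10, function(i) {
    nf <- planted_features(n_per_class = 15, n_noise = 4, effect = 1,
                           seed = 100 + i)
    e <- train_ensemble(nf, sel, 2, cfg)
    evaluate_roc(e, nf, cfg)$mean_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("the ROC operating point reports the worst-noise curve", {
  feats <- planted_features(n_per_class = 15, n_noise = 2, effect = 10)
  cfg <- ml_config(ensemble_size = 1, noise_amplitudes = c(0, 0.25))
  sel <- tibble::tibble(dim = 2L, rank = 1L, score = 1,
                        features = list(c("ca_1", "ca_2")))
  ens <- train_ensemble(feats, sel, 2, cfg)
  r <- evaluate_roc(ens, feats, cfg, operating_fpr = 0.1)
  expect_true(all(c("fpr", "tpr") %in% names(r$operating_point)))
  expect_lte(r$operating_point["fpr"], 0.1 + 1e-9)
})

test_that("the two-stage pipeline is deterministic and validates its inputs", {
  run <- default_run()
  cfg <- quick_ml_config(seed = 17)
  ts1 <- suppressMessages(two_stage_classify(run$activity,
                                             run$sim$metadata, cfg))
  ts2 <- suppressMessages(two_stage_classify(run$activity,
                                             run$sim$metadata, cfg))
  expect_identical(ts1$stage1$selection, ts2$stage1$selection)
  expect_identical(ts1$stage1$roc$auc, ts2$stage1$roc$auc)
  expect_identical(ts1$stage2$roc$auc, ts2$stage2$roc$auc)
  expect_s3_class(glance(ts1), "tbl_df")
  expect_true(ts1$feature_overlap >= 0 && ts1$feature_overlap <= 1)

  # control-only input fails informatively at stage 1
  meta_ctrl <- dplyr::filter(run$sim$metadata, group == "control")
  act_ctrl <- dplyr::semi_join(run$activity, meta_ctrl, by = "sample_id")
  expect_error(
    suppressMessages(two_stage_classify(act_ctrl, meta_ctrl, cfg)),
    "single class")
})

test_that("stage-2 labels come from the transgenic phenotype layer", {
  run <- default_run()
  f2 <- feature_matrix(run$activity, run$sim$metadata, stage = "phenotype")
  expect_setequal(levels(droplevels(f2$label)), c("pre_cancer", "cancer"))
  expect_true(all(startsWith(f2$sample_id, "T")))
  f1 <- feature_matrix(run$activity, run$sim$metadata, stage = "group")
  expect_true(all(f2$sample_id %in% f1$sample_id))
  expect_equal(nrow(f1), 120)
})
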