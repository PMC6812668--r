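# a small separable fixture: 6 rotamers spanning the four pucker families,
# near-zero generator noise, one sequence
fixture_records <- function(n = 12, seed = 101) {
  generate_theoretical(CAT, "AA", n, params = separable_params(),
                       seed = seed,
                       rotamers = c("1a", "1b", "2a", "2[", "5j", "4s"),
                       family_map = FMAP)
}

test_that("featurize produces the documented feature dimensions", {
  rec <- fixture_records(4)
  f5 <- featurize(rec, "rotamer", use_sequence = FALSE, FMAP)
  expect_equal(ncol(f5$x), 5L)
  f21 <- featurize(rec, "rotamer", use_sequence = TRUE, FMAP)
  expect_equal(ncol(f21$x), 21L)
  expect_true(all(rowSums(f21$x[, 6:21]) == 1))
  fdd <- featurize(rec, "dd", use_sequence = TRUE, FMAP)
  expect_lte(length(unique(fdd$y)), 4L)
  # records with missing shifts are dropped and counted
  rec$C2p[3] <- NA
  fdrop <- featurize(rec, "rotamer", TRUE, FMAP)
  expect_equal(nrow(fdrop$x), nrow(rec) - 1L)
  expect_equal(attr(fdrop, "n_dropped"), 1L)
})

test_that("every classifier separates the separable fixture", {
  rec <- fixture_records(10)
  test <- fixture_records(6, seed = 202)
  R <- build_rosum(CAT, "rotamer", family_map = FMAP)
  for (cl in c("NN", "DT", "RF", "MLP", "SVM")) {
    rep_ <- run_regime("exp_vs_theo", rec, test, "rotamer",
                       classifier_spec(cl), R, seed = 1,
                       catalog = CAT, family_map = FMAP)
    expect_gt(rep_$f1, 0.95, label = paste("F1 of", cl))
    expect_equal(rep_$n_test, nrow(test))
  }
})

test_that("LOO on the separable fixture is perfect and deterministic", {
  rec <- fixture_records(6)
  R <- build_rosum(CAT, "rotamer", family_map = FMAP)
  r1 <- run_regime("theo_vs_theo", rec, NULL, "rotamer",
                   classifier_spec("NN", k = 1), R, seed = 4,
                   catalog = CAT, family_map = FMAP)
  expect_equal(r1$f1, 1.0)
  expect_equal(r1$weighted_accuracy, 1.0)
  r2 <- run_regime("theo_vs_theo", rec, NULL, "rotamer",
                   classifier_spec("NN", k = 1), R, seed = 4,
                   catalog = CAT, family_map = FMAP)
  expect_identical(r1, r2)
  # decision tree LOO is deterministic under a fixed seed too
  d1 <- run_regime("theo_vs_theo", rec, NULL, "dd", classifier_spec("DT"),
                   NULL, seed = 4, catalog = CAT, family_map = FMAP)
  d2 <- run_regime("theo_vs_theo", rec, NULL, "dd", classifier_spec("DT"),
                   NULL, seed = 4, catalog = CAT, family_map = FMAP)
  expect_identical(d1, d2)
})

test_that("the random classifier sits at the uniform baseline", {
  # balanced 4-class problem: RAND plain accuracy ~ 1/4
  rec <- fixture_records(40, seed = 7)
  rec <- rec[rec$rotamer_id %in% c("1a", "1b", "2a", "2["), ]
  R <- build_rosum(CAT, "dd", family_map = FMAP)
  rep_ <- run_regime("exp_vs_theo", rec, rec, "dd",
                     classifier_spec("RAND"), R, seed = 11,
                     catalog = CAT, family_map = FMAP)
  n <- rep_$n_test
  se <- sqrt(0.25 * 0.75 / n)
  acc <- rep_$recall  # support-weighted recall equals plain accuracy here
  expect_lt(abs(acc - 0.25), 3 * se)
})

test_that("hyperparameter sweeps honour the max contract", {
  rec <- fixture_records(6)
  R <- build_rosum(CAT, "rotamer", family_map = FMAP)
  one <- hyperparameter_sweep(list(NN = list(classifier_spec("NN"))),
                              "exp_vs_theo", rec, rec, "rotamer", R,
                              seed = 1, catalog = CAT, family_map = FMAP)
  expect_equal(nrow(one$reports), 1L)
  grids <- list(NN = lapply(c(1, 3, 5), function(k)
    classifier_spec("NN", k = k)))
  sw <- hyperparameter_sweep(grids, "exp_vs_theo", rec, rec, "rotamer", R,
                             seed = 1, catalog = CAT, family_map = FMAP)
  expect_equal(nrow(sw$reports), 3L)
  expect_true(all(sw$reports$f1 == 1.0))  # separable at every k
  for (cl in unique(sw$reports$classifier))
    expect_gte(sw$best$f1[sw$best$classifier == cl],
               max(sw$reports$f1[sw$reports$classifier == cl]))
})

test_that("sparsification lowers scores and full retention changes nothing", {
  rec <- fixture_records(8)
  R <- build_rosum(CAT, "rotamer", family_map = FMAP)
  keep_all <- setNames(rep(1.0, 6), unique(rec$rotamer_id))
  same <- sparsity_experiment(rec, keep_all, "rotamer",
                              classifier_spec("NN", k = 1), R, seed = 2,
                              catalog = CAT, family_map = FMAP)
  expect_equal(unname(same$delta), rep(0, 4))
})

test_that("noise degrades scores monotonically on the fixture", {
  rec <- fixture_records(12)
  R <- build_rosum(CAT, "rotamer", family_map = FMAP)
  ne <- noise_experiment(rec, c(0, 0.5, 1.47, 3), "rotamer",
                         classifier_spec("NN", k = 1), R, seed = 6,
                         catalog = CAT, family_map = FMAP)
  expect_equal(ne$noise_sd, c(0, 0.5, 1.47, 3))
  # zero noise reproduces the training data exactly
  expect_equal(ne$f1[1], 1.0)
  expect_true(all(diff(ne$f1) <= 0.05))  # non-increasing within noise bands
  expect_lt(ne$f1[4], ne$f1[1])
})

test_that("test labels outside the scheme raise an error", {
  rec <- fixture_records(4)
  R <- build_rosum(CAT, "rotamer", family_map = FMAP)
  toy <- R; toy$labels <- "1a"; toy$weights <- toy$weights[1, 1, drop = FALSE]
  expect_error(run_regime("exp_vs_theo", rec, rec, "rotamer",
                          classifier_spec("NN"), toy, seed = 1,
                          catalog = CAT, family_map = FMAP),
               "outside the scheme")
})
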