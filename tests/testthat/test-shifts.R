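test_that("simple referencing implements delta = sigma_ref - sigma", {
  s <- simple_reference()
  expect_equal(reference_shift(0, s), 185.00)
  expect_equal(reference_shift(185.00, s), 0)
  # linearity of the subtractive form
  a <- 0.3; s1 <- 112.4; s2 <- 98.6
  expect_equal(reference_shift(a * s1 + (1 - a) * s2, s),
               a * reference_shift(s1, s) + (1 - a) * reference_shift(s2, s))
})

test_that("effective references recover known structure from pairs", {
  set.seed(31)
  # per-sequence offsets between experiment and simply-referenced theory
  offs <- c(AA = 1.2, GC = -0.8)
  n <- 100
  pairs <- do.call(rbind, lapply(names(offs), function(sq) {
    sigma <- rnorm(n, 110, 3)
    data.frame(sequence = sq, sigma = sigma,
               delta_exp = 185 - sigma + offs[[sq]] + rnorm(n, 0, 0.2))
  }))
  fit <- fit_effective_reference(pairs, "by_sequence")
  se <- 0.2 / sqrt(n)
  expect_lt(abs(fit$table[["AA"]] - (185 + 1.2)), 2 * se + 1e-9)
  expect_lt(abs(fit$table[["GC"]] - (185 - 0.8)), 2 * se + 1e-9)
  # referencing with the fitted scheme zeroes the per-cell mean residual
  resid <- reference_shift(pairs$sigma, fit, pairs$sequence) -
    pairs$delta_exp
  for (sq in names(offs))
    expect_lt(abs(mean(resid[pairs$sequence == sq])), 1e-9)
})

test_that("a global shift refits the simple reference accordingly", {
  sigma <- seq(100, 120, length.out = 50)
  pairs <- data.frame(sigma = sigma, delta_exp = 185 - sigma + 2.5)
  fit <- fit_effective_reference(pairs, "simple")
  expect_equal(fit$sigma_ref, 187.5)
})

test_that("regression referencing on collinear pairs finds slope -1", {
  sigma <- seq(90, 125, length.out = 40)
  pairs <- data.frame(sigma = sigma, delta_exp = 185 - sigma)
  fit <- fit_effective_reference(pairs, "regression")
  expect_equal(fit$slope, -1, tolerance = 1e-9)
  expect_equal(fit$intercept, 185, tolerance = 1e-9)
})

test_that("per-nucleus fitting zeroes each nucleus mean residual", {
  set.seed(5)
  pairs <- do.call(rbind, lapply(c("C1p", "C3p"), function(nuc) {
    sigma <- rnorm(60, if (nuc == "C1p") 93 else 112, 2)
    data.frame(nucleus = nuc, sigma = sigma,
               delta_exp = 184.2 - sigma + rnorm(60, 0, 0.3))
  }))
  fit <- fit_effective_reference(pairs, "by_nucleus")
  resid <- reference_shift(pairs$sigma, fit, pairs$nucleus) - pairs$delta_exp
  for (nuc in c("C1p", "C3p"))
    expect_lt(abs(mean(resid[pairs$nucleus == nuc])), 1e-9)
  # unknown context cells error without a fallback
  nofall <- fit; nofall$fallback <- NULL
  expect_error(reference_shift(100, nofall, "C5p"), "reference-resolution")
})

test_that("underfilled cells fall back to the 185 ppm reference", {
  pairs <- data.frame(sequence = c("AA", "AA", "GC"),
                      sigma = c(110, 111, 109),
                      delta_exp = c(76, 75, 74))
  expect_warning(fit <- fit_effective_reference(pairs, "by_sequence"),
                 "fall back")
  expect_equal(reference_shift(110, fit, "GC"), 75)
})

test_that("the synthetic generator is deterministic and label-faithful", {
  g1 <- generate_theoretical(CAT, "AA", 5, seed = 77,
                             rotamers = c("1a", "2["), family_map = FMAP)
  g2 <- generate_theoretical(CAT, "AA", 5, seed = 77,
                             rotamers = c("1a", "2["), family_map = FMAP)
  expect_identical(g1, g2)
  expect_true(all(g1$rotamer_id %in% CAT$rotamer_id))
  expect_true(all(family_of(g1$rotamer_id, "dd", FMAP) %in%
                    c("a", "b", "c", "d")))
  # shifts are the simply-referenced shieldings
  expect_equal(g1$C3p, 185 - g1$sigma_C3p)
})

test_that("with null effect sizes all rotamers share one shielding value", {
  p <- default_shift_params()
  p$pucker_effect[] <- 0
  p$angle_amp[] <- 0
  p$noise_sd <- 0
  g <- generate_theoretical(CAT, "AA", 3, params = p, seed = 1,
                            rotamers = c("1a", "1b", "2a", "2["),
                            family_map = FMAP)
  for (nuc in paste0("sigma_", c("C1p", "C2p", "C3p", "C4p", "C5p")))
    expect_equal(length(unique(g[[nuc]])), 1L)
})

test_that("pucker families dominate the generated C3' variance", {
  g <- generate_theoretical(CAT, "AA", 40, seed = 9, family_map = FMAP)
  fam <- family_of(g$rotamer_id, "dd", FMAP)
  fit <- stats::aov(g$sigma_C3p ~ fam)
  fstat <- summary(fit)[[1]][["F value"]][1]
  expect_gt(fstat, 10)
})

test_that("experimental-like records carry the stated noise and sparsity", {
  theo <- generate_theoretical(CAT, "AA", 50, seed = 3, family_map = FMAP)
  # identity when nothing is perturbed
  same <- generate_experimental_like(theo, noise_sd = 0, seed = 1)
  expect_equal(same$C2p, theo$C2p)
  expect_equal(unique(same$origin), "experimental_like")
  # zeroing 8 rotamers leaves 38 represented
  gone <- setNames(rep(0, 8), CAT$rotamer_id[1:8])
  sp <- generate_experimental_like(theo, noise_sd = 0, sparsity = gone,
                                   seed = 2)
  expect_equal(length(unique(sp$rotamer_id)), 38L)
  expect_error(generate_experimental_like(theo, sparsity = c(zz = 0.5)),
               "unknown rotamer")
  # noise sd close to the requested 1.47 ppm at n = 2000
  theo1 <- generate_theoretical(CAT, "AA", 2000, seed = 4,
                                rotamers = "1a", family_map = FMAP)
  noisy <- generate_experimental_like(theo1, noise_sd = 1.47, seed = 5)
  for (nuc in c("C1p", "C3p", "C5p")) {
    sdn <- sd(noisy[[nuc]] - theo1[[nuc]])
    expect_lt(abs(sdn - 1.47) / 1.47, 0.10)
  }
})
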