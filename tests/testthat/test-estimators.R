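test_that("Wald ratios follow the first-order arithmetic", {
  h <- HarmonizedSet("rs1", beta_exposure = 0.04, se_exposure = 0.004,
                     beta_outcome = 0.008, se_outcome = 0.002)
  wr <- waldRatio(h)
  expect_equal(wr$ratio, 0.2)
  expect_equal(wr$se, 0.05)

  h0 <- HarmonizedSet("rs1", beta_exposure = 0.04, se_exposure = 0.004,
                      beta_outcome = 0, se_outcome = 0.002)
  expect_equal(waldRatio(h0)$ratio, 0)

  hz <- HarmonizedSet("rs1", beta_exposure = 0, se_exposure = 0.004,
                      beta_outcome = 0.01, se_outcome = 0.002)
  expect_error(waldRatio(hz), "beta_exposure is zero")
})

test_that("IVW pools ratios with inverse-variance weights", {
  # ratios 0.2 (se 0.05) and 0.1 (se 0.1): theta = (400*0.2+100*0.1)/500
  h <- HarmonizedSet(c("rs1", "rs2"), beta_exposure = c(1, 1),
                     se_exposure = 0.01, beta_outcome = c(0.2, 0.1),
                     se_outcome = c(0.05, 0.1))
  est <- mrIVW(h, mode = "fixed")
  expect_equal(estimate(est), 0.18)
  expect_equal(stdError(est), 1 / sqrt(500))
  expect_equal(unname(confInt(est)),
               0.18 + c(-1, 1) * 1.96 / sqrt(500))

  # single instrument degenerates to the Wald ratio exactly
  h1 <- HarmonizedSet("rs1", beta_exposure = 0.04, se_exposure = 0.004,
                      beta_outcome = 0.008, se_outcome = 0.002)
  est1 <- mrIVW(h1, mode = "fixed")
  expect_equal(estimate(est1), 0.2)
  expect_equal(stdError(est1), 0.05)
  expect_equal(nSNPs(est1), 1L)

  # identical ratios: theta equals the ratio and Q = 0
  hc <- HarmonizedSet(paste0("rs", 1:4), beta_exposure = c(0.1, 0.2, 0.4, 0.8),
                      se_exposure = 0.01,
                      beta_outcome = 0.3 * c(0.1, 0.2, 0.4, 0.8),
                      se_outcome = 0.01)
  estc <- mrIVW(hc)
  expect_equal(estimate(estc), 0.3)
  expect_equal(unname(heterogeneity(estc)["Q"]), 0)

  expect_error(mrIVW(HarmonizedSet(character(0), numeric(0), numeric(0),
                                   numeric(0), numeric(0))),
               "at least 1")
})

test_that("the random-effects inflation floors at the fixed-effect SE", {
  h <- randomHarmonizedSet(20, seed = 5)
  fixed <- mrIVW(h, mode = "fixed")
  random <- mrIVW(h, mode = "random")
  expect_equal(estimate(random), estimate(fixed))
  expect_gte(stdError(random), stdError(fixed))
  q <- unname(heterogeneity(random)["Q"])
  expect_equal(stdError(random),
               stdError(fixed) * max(1, sqrt(q / (nSNPs(random) - 1))))
})

test_that("IVW ratio pooling equals weighted regression through the origin", {
  for (seed in 1:100) {
    h <- randomHarmonizedSet(sample(3:40, 1), seed = seed)
    p <- harmonizedPairs(h)
    fit <- lm(p$beta_outcome ~ p$beta_exposure + 0,
              weights = 1 / p$se_outcome^2)
    expect_equal(estimate(mrIVW(h)), unname(coef(fit)[1]),
                 tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers exact linear and affine data", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  h_lin <- HarmonizedSet(paste0("rs", 1:5), beta_exposure = bx,
                         se_exposure = 0.01, beta_outcome = 0.3 * bx,
                         se_outcome = 0.01)
  est <- mrEgger(h_lin)
  expect_equal(estimate(est), 0.3)
  expect_equal(unname(eggerIntercept(est)["intercept"]), 0,
               tolerance = 1e-12)

  h_aff <- HarmonizedSet(paste0("rs", 1:5), beta_exposure = bx,
                         se_exposure = 0.01, beta_outcome = 0.01 + 0.3 * bx,
                         se_outcome = 0.01)
  est2 <- mrEgger(h_aff)
  expect_equal(estimate(est2), 0.3)
  expect_equal(unname(eggerIntercept(est2)["intercept"]), 0.01)
})

test_that("MR-Egger matches the closed-form weighted normal equations", {
  for (seed in c(2, 13, 77)) {
    h <- randomHarmonizedSet(5, seed = seed)
    p <- harmonizedPairs(h)
    oracle <- eggerNormalEquations(p$beta_exposure, p$beta_outcome,
                                   p$se_outcome)
    est <- mrEgger(h)
    expect_equal(estimate(est), oracle$slope, tolerance = 1e-12)
    expect_equal(unname(eggerIntercept(est)["intercept"]), oracle$intercept,
                 tolerance = 1e-12)
    expect_equal(stdError(est), oracle$se_slope, tolerance = 1e-12)
    expect_equal(unname(eggerIntercept(est)["se"]), oracle$se_intercept,
                 tolerance = 1e-12)
    # t-based inference with J - 2 degrees of freedom
    expect_equal(pValue(est),
                 2 * pt(-abs(oracle$slope / oracle$se_slope), df = 3))
  }
})

test_that("MR-Egger degeneracies are rejected", {
  h2 <- randomHarmonizedSet(2, seed = 1)
  expect_error(mrEgger(h2), "at least 3")
  h_const <- HarmonizedSet(paste0("rs", 1:4), beta_exposure = 0.2,
                           se_exposure = 0.01,
                           beta_outcome = c(0.01, 0.02, 0.03, 0.04),
                           se_outcome = 0.01)
  expect_error(mrEgger(h_const), "singular")
})

test_that("the weighted median interpolates the cumulative weight function", {
  # equal weights: the crossing lands exactly on the middle ratio
  h <- HarmonizedSet(paste0("rs", 1:3), beta_exposure = 1, se_exposure = 0.01,
                     beta_outcome = c(0.1, 0.2, 0.3), se_outcome = 0.05)
  expect_equal(estimate(mrWeightedMedian(h, seed = 1)), 0.2)

  # ratios 0, 0.2, 0.4 with weights 1, 1, 2 (se(r) = 1, 1, 1/sqrt(2))
  h2 <- HarmonizedSet(paste0("rs", 1:3), beta_exposure = 1, se_exposure = 0.01,
                      beta_outcome = c(0, 0.2, 0.4),
                      se_outcome = c(1, 1, 1 / sqrt(2)))
  expect_equal(estimate(mrWeightedMedian(h2, seed = 1)),
               0.2 + 0.2 * (0.5 - 0.375) / (0.75 - 0.375))

  # constant ratios recover the constant regardless of weights
  h3 <- HarmonizedSet(paste0("rs", 1:5), beta_exposure = c(1, 2, 1, 3, 2),
                      se_exposure = 0.01,
                      beta_outcome = 0.07 * c(1, 2, 1, 3, 2),
                      se_outcome = runif(5, 0.01, 0.1))
  expect_equal(estimate(mrWeightedMedian(h3, seed = 1)), 0.07)

  expect_error(mrWeightedMedian(randomHarmonizedSet(2, 1), seed = 1),
               "at least 3")
  expect_error(mrWeightedMedian(randomHarmonizedSet(5, 1)), "seed")
})

test_that("the weighted median stays within the ratio range", {
  for (seed in 1:20) {
    h <- randomHarmonizedSet(sample(3:30, 1), seed = seed)
    r <- waldRatio(h)$ratio
    theta <- estimate(mrWeightedMedian(h, n_boot = 50, seed = seed))
    expect_gte(theta, min(r))
    expect_lte(theta, max(r))
  }
})

test_that("estimators are invariant to permutation and sign reorientation", {
  h <- randomHarmonizedSet(12, seed = 31)
  p <- harmonizedPairs(h)
  perm <- sample(nrow(p))
  h_perm <- HarmonizedSet(p$snp_id[perm], p$beta_exposure[perm],
                          p$se_exposure[perm], p$beta_outcome[perm],
                          p$se_outcome[perm])
  # negate both betas of one pair: the Wald ratio is unchanged
  p_sign <- p
  p_sign$beta_exposure[3] <- -p_sign$beta_exposure[3]
  p_sign$beta_outcome[3] <- -p_sign$beta_outcome[3]
  h_sign <- HarmonizedSet(p_sign$snp_id, p_sign$beta_exposure,
                          p_sign$se_exposure, p_sign$beta_outcome,
                          p_sign$se_outcome)
  for (variant in list(h_perm, h_sign)) {
    expect_equal(estimate(mrIVW(variant)), estimate(mrIVW(h)))
    expect_equal(stdError(mrIVW(variant)), stdError(mrIVW(h)))
    expect_equal(estimate(mrEgger(variant)), estimate(mrEgger(h)))
    expect_equal(eggerIntercept(mrEgger(variant)), eggerIntercept(mrEgger(h)))
    # canonical internal ordering makes even the bootstrap SE identical
    wm <- mrWeightedMedian(variant, n_boot = 100, seed = 9)
    wm0 <- mrWeightedMedian(h, n_boot = 100, seed = 9)
    expect_identical(estimate(wm), estimate(wm0))
    expect_identical(stdError(wm), stdError(wm0))
  }
})

test_that("scaling the outcome scales every estimator equivariantly", {
  h <- randomHarmonizedSet(10, seed = 11)
  p <- harmonizedPairs(h)
  cc <- 3.7
  h_scaled <- HarmonizedSet(p$snp_id, p$beta_exposure, p$se_exposure,
                            cc * p$beta_outcome, cc * p$se_outcome)
  expect_equal(estimate(mrIVW(h_scaled)), cc * estimate(mrIVW(h)))
  expect_equal(stdError(mrIVW(h_scaled)), cc * stdError(mrIVW(h)))
  expect_equal(estimate(mrEgger(h_scaled)), cc * estimate(mrEgger(h)))
  expect_equal(estimate(mrWeightedMedian(h_scaled, n_boot = 200, seed = 2)),
               cc * estimate(mrWeightedMedian(h, n_boot = 200, seed = 2)))
})

test_that("Cochran's Q measures weighted dispersion and is minimized at IVW", {
  # two ratios 0.1 and 0.3, both se 0.1, evaluated at 0.2
  h <- HarmonizedSet(c("rs1", "rs2"), beta_exposure = c(1, 1),
                     se_exposure = 0.01, beta_outcome = c(0.1, 0.3),
                     se_outcome = 0.1)
  q <- cochranQ(h, 0.2)
  expect_equal(unname(q["q_stat"]), 2)
  expect_equal(unname(q["q_df"]), 1)

  hc <- HarmonizedSet(paste0("rs", 1:3), beta_exposure = 1, se_exposure = 0.01,
                      beta_outcome = 0.25, se_outcome = 0.05)
  qc <- cochranQ(hc, 0.25)
  expect_equal(unname(qc["q_stat"]), 0)
  expect_equal(unname(qc["q_p"]), 1)

  h2 <- randomHarmonizedSet(15, seed = 3)
  theta_ivw <- estimate(mrIVW(h2))
  q_at_ivw <- unname(cochranQ(h2, theta_ivw)["q_stat"])
  grid <- theta_ivw + seq(-0.5, 0.5, length.out = 101)
  q_grid <- vapply(grid, function(t) unname(cochranQ(h2, t)["q_stat"]),
                   numeric(1))
  expect_true(all(q_grid >= q_at_ivw - 1e-12))

  expect_error(cochranQ(HarmonizedSet("rs1", 0.1, 0.01, 0.02, 0.01), 0),
               "at least 2")
})
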