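rec <- function(snp = "rs1", ea = "a", oa = NA, eaf = NA, beta = 0.02,
                se = 0.004, p = 1e-10) {
  list(snp_id = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
       beta = beta, se = se, pvalue = p)
}

test_that("matching effect alleles keep the pair unchanged", {
  res <- harmonizePair(rec(ea = "a", beta = 0.021, se = 0.0033, eaf = 0.21),
                       rec(ea = "a", beta = 0.05, se = 0.01, eaf = 0.22))
  expect_false(res$pair$flipped)
  expect_equal(res$pair$beta_outcome, 0.05)
  expect_equal(res$pair$beta_exposure, 0.021)
  expect_equal(res$pair$eaf_outcome, 0.22)
})

test_that("an opposite outcome allele flips sign and frequency", {
  res <- harmonizePair(rec(ea = "a", oa = "g"),
                       rec(ea = "g", oa = "a", beta = -0.03, eaf = 0.7))
  expect_true(res$pair$flipped)
  expect_equal(res$pair$beta_outcome, 0.03)
  expect_equal(res$pair$eaf_outcome, 0.3)
  expect_equal(res$pair$effect_allele, "a")   # exposure allele is reference
  # same decision when only the outcome's effect allele is published
  res2 <- harmonizePair(rec(ea = "a", oa = "g"),
                        rec(ea = "g", beta = -0.03, eaf = 0.7))
  expect_true(res2$pair$flipped)
  expect_equal(res2$pair$beta_outcome, 0.03)
})

test_that("strand-complementary allele pairs are recognized", {
  # exposure a/g reported on the other strand as t/c: same orientation
  res <- harmonizePair(rec(ea = "a", oa = "g"),
                       rec(ea = "t", oa = "c", beta = 0.04))
  expect_false(res$pair$flipped)
  # c/t is the complement of the swapped pair: flip
  res2 <- harmonizePair(rec(ea = "a", oa = "g"),
                        rec(ea = "c", oa = "t", beta = 0.04))
  expect_true(res2$pair$flipped)
  # incompatible pair is dropped
  res3 <- harmonizePair(rec(ea = "a", oa = "g"), rec(ea = "a", oa = "c"))
  expect_true(res3$drop)
  expect_equal(res3$reason, "allele_mismatch")
})

test_that("palindromic variants follow the configured policy", {
  e <- rec(ea = "a", oa = "t", eaf = 0.2)
  o_conc <- rec(ea = "a", oa = "t", eaf = 0.21, beta = 0.01)
  o_disc <- rec(ea = "a", oa = "t", eaf = 0.79, beta = 0.01)
  o_ambig <- rec(ea = "a", oa = "t", eaf = 0.5, beta = 0.01)

  drop_pol <- harmonizationPolicy("drop")
  res <- harmonizePair(e, o_conc, drop_pol)
  expect_true(res$drop)
  expect_equal(res$reason, "palindromic")

  freq_pol <- harmonizationPolicy("freq")
  expect_false(harmonizePair(e, o_conc, freq_pol)$pair$flipped)
  res_disc <- harmonizePair(e, o_disc, freq_pol)
  expect_true(res_disc$pair$flipped)
  expect_equal(res_disc$pair$beta_outcome, -0.01)
  expect_true(res_disc$pair$palindromic)
  expect_equal(harmonizePair(e, o_ambig, freq_pol)$reason, "palindromic")
})

test_that("effect-allele-only mode flips differing alleles, drops ambiguity", {
  # non-complementary difference: must be the other allele
  res <- harmonizePair(rec(ea = "a", eaf = 0.2),
                       rec(ea = "g", beta = -0.03, eaf = 0.75))
  expect_true(res$pair$flipped)
  expect_equal(res$pair$beta_outcome, 0.03)
  # strand complement with concordant unambiguous frequencies: same allele
  res2 <- harmonizePair(rec(ea = "a", eaf = 0.2),
                        rec(ea = "t", beta = 0.03, eaf = 0.22))
  expect_false(res2$pair$flipped)
  # strand complement with discordant frequencies: opposite allele
  res3 <- harmonizePair(rec(ea = "a", eaf = 0.2),
                        rec(ea = "t", beta = 0.03, eaf = 0.78))
  expect_true(res3$pair$flipped)
  # frequencies too close to 0.5 cannot arbitrate: drop
  res4 <- harmonizePair(rec(ea = "a", eaf = 0.5),
                        rec(ea = "t", beta = 0.03, eaf = 0.5))
  expect_true(res4$drop)
  expect_equal(res4$reason, "ambiguous")
})

test_that("indel codes are compared literally and never complemented", {
  expect_false(harmonizePair(rec(ea = "d"), rec(ea = "d"))$pair$flipped)
  res <- harmonizePair(rec(ea = "d", eaf = 0.45),
                       rec(ea = "i", beta = 0.02, eaf = 0.55))
  expect_true(res$pair$flipped)
  expect_equal(res$pair$beta_outcome, -0.02)
})

test_that("mismatched identifiers are a contract violation", {
  expect_error(harmonizePair(rec(snp = "rs1"), rec(snp = "rs2")), "snp_id")
})

test_that("table harmonization merges, audits and preserves errors", {
  e_df <- exampleRecords(3)
  o_df <- exampleRecords(3)
  o_df$beta <- c(0.05, -0.01, 0.02)
  # flip rs2's orientation in the outcome table
  o_tab <- flipOrientation(SummaryStats(o_df, trait = "out"), "rs2")
  e_tab <- SummaryStats(e_df, trait = "exp")

  h <- harmonizeTables(e_tab, o_tab)
  expect_equal(length(h), 3L)
  pairs <- harmonizedPairs(h)
  expect_equal(sum(pairs$flipped), 1L)
  expect_equal(pairs$snp_id[pairs$flipped], "rs2")
  # the flip restored the original outcome effect
  expect_equal(pairs$beta_outcome, c(0.05, -0.01, 0.02))
  # harmonization never touches standard errors or the exposure side
  expect_equal(pairs$se_outcome, o_df$se)
  expect_equal(pairs$beta_exposure, e_df$beta)
  expect_equal(pairs$se_exposure, e_df$se)
  expect_setequal(auditLog(h)$action, c("kept", "flipped"))
})

test_that("disjoint tables harmonize to an empty set", {
  a <- SummaryStats(exampleRecords(3))
  b_df <- exampleRecords(3)
  b_df$snp_id <- paste0("rs", 11:13)
  h <- harmonizeTables(a, SummaryStats(b_df))
  expect_equal(length(h), 0L)
})

test_that("a table harmonized against itself is the identity", {
  tab <- SummaryStats(exampleRecords(5))
  h <- harmonizeTables(tab, tab)
  pairs <- harmonizedPairs(h)
  expect_false(any(pairs$flipped))
  expect_equal(pairs$beta_outcome, pairs$beta_exposure)
})

test_that("harmonization undoes any pre-flip of the outcome (involution)", {
  sim <- simulateTwoSample(simConfig(n_snps = 25, theta_true = 0.1,
                                     gamma_sd = 0.1, seed = 19))
  h_orig <- harmonizeTables(sim$exposure, sim$outcome)
  for (snps in list(snpIds(sim$outcome)[c(1, 5, 9)], snpIds(sim$outcome))) {
    flipped_tab <- flipOrientation(sim$outcome, snps)
    h_flip <- harmonizeTables(sim$exposure, flipped_tab)
    keep <- setdiff(colnames(harmonizedPairs(h_orig)),
                    c("flipped"))
    expect_equal(harmonizedPairs(h_flip)[, keep],
                 harmonizedPairs(h_orig)[, keep])
    expect_setequal(harmonizedPairs(h_flip)$snp_id[harmonizedPairs(h_flip)$flipped],
                    snps)
  }
})
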