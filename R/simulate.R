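#' @include estimators.R
NULL

NONPALINDROMIC_PAIRS <- matrix(c("a", "g",  "g", "a",  "a", "c",  "c", "a",
                                 "t", "g",  "g", "t",  "t", "c",  "c", "t"),
                               ncol = 2L, byrow = TRUE)

#' Configuration for the two-sample GWAS simulator
#'
#' Defaults emulate the periodontal-liability study design: 47 instruments,
#' an exposure GWAS of 487,823 individuals, outcome consortia of around half
#' a million, and true instrument effects on the scale of the bundled
#' periodontal instruments (per-allele liability effects of roughly 0.015 to
#' 0.08).  Traits are treated as standardized, so the standard error of an
#' effect at minor-allele frequency `p` in a GWAS of `n` individuals is
#' `1/sqrt(2 p (1 - p) n)`.
#'
#' Raw instrument effects are drawn from a mean-zero normal with standard
#' deviation `gamma_sd` and every variant is then reported on its
#' exposure-increasing allele, the orientation on which directional
#' pleiotropy is defined; the emitted effect magnitudes are therefore
#' half-normal.  `gamma_list` overrides the draw with fixed true effects.
#' A fraction `prop_invalid` of variants (exactly
#' `round(prop_invalid * n_snps)`, chosen at random) receive a pleiotropic
#' direct effect on the outcome drawn from `Normal(mu_alpha, sigma_alpha^2)`
#' plus `inside_violation * gamma`; a non-zero `inside_violation` correlates
#' pleiotropy with instrument strength and so breaks the InSIDE assumption.
#'
#' @param n_snps number of instruments J
#' @param theta_true causal effect of exposure on outcome
#' @param n_exposure,n_outcome GWAS sample sizes
#' @param maf_range interval within (0, 0.5] from which minor-allele
#'   frequencies are drawn uniformly (a degenerate interval fixes the MAF)
#' @param gamma_sd standard deviation of the raw instrument effects
#' @param gamma_list optional fixed vector of true instrument effects,
#'   recycled to `n_snps`
#' @param mu_alpha,sigma_alpha mean and SD of pleiotropic direct effects
#' @param prop_invalid fraction of instruments receiving pleiotropy
#' @param inside_violation coefficient coupling pleiotropy to instrument
#'   strength (0 = InSIDE holds)
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration
#' @return a validated configuration list of class `"simConfig"`
#' @export
simConfig <- function(n_snps = 47L, theta_true = 0, n_exposure = 487823L,
                      n_outcome = 500000L, maf_range = c(0.05, 0.5),
                      gamma_sd = 0.02, gamma_list = NULL, mu_alpha = 0,
                      sigma_alpha = 0, prop_invalid = 0,
                      inside_violation = 0, seed = 1L) {
  stopifnot(n_snps >= 1, n_exposure >= 2, n_outcome >= 2,
            length(maf_range) == 2L, maf_range[1] > 0,
            maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            gamma_sd >= 0, sigma_alpha >= 0,
            prop_invalid >= 0, prop_invalid <= 1)
  cfg <- list(n_snps = as.integer(n_snps), theta_true = theta_true,
              n_exposure = n_exposure, n_outcome = n_outcome,
              maf_range = maf_range, gamma_sd = gamma_sd,
              gamma_list = gamma_list, mu_alpha = mu_alpha,
              sigma_alpha = sigma_alpha, prop_invalid = prop_invalid,
              inside_violation = inside_violation, seed = as.integer(seed))
  class(cfg) <- "simConfig"
  cfg
}

#' Simulate paired two-sample GWAS summary statistics
#'
#' Generates one exposure and one outcome summary-statistic table under a
#' known causal effect, together with the generating truth.  For each
#' variant `j`: a minor-allele frequency `p_j` is drawn uniformly from
#' `maf_range`; the true exposure effect `gamma_j` is drawn (or taken from
#' `gamma_list`); the observed exposure effect is
#' `Normal(gamma_j, se_x^2)` with `se_x = 1/sqrt(2 p_j (1 - p_j)
#' n_exposure)`; invalid variants receive a pleiotropic effect `alpha_j`;
#' and the observed outcome effect is
#' `Normal(theta_true * gamma_j + alpha_j, se_y^2)`.  P-values are the
#' two-sided normal tails of `beta/se`.  Allele labels are drawn from
#' non-palindromic pairs and shared between the two tables, so harmonization
#' keeps every variant unless the caller re-orients a table deliberately
#' (see [flipOrientation()]).
#'
#' @param config a [simConfig()]
#' @return list with components `exposure` and `outcome`
#'   ([SummaryStats-class]) and `truth`, a `data.frame` (`snp_id`, `gamma`,
#'   `alpha`, `invalid`) carrying `theta_true` and the seed as attributes
#' @examples
#' sim <- simulateTwoSample(simConfig(n_snps = 20, theta_true = 0.2,
#'                                    seed = 42))
#' head(sim$truth)
#' @export
simulateTwoSample <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  J <- config$n_snps
  withSeed(config$seed, {
    maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
    gamma <- if (!is.null(config$gamma_list))
      rep_len(as.numeric(config$gamma_list), J)
    else abs(stats::rnorm(J, 0, config$gamma_sd))
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
    beta_x <- stats::rnorm(J, gamma, se_x)
    n_invalid <- round(config$prop_invalid * J)
    invalid <- rep(FALSE, J)
    if (n_invalid > 0) invalid[sample.int(J, n_invalid)] <- TRUE
    alpha <- numeric(J)
    if (n_invalid > 0)
      alpha[invalid] <- stats::rnorm(n_invalid, config$mu_alpha,
                                     config$sigma_alpha) +
        config$inside_violation * gamma[invalid]
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome)
    beta_y <- stats::rnorm(J, config$theta_true * gamma + alpha, se_y)
    allele_idx <- sample.int(nrow(NONPALINDROMIC_PAIRS), J, replace = TRUE)
    snp_id <- sprintf("snp_%04d", seq_len(J))

    makeTable <- function(beta, se, n, trait) {
      SummaryStats(data.frame(
        snp_id = snp_id,
        effect_allele = NONPALINDROMIC_PAIRS[allele_idx, 1L],
        other_allele = NONPALINDROMIC_PAIRS[allele_idx, 2L],
        eaf = maf, beta = beta, se = se,
        pvalue = pNormTwoSided(beta / se), n = n,
        stringsAsFactors = FALSE),
        trait = trait,
        provenance = sprintf("simulated (seed %d)", config$seed))
    }
    truth <- data.frame(snp_id = snp_id, gamma = gamma, alpha = alpha,
                        invalid = invalid, stringsAsFactors = FALSE)
    attr(truth, "theta_true") <- config$theta_true
    attr(truth, "seed") <- config$seed
    list(exposure = makeTable(beta_x, se_x, config$n_exposure,
                              "simulated exposure"),
         outcome = makeTable(beta_y, se_y, config$n_outcome,
                             "simulated outcome"),
         truth = truth)
  })
}

#' Write a simulation truth table
#'
#' @param truth the `truth` component of [simulateTwoSample()]
#' @param path destination file
#' @return `path`, invisibly
#' @export
writeTruth <- function(truth, path) {
  out <- truth
  out$gamma <- formatRoundTrip(truth$gamma)
  out$alpha <- formatRoundTrip(truth$alpha)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Replicate a simulated MR study and summarize estimator recovery
#'
#' Runs [simulateTwoSample()] followed by harmonization and all three
#' estimators `n_reps` times and reports, per method: the mean estimate, the
#' empirical standard error (SD of the estimates across replicates), the
#' mean bias against `theta_true`, the empirical 95\% confidence-interval
#' coverage, and the rejection rate of the null `theta = 0` at level
#' `alpha`.  For the MR-Egger method the mean intercept estimate and the
#' intercept rejection rate are reported as well.
#'
#' Replicate `i` uses seed `seed + i` for data generation and
#' `seed + n_reps + i` for the weighted-median bootstrap, so any single
#' replicate can be reproduced in isolation.
#'
#' @param config a [simConfig()]; its own `seed` field is ignored here
#' @param n_reps number of replicates
#' @param seed master seed for the replicate-seed scheme
#' @param alpha nominal test level for the rejection rate (default 0.05)
#' @param n_boot weighted-median bootstrap replicates per fit (default 1000)
#' @return `data.frame` with one row per method and columns `method`,
#'   `n_reps`, `mean_estimate`, `empirical_se`, `mean_bias`, `coverage`,
#'   `rejection_rate`, `mean_intercept`, `intercept_rejection_rate`;
#'   the per-replicate estimates are attached as attribute `"replicates"`
#' @export
replicateStudy <- function(config, n_reps, seed, alpha = 0.05,
                           n_boot = 1000L) {
  stopifnot(inherits(config, "simConfig"), n_reps >= 1)
  methods_run <- c("IVW", "MR-Egger", "weighted-median")
  reps <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg_i <- config
    cfg_i$seed <- as.integer(seed + i)
    sim <- simulateTwoSample(cfg_i)
    h <- harmonizeTables(sim$exposure, sim$outcome)
    ests <- list(
      "IVW" = mrIVW(h),
      "MR-Egger" = mrEgger(h),
      "weighted-median" = mrWeightedMedian(h, n_boot = n_boot,
                                           seed = seed + n_reps + i))
    reps[[i]] <- do.call(rbind, lapply(methods_run, function(m) {
      e <- ests[[m]]
      data.frame(rep = i, method = m, theta = e@theta, se = e@se,
                 ci_low = e@ci_low, ci_high = e@ci_high, pvalue = e@pvalue,
                 intercept = e@intercept, intercept_p = e@intercept_p,
                 stringsAsFactors = FALSE)
    }))
  }
  all_reps <- do.call(rbind, reps)
  theta_true <- config$theta_true
  summary <- do.call(rbind, lapply(methods_run, function(m) {
    d <- all_reps[all_reps$method == m, , drop = FALSE]
    data.frame(
      method = m, n_reps = n_reps,
      mean_estimate = mean(d$theta),
      empirical_se = stats::sd(d$theta),
      mean_bias = mean(d$theta) - theta_true,
      coverage = mean(d$ci_low <= theta_true & theta_true <= d$ci_high),
      rejection_rate = mean(d$pvalue < alpha),
      mean_intercept = mean(d$intercept),
      intercept_rejection_rate = if (all(is.na(d$intercept_p))) NA_real_
                                 else mean(d$intercept_p < alpha),
      stringsAsFactors = FALSE)
  }))
  attr(summary, "replicates") <- all_reps
  attr(summary, "theta_true") <- theta_true
  summary
}
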