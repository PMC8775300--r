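#' @include harmonize.R
NULL

# Wald ratios and their first-order standard errors for a pairs data.frame.
# Outcome-side error only (NOME: the exposure associations are treated as
# measured without error), which makes ratio pooling algebraically identical
# to weighted regression through the origin.
waldComponents <- function(pairs) {
  bx <- pairs$beta_exposure
  if (any(bx == 0))
    stop("Wald ratio undefined: beta_exposure is zero for ",
         paste(pairs$snp_id[bx == 0], collapse = ", "), call. = FALSE)
  list(ratio = pairs$beta_outcome / bx,
       se = pairs$se_outcome / abs(bx))
}

requirePairs <- function(x, n, method) {
  if (nrow(x@pairs) < n)
    stop(method, " requires at least ", n, " instrument(s), got ",
         nrow(x@pairs), call. = FALSE)
}

#' Per-variant Wald ratio estimates
#'
#' The causal effect implied by a single instrument: the outcome effect
#' divided by the exposure effect, with the first-order standard error
#' `se_outcome / |beta_exposure|` (exposure-side error ignored, the NOME
#' assumption).
#'
#' @param x a [HarmonizedSet-class]
#' @return `data.frame` with `snp_id`, `ratio`, `se`, one row per pair
#' @examples
#' h <- HarmonizedSet("rs1", beta_exposure = 0.04, se_exposure = 0.004,
#'                    beta_outcome = 0.008, se_outcome = 0.002)
#' waldRatio(h)  # ratio 0.2, se 0.05
#' @export
setMethod("waldRatio", "HarmonizedSet", function(x) {
  requirePairs(x, 1L, "waldRatio")
  w <- waldComponents(x@pairs)
  data.frame(snp_id = x@pairs$snp_id, ratio = w$ratio, se = w$se,
             stringsAsFactors = FALSE)
})

#' Inverse-variance-weighted (IVW) causal estimate
#'
#' Pools the per-variant Wald ratios with weights equal to their inverse
#' variances: `theta = sum(w * r) / sum(w)` with `w = 1/se(r)^2`.  In
#' `"fixed"` mode the standard error is `1/sqrt(sum(w))`; the default
#' `"random"` (multiplicative random-effects) mode inflates it by
#' `max(1, sqrt(Q/(J - 1)))`, where `Q` is the Cochran heterogeneity
#' statistic, so over-dispersed instrument sets widen the interval while
#' under-dispersion is never rewarded.  P-values and the 95\% interval use
#' the standard normal.
#'
#' @param x a [HarmonizedSet-class] with at least one pair
#' @param mode `"random"` (default) or `"fixed"`
#' @return an [MREstimate-class]; heterogeneity slots are filled when at
#'   least two instruments are available
#' @examples
#' h <- HarmonizedSet(c("rs1", "rs2"),
#'                    beta_exposure = c(1, 1), se_exposure = 0.01,
#'                    beta_outcome = c(0.2, 0.1), se_outcome = c(0.05, 0.1))
#' estimate(mrIVW(h, mode = "fixed"))  # 0.18
#' @export
setMethod("mrIVW", "HarmonizedSet", function(x, mode = c("random", "fixed")) {
  mode <- match.arg(mode)
  requirePairs(x, 1L, "IVW")
  wc <- waldComponents(x@pairs)
  r <- wc$ratio
  w <- 1 / wc$se^2
  J <- length(r)
  theta <- sum(w * r) / sum(w)
  se <- sqrt(1 / sum(w))
  q_stat <- q_df <- q_p <- NA_real_
  if (J >= 2L) {
    q_stat <- sum(w * (r - theta)^2)
    q_df <- J - 1
    q_p <- stats::pchisq(q_stat, df = q_df, lower.tail = FALSE)
    if (mode == "random") se <- se * max(1, sqrt(q_stat / (J - 1)))
  }
  MREstimate("IVW", theta = theta, se = se,
             pvalue = pNormTwoSided(theta / se), n_snps = J,
             ci_low = theta - 1.96 * se, ci_high = theta + 1.96 * se,
             q_stat = q_stat, q_df = q_df, q_p = q_p)
})

#' MR-Egger regression estimate
#'
#' Weighted least-squares regression of the outcome effects on the exposure
#' effects with a free intercept and weights `1/se_outcome^2`, after
#' orienting every pair so the exposure effect is non-negative (both effects
#' of a pair are negated together, which leaves its Wald ratio unchanged).
#' The slope estimates the causal effect; the intercept estimates the
#' average directional pleiotropy, and its test is the Egger pleiotropy
#' test.  Standard errors are the unit-dispersion weighted-regression errors
#' scaled by `max(1, residual standard deviation)`; inference uses the t
#' distribution with `J - 2` degrees of freedom.
#'
#' @param x a [HarmonizedSet-class] with at least three pairs and
#'   non-constant oriented exposure effects
#' @return an [MREstimate-class] with the intercept slots filled;
#'   `q_stat`/`q_df`/`q_p` hold the Rucker-type heterogeneity of the
#'   regression residuals on `J - 2` degrees of freedom
#' @examples
#' h <- HarmonizedSet(paste0("rs", 1:4),
#'                    beta_exposure = c(0.1, 0.2, 0.3, 0.4),
#'                    se_exposure = 0.01,
#'                    beta_outcome = 0.01 + 0.3 * c(0.1, 0.2, 0.3, 0.4),
#'                    se_outcome = 0.01)
#' est <- mrEgger(h)
#' c(estimate(est), eggerIntercept(est)[["intercept"]])  # 0.3 and 0.01
#' @export
setMethod("mrEgger", "HarmonizedSet", function(x) {
  requirePairs(x, 3L, "MR-Egger")
  bx <- x@pairs$beta_exposure
  by <- x@pairs$beta_outcome
  sy <- x@pairs$se_outcome
  flip <- bx < 0
  bx[flip] <- -bx[flip]
  by[flip] <- -by[flip]
  if (length(unique(bx)) < 2L)
    stop("MR-Egger design is singular: oriented exposure effects ",
         "have no spread", call. = FALSE)
  w <- 1 / sy^2
  J <- length(bx)
  fit <- stats::lm(by ~ bx, weights = w)
  coefs <- stats::coef(fit)
  X <- cbind(1, bx)
  xtwxi <- solve(crossprod(X, w * X))
  se_unit <- unname(sqrt(diag(xtwxi)))  # SEs at unit residual dispersion
  rss <- sum(w * stats::residuals(fit)^2)
  sigma <- sqrt(rss / (J - 2))
  scale <- max(1, sigma)
  se <- se_unit * scale
  tcrit <- stats::qt(0.975, df = J - 2)
  theta <- unname(coefs[2L])
  intercept <- unname(coefs[1L])
  MREstimate("MR-Egger", theta = theta, se = se[2L],
             pvalue = pTTwoSided(theta / se[2L], J - 2), n_snps = J,
             ci_low = theta - tcrit * se[2L],
             ci_high = theta + tcrit * se[2L],
             intercept = intercept, intercept_se = se[1L],
             intercept_p = pTTwoSided(intercept / se[1L], J - 2),
             q_stat = rss, q_df = J - 2,
             q_p = stats::pchisq(rss, df = J - 2, lower.tail = FALSE))
})

# Weighted median of ratios r with weights w: the weighted 50th percentile
# of the ordered ratios, linearly interpolated on the standardized
# cumulative weights p_j = (S_j - w_j/2) / S_total.
weightedMedianPoint <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o]
  cw <- cumsum(w)
  p <- (cw - w / 2) / cw[length(cw)]
  if (0.5 <= p[1L]) return(r[1L])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The weighted 50th percentile of the ordered Wald ratios, consistent as
#' long as instruments carrying at least half of the total weight are valid.
#' The standard error comes from a parametric bootstrap: both effect vectors
#' are resampled from normal distributions centred on the observed effects
#' with their stated standard errors, the weighted median is recomputed, and
#' the standard deviation across replicates is taken.  The bootstrap is
#' seeded explicitly for reproducibility; pairs are processed in canonical
#' order (sorted by `snp_id`, exposure effects oriented non-negative), so
#' the result is invariant to permutation and per-pair sign reorientation of
#' the input.
#'
#' @param x a [HarmonizedSet-class] with at least three pairs
#' @param n_boot number of bootstrap replicates (default 1000)
#' @param seed mandatory integer seed for the bootstrap
#' @return an [MREstimate-class]
#' @examples
#' h <- HarmonizedSet(paste0("rs", 1:3),
#'                    beta_exposure = 1, se_exposure = 0.01,
#'                    beta_outcome = c(0.1, 0.2, 0.3), se_outcome = 0.05)
#' estimate(mrWeightedMedian(h, seed = 1))  # 0.2
#' @export
setMethod("mrWeightedMedian", "HarmonizedSet",
          function(x, n_boot = 1000L, seed) {
  requirePairs(x, 3L, "weighted-median")
  if (missing(seed)) stop("an explicit bootstrap seed is required",
                          call. = FALSE)
  stopifnot(is.numeric(n_boot), length(n_boot) == 1L, n_boot >= 2)
  # Canonical order and orientation make the stochastic SE invariant to
  # permutation and sign reorientation of the pairs.
  ord <- order(x@pairs$snp_id)
  pairs <- x@pairs[ord, , drop = FALSE]
  flip <- pairs$beta_exposure < 0
  pairs$beta_exposure[flip] <- -pairs$beta_exposure[flip]
  pairs$beta_outcome[flip] <- -pairs$beta_outcome[flip]
  wc <- waldComponents(pairs)
  theta <- weightedMedianPoint(wc$ratio, 1 / wc$se^2)
  J <- nrow(pairs)
  boot <- withSeed(seed, {
    bx <- matrix(stats::rnorm(J * n_boot, pairs$beta_exposure,
                              pairs$se_exposure), nrow = J)
    by <- matrix(stats::rnorm(J * n_boot, pairs$beta_outcome,
                              pairs$se_outcome), nrow = J)
    vapply(seq_len(n_boot), function(b) {
      r <- by[, b] / bx[, b]
      w <- (bx[, b] / pairs$se_outcome)^2
      weightedMedianPoint(r, w)
    }, numeric(1L))
  })
  se <- stats::sd(boot)
  MREstimate("weighted-median", theta = theta, se = se,
             pvalue = pNormTwoSided(theta / se), n_snps = J,
             ci_low = theta - 1.96 * se, ci_high = theta + 1.96 * se)
})

#' Cochran heterogeneity statistic
#'
#' `Q = sum(w * (r - theta)^2)` over the Wald ratios `r` with inverse
#' variance weights `w`, on `J - 1` degrees of freedom; the p-value is the
#' upper chi-square tail.  `Q` evaluated at the IVW estimate is its minimum
#' over `theta`.
#'
#' @param x a [HarmonizedSet-class] with at least two pairs
#' @param theta the causal effect at which to evaluate the statistic
#'   (typically the IVW estimate)
#' @return named numeric `c(q_stat, q_df, q_p)`
#' @export
setMethod("cochranQ", "HarmonizedSet", function(x, theta) {
  requirePairs(x, 2L, "cochranQ")
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  wc <- waldComponents(x@pairs)
  w <- 1 / wc$se^2
  q <- sum(w * (wc$ratio - theta)^2)
  df <- nrow(x@pairs) - 1
  c(q_stat = q, q_df = df,
    q_p = stats::pchisq(q, df = df, lower.tail = FALSE))
})
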