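# Shared fixtures and independent oracles for the estimator tests.

# Write a data.frame as a canonical tab-separated summary file and return
# the path.
writeTempTSV <- function(df, path = tempfile(fileext = ".tsv")) {
  out <- df
  for (col in colnames(out)) out[[col]] <- as.character(out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}

# A small well-formed summary data.frame.
exampleRecords <- function(n = 3L) {
  data.frame(snp_id = sprintf("rs%d", seq_len(n)),
             effect_allele = rep_len(c("a", "t", "c"), n),
             other_allele = rep_len(c("g", "c", "a"), n),
             eaf = seq(0.1, 0.4, length.out = n),
             beta = seq(0.01, 0.03, length.out = n),
             se = rep(0.004, n),
             pvalue = rep(1e-10, n),
             n = rep(10000, n),
             stringsAsFactors = FALSE)
}

# Random harmonized sets for property loops.
randomHarmonizedSet <- function(J, seed) {
  set.seed(seed)
  HarmonizedSet(snp_id = sprintf("rs%03d", sample.int(999, J)),
                beta_exposure = runif(J, 0.02, 0.2) * sample(c(-1, 1), J,
                                                             replace = TRUE),
                se_exposure = runif(J, 0.002, 0.01),
                beta_outcome = rnorm(J, 0, 0.05),
                se_outcome = runif(J, 0.005, 0.05))
}

# Independent MR-Egger oracle: weighted least squares by explicit normal
# equations, intercept SE scaling by max(1, residual SD), never via lm().
eggerNormalEquations <- function(bx, by, sy) {
  flip <- bx < 0
  bx[flip] <- -bx[flip]
  by[flip] <- -by[flip]
  w <- 1 / sy^2
  J <- length(bx)
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- by - intercept - slope * bx
  sigma <- sqrt(sum(w * resid^2) / (J - 2))
  scale <- max(1, sigma)
  se_slope <- sqrt(sw / det) * scale
  se_intercept <- sqrt(swxx / det) * scale
  list(slope = slope, intercept = intercept,
       se_slope = se_slope, se_intercept = se_intercept)
}

# Exact binomial 99% acceptance interval for a proportion.
binomBounds99 <- function(n, p) qbinom(c(0.005, 0.995), n, p) / n
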