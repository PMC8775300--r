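#' @include simulate.R
NULL

#' Bonferroni-corrected significance threshold
#'
#' Familywise error control over `m` outcomes: the corrected threshold is
#' `alpha / m` (0.05 over 8 outcomes gives 0.00625), and a p-value is
#' declared significant only when it falls strictly below it.
#'
#' @param alpha familywise level in (0, 1)
#' @param m number of outcomes tested, >= 1
#' @return the corrected threshold `alpha / m`
#' @seealso [isSignificant()]
#' @examples
#' bonferroniThreshold(0.05, 8)      # 0.00625
#' isSignificant(0.015, bonferroniThreshold(0.05, 8))  # FALSE
#' @export
bonferroniThreshold <- function(alpha, m) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(m), length(m) == 1L, m >= 1)
  alpha / m
}

#' @rdname bonferroniThreshold
#' @param p p-value(s) to test
#' @param threshold corrected threshold from [bonferroniThreshold()]
#' @export
isSignificant <- function(p, threshold) p < threshold

#' Pipeline configuration
#'
#' All tunable settings of [runMR()] as one structured list, readable from
#' and writable to a YAML file so a run's resolved configuration can be
#' archived alongside its results.
#'
#' @param p_exposure exposure-side instrument selection threshold
#'   (genome-wide significance, 5e-8)
#' @param p_outcome outcome-side exclusion threshold (default the same
#'   genome-wide level; the study design does not fix it, so it is a knob)
#' @param ivw_mode `"random"` or `"fixed"`, see [mrIVW()]
#' @param palindromic,palindromic_freq_threshold see [harmonizationPolicy()]
#' @param n_boot weighted-median bootstrap replicates
#' @param seed seed for the weighted-median bootstrap (outcome `k` of a run
#'   uses `seed + k`)
#' @param alpha familywise significance level before correction
#' @return a configuration list of class `"mrConfig"`
#' @export
mrConfig <- function(p_exposure = 5e-8, p_outcome = 5e-8,
                     ivw_mode = c("random", "fixed"),
                     palindromic = c("freq", "drop"),
                     palindromic_freq_threshold = 0.42,
                     n_boot = 1000L, seed = 1L, alpha = 0.05) {
  cfg <- list(p_exposure = p_exposure, p_outcome = p_outcome,
              ivw_mode = match.arg(ivw_mode),
              palindromic = match.arg(palindromic),
              palindromic_freq_threshold = palindromic_freq_threshold,
              n_boot = as.integer(n_boot), seed = as.integer(seed),
              alpha = alpha)
  class(cfg) <- "mrConfig"
  cfg
}

#' @rdname mrConfig
#' @param path YAML file to read or write
#' @export
readMRConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(mrConfig, vals)
}

#' @rdname mrConfig
#' @param config an `mrConfig` list
#' @export
writeMRConfig <- function(config, path) {
  stopifnot(inherits(config, "mrConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full two-sample MR study grid
#'
#' For each outcome table: selects exposure instruments at genome-wide
#' significance, applies the outcome-side exclusion rule, harmonizes the
#' surviving instruments onto the exposure's effect alleles, and computes
#' the IVW, MR-Egger and weighted-median estimates with Bonferroni verdicts
#' at `alpha / m`, where `m` is the number of outcome tables supplied.
#' An outcome yielding fewer than three harmonized pairs still reports IVW
#' when at least one pair survives; MR-Egger and the weighted median are
#' then reported as unavailable with a reason.  Given the same inputs,
#' configuration and seed, two runs are identical.
#'
#' @param exposure a [SummaryStats-class] of exposure associations
#' @param outcomes named list of [SummaryStats-class] outcome tables
#' @param config an [mrConfig()]
#' @return named list of [MRResult-class], one per outcome
#' @examples
#' sim <- simulateTwoSample(simConfig(n_snps = 30, theta_true = 0.1,
#'                                    gamma_sd = 0.1, seed = 3))
#' res <- runMR(sim$exposure, list(sim_outcome = sim$outcome))
#' res$sim_outcome
#' @export
runMR <- function(exposure, outcomes, config = mrConfig()) {
  stopifnot(methods::is(exposure, "SummaryStats"), length(exposure) > 0,
            is.list(outcomes), length(outcomes) >= 1,
            all(vapply(outcomes, methods::is, logical(1L), "SummaryStats")),
            inherits(config, "mrConfig"))
  if (is.null(names(outcomes)) || any(names(outcomes) == ""))
    stop("'outcomes' must be a fully named list", call. = FALSE)
  m <- length(outcomes)
  alpha_b <- bonferroniThreshold(config$alpha, m)
  policy <- harmonizationPolicy(config$palindromic,
                                config$palindromic_freq_threshold)
  selected <- selectInstruments(exposure, config$p_exposure)
  exposure_label <- if (is.na(trait(exposure))) "exposure" else trait(exposure)

  results <- vector("list", m)
  names(results) <- names(outcomes)
  for (k in seq_len(m)) {
    out_name <- names(outcomes)[k]
    outcome <- outcomes[[k]]
    kept <- excludeOutcomeAssociated(selected, outcome, config$p_outcome)
    h <- harmonizeTables(kept, outcome, policy)
    n_used <- length(h)
    ests <- list()
    unavailable <- character(0)
    if (n_used >= 1L) {
      ests[["IVW"]] <- mrIVW(h, mode = config$ivw_mode)
    } else {
      unavailable[["IVW"]] <- "no harmonized instruments"
    }
    if (n_used >= 3L) {
      ests[["MR-Egger"]] <- mrEgger(h)
      ests[["weighted-median"]] <-
        mrWeightedMedian(h, n_boot = config$n_boot, seed = config$seed + k)
    } else {
      why <- sprintf("requires >= 3 instruments, got %d", n_used)
      unavailable[["MR-Egger"]] <- why
      unavailable[["weighted-median"]] <- why
    }
    significant <- vapply(ests, function(e) e@pvalue < alpha_b, logical(1L))
    audit <- rbind(auditLog(kept), auditLog(h))
    res <- methods::new("MRResult",
                        exposure = exposure_label,
                        outcome = if (is.na(trait(outcome))) out_name
                                  else trait(outcome),
                        n_instruments_initial = length(selected),
                        n_instruments_used = n_used,
                        estimates = ests, unavailable = unavailable,
                        bonferroni_alpha = alpha_b,
                        significant = significant, audit = audit)
    methods::validObject(res)
    results[[k]] <- res
  }
  results
}

FOREST_COLUMNS <- c("exposure", "outcome", "method", "n_snps", "theta", "se",
                    "ci_low", "ci_high", "pvalue", "intercept",
                    "intercept_se", "intercept_p", "q_stat", "q_p",
                    "significant")

#' Tabulate MR results as forest-plot data
#'
#' One row per outcome-method combination: the estimate, its 95\% interval,
#' p-value and instrument count — the data behind a forest plot.  Methods
#' that could not be computed for an outcome appear as rows of `NA`, so a
#' grid of 8 outcomes always yields 24 rows.
#'
#' @param results list of [MRResult-class] from [runMR()]
#' @return `data.frame` with columns `exposure`, `outcome`, `method`,
#'   `n_snps`, `theta`, `se`, `ci_low`, `ci_high`, `pvalue`, `intercept`,
#'   `intercept_se`, `intercept_p`, `q_stat`, `q_p`, `significant`
#' @seealso [writeForestTable()], [plotForest()]
#' @export
forestTable <- function(results) {
  stopifnot(is.list(results), length(results) >= 1,
            all(vapply(results, methods::is, logical(1L), "MRResult")))
  rows <- lapply(results, function(res) {
    all_methods <- c("IVW", "MR-Egger", "weighted-median")
    do.call(rbind, lapply(all_methods, function(m) {
      if (m %in% names(res@estimates)) {
        e <- res@estimates[[m]]
        data.frame(exposure = res@exposure, outcome = res@outcome,
                   method = m, n_snps = e@n_snps, theta = e@theta,
                   se = e@se, ci_low = e@ci_low, ci_high = e@ci_high,
                   pvalue = e@pvalue, intercept = e@intercept,
                   intercept_se = e@intercept_se,
                   intercept_p = e@intercept_p, q_stat = e@q_stat,
                   q_p = e@q_p,
                   significant = unname(res@significant[m]),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(exposure = res@exposure, outcome = res@outcome,
                   method = m, n_snps = NA_integer_, theta = NA_real_,
                   se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   pvalue = NA_real_, intercept = NA_real_,
                   intercept_se = NA_real_, intercept_p = NA_real_,
                   q_stat = NA_real_, q_p = NA_real_, significant = NA,
                   stringsAsFactors = FALSE)
      }
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, FOREST_COLUMNS]
}

#' Write and re-read a forest/results table
#'
#' Tab-separated, round-trip stable: re-reading reproduces the estimate
#' fields exactly.
#'
#' @param x a `data.frame` from [forestTable()]
#' @param path destination file
#' @return `path` invisibly (`readForestTable`: the `data.frame`)
#' @export
writeForestTable <- function(x, path) {
  out <- x
  for (col in colnames(out))
    if (is.numeric(out[[col]])) out[[col]] <- formatRoundTrip(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname writeForestTable
#' @export
readForestTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = "NA", stringsAsFactors = FALSE)
  df$n_snps <- as.integer(df$n_snps)
  df$significant <- as.logical(df$significant)
  df
}

#' Draw a forest plot of MR estimates
#'
#' Point estimates with 95\% confidence whiskers, one row per
#' outcome-method combination, with a dashed line at the null.
#'
#' @param x a `data.frame` from [forestTable()]
#' @param main plot title
#' @return invisibly, the plotted `data.frame` (rows with estimates)
#' @export
plotForest <- function(x, main = "Mendelian randomization estimates") {
  d <- x[!is.na(x$theta), , drop = FALSE]
  if (!nrow(d)) stop("nothing to plot: no available estimates", call. = FALSE)
  d <- d[rev(seq_len(nrow(d))), ]
  ylab <- paste(d$outcome, d$method, sep = " / ")
  xlim <- range(c(d$ci_low, d$ci_high, 0))
  old <- graphics::par(mar = c(4.5, 12, 3, 1))
  on.exit(graphics::par(old))
  plot(d$theta, seq_len(nrow(d)), xlim = xlim, yaxt = "n", ylab = "",
       xlab = "causal effect (95% CI)", pch = 15, main = main)
  graphics::segments(d$ci_low, seq_len(nrow(d)), d$ci_high)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  graphics::axis(2, at = seq_len(nrow(d)), labels = ylab, las = 1,
                 cex.axis = 0.7)
  invisible(d)
}
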