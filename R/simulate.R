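# Monte-Carlo validation of the subtraction estimator on simulated trios,
# reported in the ADEMP style (aims, data-generating mechanism, estimand,
# methods, performance measures).
#
# Data-generating mechanism, per replicate of n individuals:
#   F_i, M_i ~ Bernoulli(maf)        transmitted paternal / maternal alleles
#   C_g = F_i + M_i                  child genotype (0/1/2)
#   W ~ N(w_mean, w_scale)           genotype-phenotype weight (one draw)
#   C_p = C_g * W + N(0, noise_sd)   child phenotype
#   M_g = M_nt + M_i,  M_nt ~ Bernoulli(maf)   maternal genotype
#   M_p = M_g * W + N(0, noise_sd)   maternal phenotype
#   F_p = (F_i + F_nt) * W + N(0, noise_sd),  F_nt ~ Bernoulli(maf)
# Estimand: the child-genotype/paternal-phenotype association, 0.5 * W.

#' Configuration for the trio simulation
#'
#' @param n individuals per replicate (default 10,000).
#' @param reps number of Monte-Carlo replicates (default 1,000).
#' @param w_mean mean of the genotype-phenotype weight W (default 1).
#' @param w_scale spread of W. Interpreted as the standard deviation by
#'   default (the rnorm convention); set `variance_parameterization = TRUE`
#'   to read it as a variance instead. Default 0.006.
#' @param maf transmission probability of each allele (default 0.5).
#' @param noise_sd SD of the additive Gaussian phenotype noise (default 1).
#' @param seed master seed; per-replicate substreams are derived from it so
#'   results are reproducible and replicate-order independent.
#' @param variance_parameterization treat `w_scale` as a variance.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n = 10000, reps = 1000, w_mean = 1, w_scale = 0.006,
                       maf = 0.5, noise_sd = 1, seed = 1,
                       variance_parameterization = FALSE) {
  stopifnot(n >= 2, reps >= 1, maf > 0, maf < 1, noise_sd >= 0,
            w_scale >= 0, is.numeric(seed))
  structure(list(n = as.integer(n), reps = as.integer(reps), w_mean = w_mean,
                 w_scale = w_scale, maf = maf, noise_sd = noise_sd,
                 seed = as.integer(seed),
                 variance_parameterization = isTRUE(variance_parameterization)),
            class = "sim_config")
}

.w_sd <- function(config) {
  if (config$variance_parameterization) sqrt(config$w_scale) else config$w_scale
}

#' Simulate one trio cohort
#'
#' Draws one cohort from the data-generating mechanism above. The child
#' inherits exactly one transmitted allele from each parent; parental
#' genotypes add an independent non-transmitted allele, so the child-parent
#' genotype correlation tends to 0.5.
#'
#' @param config a [sim_config].
#' @param w_value optional fixed weight overriding the `W` draw (used by the
#'   grid runs where W is held constant within a cell).
#' @return A data.frame of class `trio_cohort` with columns `F_i`, `M_i`,
#'   `F_nt`, `M_nt`, `C_g`, `M_g`, `F_g`, `C_p`, `M_p`, `F_p` and attribute
#'   `W`.
#' @export
simulate_trio_cohort <- function(config, w_value = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  W <- if (is.null(w_value)) {
    stats::rnorm(1, config$w_mean, .w_sd(config))
  } else {
    w_value
  }
  F_i <- stats::rbinom(n, 1, config$maf)
  M_i <- stats::rbinom(n, 1, config$maf)
  M_nt <- stats::rbinom(n, 1, config$maf)
  F_nt <- stats::rbinom(n, 1, config$maf)
  C_g <- F_i + M_i
  M_g <- M_nt + M_i
  F_g <- F_i + F_nt
  C_p <- C_g * W + stats::rnorm(n, 0, config$noise_sd)
  M_p <- M_g * W + stats::rnorm(n, 0, config$noise_sd)
  F_p <- F_g * W + stats::rnorm(n, 0, config$noise_sd)
  structure(data.frame(F_i, M_i, F_nt, M_nt, C_g, M_g, F_g, C_p, M_p, F_p),
            class = c("trio_cohort", "data.frame"), W = W)
}

# OLS slope and SE of y on x with intercept, closed form (matches lm).
.ols_slope <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx <= 0) stop("constant genotype: slope undefined")
  yc <- y - mean(y)
  slope <- sum(xc * yc) / sxx
  rss <- sum(yc^2) - slope^2 * sxx
  rss <- max(rss, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  list(estimate = slope, se = se)
}

#' Direct paternal regression estimator
#'
#' OLS slope (with intercept) of the paternal phenotype on the child
#' genotype -- the analogue of running a traditional GWAS of the paternal
#' phenotype on the index person's genotype. Its population value under the
#' data-generating mechanism is `0.5 * W`.
#'
#' @param cohort a [simulate_trio_cohort()] cohort.
#' @return List with `estimate` and `se`.
#' @export
estimate_direct <- function(cohort) {
  stopifnot(inherits(cohort, "trio_cohort"))
  .ols_slope(cohort$C_g, cohort$F_p)
}

#' Weighted-linear-model (subtraction) estimator
#'
#' Slope of the child phenotype on the child genotype minus the slope of the
#' maternal phenotype on the child genotype, the individual-level analogue of
#' [subtract_gwas()]. Its SE is the square root of the summed squared slope
#' SEs, mirroring the summary-statistic error propagation. Population value:
#' `W - 0.5 * W = 0.5 * W`.
#'
#' @inheritParams estimate_direct
#' @return List with `estimate` and `se`.
#' @export
estimate_wlm <- function(cohort) {
  stopifnot(inherits(cohort, "trio_cohort"))
  child <- .ols_slope(cohort$C_g, cohort$C_p)
  maternal <- .ols_slope(cohort$C_g, cohort$M_p)
  list(estimate = child$estimate - maternal$estimate,
       se = sqrt(child$se^2 + maternal$se^2))
}

.summarise_bias <- function(bias) {
  m <- mean(bias)
  mcse <- if (length(bias) > 1L) stats::sd(bias) / sqrt(length(bias)) else NA_real_
  c(mean_bias = m, mcse = mcse,
    ci_low = m - 1.96 * mcse, ci_high = m + 1.96 * mcse)
}

#' Run the Monte-Carlo bias comparison
#'
#' Draws `reps` independent replicates (fresh W, genotypes and noise each
#' time unless `w_value` is supplied), computes both estimators per
#' replicate, and summarises per-estimator bias against the truth `0.5 * W`:
#' mean bias, Monte-Carlo standard error (`sd(bias)/sqrt(reps)`) and the
#' normal 95% CI `mean +/- 1.96 * MCSE`.
#'
#' @param config a [sim_config]; its `seed` spawns one substream per
#'   replicate, so results are bit-reproducible.
#' @param w_value optional fixed weight held constant across replicates.
#' @return An object of class `wlm_sim`: list with `config`, per-replicate
#'   `replicates` data.frame (`rep`, `W`, `truth`, `estimate_direct`,
#'   `se_direct`, `estimate_wlm`, `se_wlm`) and a `summary` data.frame with
#'   one row per estimator.
#' @export
run_simulation <- function(config, w_value = NULL) {
  stopifnot(inherits(config, "sim_config"))
  reps <- config$reps
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  est_d <- se_d <- est_w <- se_w <- truth <- Ws <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(sub_seeds[r])
    cohort <- simulate_trio_cohort(config, w_value = w_value)
    W <- attr(cohort, "W")
    d <- estimate_direct(cohort)
    w <- estimate_wlm(cohort)
    est_d[r] <- d$estimate; se_d[r] <- d$se
    est_w[r] <- w$estimate; se_w[r] <- w$se
    truth[r] <- 0.5 * W; Ws[r] <- W
  }
  replicates <- data.frame(rep = seq_len(reps), W = Ws, truth = truth,
                           estimate_direct = est_d, se_direct = se_d,
                           estimate_wlm = est_w, se_wlm = se_w)
  summary <- rbind(
    data.frame(estimator = "direct", t(.summarise_bias(est_d - truth))),
    data.frame(estimator = "wlm", t(.summarise_bias(est_w - truth)))
  )
  structure(list(config = config, replicates = replicates, summary = summary),
            class = "wlm_sim")
}

#' @export
print.wlm_sim <- function(x, ...) {
  cat(sprintf(paste0("Trio Monte-Carlo validation: %d replicates of n = %d ",
                     "(maf = %g, noise_sd = %g)\n"),
              x$config$reps, x$config$n, x$config$maf, x$config$noise_sd))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-6s mean bias = %6.3f (95%% CI %.3f to %.3f)\n",
                s$estimator[i], s$mean_bias[i], s$ci_low[i], s$ci_high[i]))
  }
  invisible(x)
}

#' @export
summary.wlm_sim <- function(object, ...) object$summary

#' Bias grid over genotype-phenotype weights and allele frequencies
#'
#' Re-runs the Monte-Carlo comparison over a grid of fixed weights `W` and
#' transmission probabilities (minor allele frequencies), mirroring the
#' additional-simulations design that swept the betas and allele frequencies
#' of genome-wide-significant smoking SNPs (and their six-number summaries).
#' Within a cell W is held fixed (not redrawn) and the maf drives all four
#' allele draws.
#'
#' @param w_values weights to fix per cell.
#' @param maf_values allele frequencies per cell.
#' @param config base [sim_config] supplying n, reps, noise and the master
#'   seed (one substream per cell).
#' @param crossed if `TRUE` (default) the full `w x maf` cross is run;
#'   otherwise the vectors are paired element-wise (equal lengths required).
#' @return A data.frame of class `wlm_grid`: one row per (cell, estimator)
#'   with `W`, `maf`, `estimator`, `mean_bias`, `mcse`, `ci_low`, `ci_high`,
#'   `reps`.
#' @export
run_grid <- function(w_values, maf_values, config, crossed = TRUE) {
  stopifnot(inherits(config, "sim_config"),
            length(w_values) >= 1, length(maf_values) >= 1)
  cells <- if (crossed) {
    expand.grid(W = w_values, maf = maf_values)
  } else {
    stopifnot(length(w_values) == length(maf_values))
    data.frame(W = w_values, maf = maf_values)
  }
  set.seed(config$seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- config
    cfg$maf <- cells$maf[i]
    cfg$seed <- cell_seeds[i]
    sim <- run_simulation(cfg, w_value = cells$W[i])
    s <- sim$summary
    rows[[i]] <- data.frame(W = cells$W[i], maf = cells$maf[i],
                            estimator = s$estimator, mean_bias = s$mean_bias,
                            mcse = s$mcse, ci_low = s$ci_low,
                            ci_high = s$ci_high, reps = config$reps)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("wlm_grid", "data.frame"))
}
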