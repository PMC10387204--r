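# Two-sample Mendelian-randomization validation of a derived GWAS:
# instrument selection, winner's-curse correction, LD clumping,
# exposure-outcome harmonization and IVW with multiplicative random effects.

#' Select instruments by p-value threshold
#'
#' @param table a [sumstats] table; p-values are recomputed from beta/se when
#'   absent.
#' @param p_threshold keep SNPs with `p < p_threshold`. Default 5e-6, the
#'   relaxed threshold used to boost instrument counts for a low-powered
#'   derived GWAS; 5e-7 and 5e-8 serve as sensitivity thresholds.
#' @return The subset table, input order preserved.
#' @export
select_instruments <- function(table, p_threshold = 5e-6) {
  stopifnot(inherits(table, "sumstats"))
  p <- table$pvalue
  if (anyNA(p)) p <- recompute_pvalue(table$beta, table$se)
  keep <- p < p_threshold
  if (!any(keep)) stop("no SNPs pass p < ", format(p_threshold))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Winner's-curse correction by FDR inverse quantile transformation (FIQT)
#'
#' Shrinks effect sizes selected for significance back toward the null:
#' each SNP's two-sided p is Benjamini-Hochberg adjusted across the whole
#' table, and the z-score is replaced by the normal quantile of the adjusted
#' p, keeping its sign: `z_adj = sign(z) * qnorm(1 - p_adj/2)`. The adjusted
#' beta is `z_adj * se` with se unchanged. Apply genome-wide, before
#' thresholding, so the multiplicity m is the full SNP count. The returned
#' table keeps the *unadjusted* p-values (selection is done on those; see
#' [run_mr()]) and gains a `beta_raw` column.
#'
#' @param table a non-empty [sumstats] table.
#' @return The table with shrunken betas, attribute `fiqt = TRUE`.
#' @export
fiqt_adjust <- function(table) {
  stopifnot(inherits(table, "sumstats"))
  if (nrow(table) == 0L) stop("empty table")
  z <- table$beta / table$se
  p <- recompute_pvalue(table$beta, table$se)
  p_adj <- stats::p.adjust(p, method = "BH")
  # upper-tail form stays finite for p-values far below double precision of 1
  z_adj <- sign(z) * stats::qnorm(p_adj / 2, lower.tail = FALSE)
  table$beta_raw <- table$beta
  table$beta <- z_adj * table$se
  table$pvalue <- p
  attr(table, "fiqt") <- TRUE
  table
}

# r-squared lookup closure over an LD source: either a genotype panel
# (numeric matrix, SNPs in named columns; r2 = squared Pearson correlation of
# allele counts) or a precomputed long table with columns snp_a, snp_b, r2.
.ld_lookup <- function(ld) {
  if (is.matrix(ld)) {
    if (is.null(colnames(ld))) stop("LD genotype panel needs SNP column names")
    known <- colnames(ld)
    fun <- function(s1, s2) {
      suppressWarnings(stats::cor(ld[, s1], ld[, s2]))^2
    }
  } else if (is.data.frame(ld)) {
    need <- c("snp_a", "snp_b", "r2")
    if (!all(need %in% names(ld))) {
      stop("LD table needs columns snp_a, snp_b, r2")
    }
    env <- new.env(parent = emptyenv(), size = 2L * nrow(ld) + 1L)
    for (i in seq_len(nrow(ld))) {
      assign(paste(ld$snp_a[i], ld$snp_b[i], sep = "\r"), ld$r2[i], envir = env)
      assign(paste(ld$snp_b[i], ld$snp_a[i], sep = "\r"), ld$r2[i], envir = env)
    }
    known <- unique(c(ld$snp_a, ld$snp_b))
    fun <- function(s1, s2) {
      v <- mget(paste(s1, s2, sep = "\r"), envir = env,
                ifnotfound = NA_real_)[[1]]
      v
    }
  } else {
    stop("unsupported LD source: supply a genotype matrix or an r2 table")
  }
  list(r2 = fun, known = known)
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the remaining SNP with the smallest p-value as an index
#' SNP and removes every other remaining SNP on the same chromosome within
#' `window_kb` whose r-squared with the index exceeds `r2_threshold`. Ties on
#' p are broken by (chrom, pos, snp_id). Defaults mirror stringent MR
#' practice: r2 = 0.001 within 10,000 kb.
#'
#' @param table a [sumstats] table with `chrom` and `pos`.
#' @param ld LD source: a reference genotype matrix with SNP column names, or
#'   a data.frame `snp_a`/`snp_b`/`r2`.
#' @param r2_threshold remove SNPs correlated above this (default 0.001).
#' @param window_kb clump window in kilobases (default 10,000).
#' @param missing_policy `"permissive"` (default): SNP pairs absent from the
#'   LD source are treated as independent, with one warning; `"strict"`: any
#'   SNP absent from the LD source is an error.
#' @return The clumped table (index SNPs only), ordered by increasing p.
#' @export
clump <- function(table, ld, r2_threshold = 0.001, window_kb = 10000,
                  missing_policy = c("permissive", "strict")) {
  stopifnot(inherits(table, "sumstats"))
  missing_policy <- match.arg(missing_policy)
  if (nrow(table) == 0L) stop("empty table")
  if (anyNA(table$chrom) || anyNA(table$pos)) {
    stop("clumping needs chrom and pos on every SNP")
  }
  lk <- .ld_lookup(ld)
  absent <- setdiff(table$snp_id, lk$known)
  if (length(absent) > 0L) {
    if (missing_policy == "strict") {
      stop(length(absent), " SNP(s) absent from the LD source")
    }
    warning(length(absent), " SNP(s) absent from the LD source treated as ",
            "independent", call. = FALSE)
  }
  p <- table$pvalue
  if (anyNA(p)) p <- recompute_pvalue(table$beta, table$se)
  ord <- order(p, table$chrom, table$pos, table$snp_id)
  x <- as.data.frame(table)[ord, , drop = FALSE]
  px <- p[ord]
  alive <- rep(TRUE, nrow(x))
  keep <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    cand <- which(alive & seq_len(nrow(x)) > i &
                    x$chrom == x$chrom[i] &
                    abs(x$pos - x$pos[i]) <= window_kb * 1000)
    for (j in cand) {
      r2 <- lk$r2(x$snp_id[i], x$snp_id[j])
      if (is.na(r2)) r2 <- 0
      if (r2 > r2_threshold) alive[j] <- FALSE
    }
    alive[i] <- FALSE
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(table)
  structure(out, class = attrs$class, scale = attrs$scale,
            trait = attrs$trait, ncase = attrs$ncase, ntotal = attrs$ntotal,
            fiqt = attrs$fiqt)
}

#' Inverse-variance-weighted MR with multiplicative random effects
#'
#' Weighted least squares of the outcome betas on the exposure betas through
#' the origin with weights `1/se_out^2`. Heterogeneity beyond chance inflates
#' the standard error through a residual scale floored at 1 (no credit for
#' underdispersion):
#' \deqn{\hat\beta = \sum w b_x b_y / \sum w b_x^2,\quad
#'       Q = \sum w (b_y - \hat\beta b_x)^2,\quad
#'       \sigma^2 = \max(1, Q/(k-1)),\quad
#'       se = \sigma \sqrt{1/\sum w b_x^2}.}
#' With a single SNP the estimate reduces to the Wald ratio with
#' `se = se_out / |b_x|`.
#'
#' @param pairs harmonised exposure-outcome pairs from [align_tables()]
#'   (exposure = side a, outcome = side b), or any data.frame with columns
#'   `beta_a`, `se_a`, `beta_b`, `se_b`.
#' @return An object of class `mr_ivw`: list with `beta`, `se`, `pvalue`,
#'   `n_snps`, `Q`, `sigma` and (when derivable) `mean_f` of the exposure
#'   instruments.
#' @export
ivw_mre <- function(pairs) {
  need <- c("beta_a", "se_a", "beta_b", "se_b")
  if (!all(need %in% names(pairs))) {
    stop("pairs must carry beta_a/se_a (exposure) and beta_b/se_b (outcome)")
  }
  k <- nrow(pairs)
  if (k == 0L) stop("no instruments")
  bx <- pairs$beta_a; by <- pairs$beta_b; sey <- pairs$se_b
  if (any(sey <= 0)) stop("outcome se must be > 0")
  if (k == 1L && bx == 0) stop("single instrument with zero exposure effect")
  w <- 1 / sey^2
  swx2 <- sum(w * bx^2)
  beta <- sum(w * bx * by) / swx2
  Q <- sum(w * (by - beta * bx)^2)
  sigma <- if (k >= 2L) sqrt(max(1, Q / (k - 1))) else 1
  se <- sigma * sqrt(1 / swx2)
  structure(list(beta = beta, se = se,
                 pvalue = recompute_pvalue(beta, se),
                 n_snps = k, Q = Q, sigma = sigma,
                 mean_f = if ("se_a" %in% names(pairs))
                   mean((bx / pairs$se_a)^2) else NA_real_),
            class = "mr_ivw")
}

#' @export
print.mr_ivw <- function(x, digits = 4, ...) {
  cat(sprintf(paste0("IVW MR (multiplicative random effects), %d SNP(s), ",
                     "mean F = %.1f\n"), x$n_snps, x$mean_f))
  cat(sprintf("  beta = %s  se = %s  p = %.3g  (Q = %.2f, sigma = %.3f)\n",
              format(x$beta, digits = digits), format(x$se, digits = digits),
              x$pvalue, x$Q, x$sigma))
  invisible(x)
}

#' @export
coef.mr_ivw <- function(object, ...) c(beta = object$beta)

#' @export
confint.mr_ivw <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$beta - z * object$se, object$beta + z * object$se),
              nrow = 1,
              dimnames = list("beta", sprintf("%g %%",
                                              c((1 - level) / 2,
                                                1 - (1 - level) / 2) * 100)))
  m
}

#' Mean instrument strength (F statistic)
#'
#' Per-SNP F is approximated by the squared z, `(beta/se)^2`; the mean over
#' the instrument set summarises instrument strength (values well above 10
#' indicate weak-instrument bias is unlikely to dominate).
#'
#' @param instruments a non-empty [sumstats] table of instruments.
#' @return Mean F (single number).
#' @export
mean_f <- function(instruments) {
  stopifnot(inherits(instruments, "sumstats"))
  if (nrow(instruments) == 0L) stop("empty instrument set")
  mean((instruments$beta / instruments$se)^2)
}

#' Full two-sample MR validation pipeline
#'
#' For each p-value threshold: winner's-curse-correct the exposure GWAS
#' genome-wide with [fiqt_adjust()], select instruments on the *unadjusted*
#' p-values, clump them, harmonise against the outcome GWAS (palindromes
#' inferred from allele frequency by default), and estimate the causal effect
#' by [ivw_mre()] using the shrunken exposure betas. Failures at one
#' threshold (e.g. no SNP passes) are reported in the results table while the
#' other thresholds still run.
#'
#' @param exposure exposure [sumstats] table (e.g. a derived parental GWAS).
#' @param outcome outcome [sumstats] table.
#' @param ld LD source for clumping (see [clump()]).
#' @param p_thresholds instrument selection thresholds
#'   (default `c(5e-6, 5e-7, 5e-8)`).
#' @param clump_r2,clump_kb clumping parameters (defaults 0.001 and 10,000).
#' @param palindrome_policy,ambiguity_band passed to [align_tables()].
#' @param fiqt apply the winner's-curse correction (default `TRUE`).
#' @param missing_policy passed to [clump()].
#' @return An object of class `mr_scan`: a data.frame with one row per
#'   threshold (`threshold`, `n_snps`, `mean_f`, `beta`, `se`, `pvalue`, `Q`,
#'   `sigma`, `error`) carrying the per-threshold [ivw_mre()] objects in
#'   attribute `results`.
#' @export
run_mr <- function(exposure, outcome, ld,
                   p_thresholds = c(5e-6, 5e-7, 5e-8),
                   clump_r2 = 0.001, clump_kb = 10000,
                   palindrome_policy = "infer", ambiguity_band = 0.30,
                   fiqt = TRUE, missing_policy = "permissive") {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  expo <- if (fiqt) fiqt_adjust(exposure) else exposure
  rows <- vector("list", length(p_thresholds))
  results <- vector("list", length(p_thresholds))
  names(results) <- format(p_thresholds)
  for (i in seq_along(p_thresholds)) {
    thr <- p_thresholds[i]
    res <- tryCatch({
      inst <- select_instruments(expo, thr)
      inst <- clump(inst, ld, r2_threshold = clump_r2, window_kb = clump_kb,
                    missing_policy = missing_policy)
      pairs <- align_tables(inst, outcome,
                            palindrome_policy = palindrome_policy,
                            ambiguity_band = ambiguity_band)
      fit <- ivw_mre(pairs)
      fit$mean_f <- mean((pairs$beta_a / pairs$se_a)^2)
      fit$instruments <- pairs$snp_id
      fit
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(threshold = thr, n_snps = 0L, mean_f = NA_real_,
                              beta = NA_real_, se = NA_real_,
                              pvalue = NA_real_, Q = NA_real_,
                              sigma = NA_real_, error = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      results[[i]] <- res
      rows[[i]] <- data.frame(threshold = thr, n_snps = res$n_snps,
                              mean_f = res$mean_f, beta = res$beta,
                              se = res$se, pvalue = res$pvalue, Q = res$Q,
                              sigma = res$sigma, error = NA_character_,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("mr_scan", "data.frame"), results = results)
}

#' @export
print.mr_scan <- function(x, ...) {
  cat("Two-sample MR validation (IVW, multiplicative random effects)\n")
  df <- as.data.frame(x)
  df$threshold <- format(df$threshold)
  print.data.frame(df, digits = 4)
  invisible(x)
}
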