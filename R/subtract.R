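#' GWAS-by-subtraction weighted linear model on harmonised pairs
#'
#' Implements the per-SNP weighted linear model that derives the association
#' between the index person's genotype and the *other* parent's phenotype:
#' because a child inherits half of each parent's genetic liability, the
#' child-genotype/child-phenotype association is the average of the two
#' parental genotype-phenotype associations, and the child-genotype/parental-
#' phenotype association is half the corresponding parental one. Subtracting
#' the maternal-phenotype GWAS from the index GWAS therefore yields the
#' paternal-phenotype GWAS:
#' `beta_paternal = beta_child - beta_maternal`, with standard error by
#' propagation of independent errors,
#' `se = sqrt(se_child^2 + se_maternal^2)`. p-values are recomputed from the
#' derived z; eaf and alleles are carried from the reference (child) table;
#' the headline sample size is `min(n_child, n_maternal)` and both original
#' n columns are kept.
#'
#' @param pairs a `harmonized_pairs` object from [align_tables()] with the
#'   child/index GWAS as side `a` and the maternal GWAS as side `b`, both on
#'   the same effect scale (normally SMD).
#' @param force allow differing scale labels with a warning.
#' @return A [sumstats] table of class `c("gwsub", "sumstats")` carrying the
#'   derived per-SNP effects, with extra columns `n_child` and `n_maternal`.
#'   Non-finite derived rows are dropped with a count.
#' @seealso [gwas_subtract()] for the two-table interface,
#'   [genomic_inflation()], [qq_manhattan()]
#' @export
subtract_gwas <- function(pairs, force = FALSE) {
  stopifnot(inherits(pairs, "harmonized_pairs"))
  if (nrow(pairs) == 0L) stop("no harmonized pairs to subtract")
  sa <- attr(pairs, "scale_a"); sb <- attr(pairs, "scale_b")
  if (!identical(sa, sb)) {
    if (force) {
      warning("subtracting tables on different scales (", sa, " vs ", sb, ")",
              call. = FALSE)
    } else {
      stop("input scales differ (", sa, " vs ", sb,
           "); rescale both to SMD first or use force = TRUE")
    }
  }
  beta <- pairs$beta_a - pairs$beta_b
  se <- sqrt(pairs$se_a^2 + pairs$se_b^2)
  ok <- is.finite(beta) & is.finite(se) & se > 0
  if (!all(ok)) {
    warning(sum(!ok), " SNP(s) with non-finite derived values dropped",
            call. = FALSE)
  }
  out <- data.frame(
    snp_id = pairs$snp_id, chrom = pairs$chrom, pos = pairs$pos,
    effect_allele = pairs$effect_allele, other_allele = pairs$other_allele,
    eaf = pairs$eaf_a, beta = beta, se = se,
    pvalue = NA_real_, n = pmin(pairs$n_a, pairs$n_b),
    n_child = pairs$n_a, n_maternal = pairs$n_b,
    stringsAsFactors = FALSE
  )[ok, , drop = FALSE]
  if (nrow(out) == 0L) stop("no finite derived SNPs remain")
  out$pvalue <- recompute_pvalue(out$beta, out$se)
  rownames(out) <- NULL
  structure(out, class = c("gwsub", "sumstats", "data.frame"),
            scale = if (identical(sa, sb)) sa else "mixed",
            trait = "derived parental phenotype",
            ncase = NA_real_, ntotal = NA_real_)
}

#' Derive a parental-phenotype GWAS from two summary-statistic tables
#'
#' Convenience front end: harmonises the maternal table to the index (child)
#' table with [align_tables()], then applies [subtract_gwas()]. Both tables
#' should already be on the SMD scale (see [standardize_continuous()],
#' [linear_to_logodds()], [logodds_to_smd()]).
#'
#' @param child index-person GWAS ([sumstats]); its alleles, eaf and
#'   orientation define the output.
#' @param maternal GWAS of the other parent's phenotype reported on the index
#'   person's genotype.
#' @inheritParams align_tables
#' @inheritParams subtract_gwas
#' @return A `gwsub` table; see [subtract_gwas()].
#' @examples
#' child <- sumstats(data.frame(
#'   snp_id = c("rs1", "rs2"), chrom = "1", pos = c(1e5, 2e5),
#'   effect_allele = "A", other_allele = "G", eaf = 0.3,
#'   beta = c(1.0, 0.2), se = 0.1, n = 1000), scale = "smd")
#' maternal <- sumstats(data.frame(
#'   snp_id = c("rs1", "rs2"), chrom = "1", pos = c(1e5, 2e5),
#'   effect_allele = "A", other_allele = "G", eaf = 0.3,
#'   beta = c(0.4, 0.1), se = 0.1, n = 800), scale = "smd")
#' paternal <- gwas_subtract(child, maternal)
#' paternal$beta  # 0.6, 0.1
#' @export
gwas_subtract <- function(child, maternal,
                          palindrome_policy = c("infer", "drop"),
                          ambiguity_band = 0.30, force = FALSE) {
  pairs <- align_tables(child, maternal,
                        palindrome_policy = match.arg(palindrome_policy),
                        ambiguity_band = ambiguity_band)
  out <- subtract_gwas(pairs, force = force)
  attr(out, "call") <- match.call()
  out
}

#' @export
print.gwsub <- function(x, ...) {
  cat(sprintf("GWAS-by-subtraction result: %d SNP(s), scale = %s\n",
              nrow(x), attr(x, "scale")))
  lam <- tryCatch(genomic_inflation(x), error = function(e) NA_real_)
  if (is.finite(lam)) cat(sprintf("genomic inflation lambda_GC = %.3f\n", lam))
  cat(sprintf("min derived p = %.3g; %d SNP(s) at p < 5e-8\n",
              min(x$pvalue), sum(x$pvalue < 5e-8)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more row(s)\n")
  invisible(x)
}

#' Genomic-control inflation factor
#'
#' `lambda_GC` is the median association chi-square, `(beta/se)^2`, divided by
#' the median of the chi-square distribution with one degree of freedom
#' (0.4549364...). Values near 1 indicate test statistics consistent with a
#' well-calibrated null; values above 1 indicate inflation (polygenicity or
#' residual bias).
#'
#' @param table a non-empty [sumstats] table with valid beta and se.
#' @return The inflation factor (a single positive number).
#' @export
genomic_inflation <- function(table) {
  stopifnot(inherits(table, "sumstats"))
  z2 <- (table$beta / table$se)^2
  z2 <- z2[is.finite(z2)]
  if (length(z2) == 0L) stop("no finite test statistics")
  stats::median(z2) / stats::qchisq(0.5, df = 1)
}

.manhattan_coords <- function(table) {
  ord <- order(suppressWarnings(as.numeric(table$chrom)), table$chrom,
               table$pos)
  t2 <- table[ord, , drop = FALSE]
  chroms <- unique(t2$chrom)
  offset <- 0
  xs <- numeric(nrow(t2)); centers <- numeric(length(chroms))
  for (i in seq_along(chroms)) {
    sel <- t2$chrom == chroms[i]
    xs[sel] <- offset + t2$pos[sel]
    centers[i] <- offset + mean(range(t2$pos[sel]))
    offset <- offset + max(t2$pos[sel]) + 1
  }
  list(x = xs, y = -log10(t2$pvalue), chrom = t2$chrom,
       chroms = chroms, centers = centers)
}

.plot_manhattan <- function(table, main = "Manhattan plot") {
  co <- .manhattan_coords(table)
  cols <- ifelse(match(co$chrom, co$chroms) %% 2 == 0, "grey45", "grey10")
  plot(co$x, co$y, pch = 16, cex = 0.5, col = cols, xaxt = "n",
       xlab = "genomic position", ylab = expression(-log[10](p)),
       main = main, ylim = c(0, max(co$y, -log10(5e-8)) * 1.05))
  graphics::axis(1, at = co$centers, labels = co$chroms, cex.axis = 0.7)
  graphics::abline(h = -log10(5e-8), col = "red", lty = 2)
}

.plot_qq <- function(table, main = "QQ plot") {
  obs <- sort(-log10(table$pvalue), decreasing = TRUE)
  m <- length(obs)
  exp <- -log10(stats::ppoints(m))
  plot(exp, obs, pch = 16, cex = 0.5,
       xlab = expression(expected ~ -log[10](p)),
       ylab = expression(observed ~ -log[10](p)), main = main)
  graphics::abline(0, 1, col = "red")
}

#' Manhattan and QQ plots for a summary-statistic table
#'
#' Writes `<out_prefix>_manhattan.png` (genome-wide significance line at
#' 5e-8) and `<out_prefix>_qq.png` (observed vs expected -log10 p with the
#' identity line). When chromosome or position is missing the QQ plot is
#' still produced and the Manhattan plot skipped with a warning.
#'
#' @param table a [sumstats] table with p-values (recomputed from beta/se
#'   when absent).
#' @param out_prefix path prefix for the two PNG files.
#' @param width,height,res device settings passed to [grDevices::png()].
#' @return Character vector of file paths written, invisibly.
#' @export
qq_manhattan <- function(table, out_prefix, width = 1200, height = 700,
                         res = 120) {
  stopifnot(inherits(table, "sumstats"))
  if (nrow(table) == 0L) stop("empty table")
  if (anyNA(table$pvalue)) table$pvalue <- recompute_pvalue(table$beta, table$se)
  written <- character(0)
  qq_path <- paste0(out_prefix, "_qq.png")
  grDevices::png(qq_path, width = width, height = height, res = res)
  .plot_qq(table)
  grDevices::dev.off()
  written <- c(written, qq_path)
  if (anyNA(table$chrom) || anyNA(table$pos)) {
    warning("chrom/pos missing; Manhattan plot skipped", call. = FALSE)
  } else {
    man_path <- paste0(out_prefix, "_manhattan.png")
    grDevices::png(man_path, width = width, height = height, res = res)
    .plot_manhattan(table)
    grDevices::dev.off()
    written <- c(written, man_path)
  }
  invisible(written)
}

#' @export
plot.gwsub <- function(x, which = c("manhattan", "qq"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (anyNA(x$pvalue)) x$pvalue <- recompute_pvalue(x$beta, x$se)
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if ("manhattan" %in% which) .plot_manhattan(x)
  if ("qq" %in% which) .plot_qq(x)
  invisible(x)
}
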