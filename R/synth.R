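# Synthetic trio-structured data: individual-level genotypes under Mendelian
# transmission, additive phenotypes, per-SNP association scans and a
# self-contained benchmark bundle exercising every pipeline stage.

.ALLELE_PAIRS <- rbind(c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
                       c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T"))

#' Simulate trio genotype matrices under Mendelian transmission
#'
#' For each SNP four independent Bernoulli(maf) haplotypes are drawn per
#' individual: father-transmitted, father-non-transmitted,
#' mother-transmitted, mother-non-transmitted. The child genotype is the sum
#' of the two transmitted alleles, each parent the sum of their own two, so
#' the child-parent genotype correlation tends to 0.5. SNPs are laid out on
#' synthetic chromosomes at fixed 10 kb spacing so clumping windows are
#' meaningful. Optional adjacent-SNP linkage: a SNP flagged in
#' `ld_partner_of` copies each haplotype allele of the previous SNP with
#' probability `ld_tau` (allele correlation `ld_tau`, genotype r-squared
#' about `ld_tau^2`), giving real LD for the clumping stage.
#'
#' @param m_snps,n number of SNPs and individuals (both >= 1).
#' @param maf minor allele frequency, a scalar or per-SNP vector, strictly
#'   inside (0, 1).
#' @param seed optional seed set before any draw.
#' @param n_chrom number of synthetic chromosomes SNPs are split across.
#' @param spacing_bp base-pair spacing between adjacent SNPs (default 10 kb).
#' @param ld_partner_of integer vector (length `m_snps`): 0 for an
#'   independent SNP, `j - 1` to make SNP `j` a linked copy of its left
#'   neighbour (only adjacent partners on the same chromosome are supported).
#' @param ld_tau per-haplotype copy probability for linked SNPs.
#' @return List of class `trio_genomes`: integer matrices `child`, `mother`,
#'   `father` (n x m, SNP ids as column names), `snp_info` (snp_id, chrom,
#'   pos, effect_allele, other_allele, maf), `n`, `m_snps`.
#' @export
generate_trio_genomes <- function(m_snps, n, maf = 0.3, seed = NULL,
                                  n_chrom = min(20L, m_snps),
                                  spacing_bp = 10000,
                                  ld_partner_of = NULL, ld_tau = 0.8) {
  stopifnot(m_snps >= 1, n >= 1)
  maf <- rep_len(maf, m_snps)
  if (any(maf <= 0 | maf >= 1)) stop("maf must lie strictly in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ld_partner_of)) ld_partner_of <- integer(m_snps)
  stopifnot(length(ld_partner_of) == m_snps)

  chrom_size <- ceiling(m_snps / n_chrom)
  chrom_idx <- ((seq_len(m_snps) - 1L) %/% chrom_size) + 1L
  pos_in_chrom <- ((seq_len(m_snps) - 1L) %% chrom_size) + 1L
  snp_id <- sprintf("snp%05d", seq_len(m_snps))
  pair <- .ALLELE_PAIRS[sample.int(nrow(.ALLELE_PAIRS), m_snps,
                                   replace = TRUE), , drop = FALSE]
  snp_info <- data.frame(snp_id = snp_id, chrom = as.character(chrom_idx),
                         pos = pos_in_chrom * spacing_bp,
                         effect_allele = pair[, 1], other_allele = pair[, 2],
                         maf = maf, stringsAsFactors = FALSE)

  bad <- which(ld_partner_of != 0 &
                 (ld_partner_of != seq_len(m_snps) - 1L |
                    chrom_idx != c(0L, chrom_idx[-m_snps])))
  if (length(bad) > 0L) {
    stop("ld_partner_of must point to the previous SNP on the same chromosome")
  }

  child <- matrix(0L, n, m_snps, dimnames = list(NULL, snp_id))
  mother <- matrix(0L, n, m_snps, dimnames = list(NULL, snp_id))
  father <- matrix(0L, n, m_snps, dimnames = list(NULL, snp_id))

  draw_hap <- function(cols) {
    matrix(as.integer(stats::runif(n * length(cols)) <
                        rep(maf[cols], each = n)), n, length(cols))
  }
  for (ch in unique(chrom_idx)) {
    cols <- which(chrom_idx == ch)
    ft <- draw_hap(cols); fnt <- draw_hap(cols)
    mt <- draw_hap(cols); mnt <- draw_hap(cols)
    linked <- which(ld_partner_of[cols] != 0)
    for (j in linked) {
      src <- j - 1L
      copy <- stats::runif(n) < ld_tau
      ft[, j] <- ifelse(copy, ft[, src], ft[, j])
      copy <- stats::runif(n) < ld_tau
      fnt[, j] <- ifelse(copy, fnt[, src], fnt[, j])
      copy <- stats::runif(n) < ld_tau
      mt[, j] <- ifelse(copy, mt[, src], mt[, j])
      copy <- stats::runif(n) < ld_tau
      mnt[, j] <- ifelse(copy, mnt[, src], mnt[, j])
    }
    child[, cols] <- ft + mt
    mother[, cols] <- mt + mnt
    father[, cols] <- ft + fnt
  }
  structure(list(child = child, mother = mother, father = father,
                 snp_info = snp_info, n = as.integer(n),
                 m_snps = as.integer(m_snps)),
            class = "trio_genomes")
}

.geno_score <- function(geno, w) {
  nz <- which(w != 0)
  if (length(nz) == 0L) return(numeric(nrow(geno)))
  drop(geno[, nz, drop = FALSE] %*% w[nz])
}

#' Simulate trio phenotypes on generated genomes
#'
#' Continuous phenotypes are additive genetic scores plus Gaussian noise:
#' the child phenotype weights the child genotype by `w_child`, each parent's
#' phenotype weights that parent's own genotype by `w_parental`. A binary
#' paternal outcome, causally downstream of the paternal phenotype, is drawn
#' `Bernoulli(plogis(alpha + gamma * F_p))` (e.g. smoking -> lung cancer);
#' `gamma = 0` gives a null outcome.
#'
#' @param genomes a [generate_trio_genomes()] object.
#' @param w_child per-SNP weights for the child phenotype (length `m_snps`).
#' @param w_parental per-SNP weights for the parental phenotypes (defaults to
#'   `w_child`).
#' @param noise_sd SD of the phenotype noise (default 1).
#' @param alpha,gamma intercept and slope of the logistic outcome model.
#' @param seed optional seed.
#' @return List of class `trio_phenotypes`: `C_p`, `M_p`, `F_p` (numeric),
#'   `F_out` (0/1), plus `alpha`, `gamma` and the realised outcome
#'   `prevalence`.
#' @export
generate_phenotypes <- function(genomes, w_child, w_parental = w_child,
                                noise_sd = 1, alpha = -2.5, gamma = 0,
                                seed = NULL) {
  stopifnot(inherits(genomes, "trio_genomes"))
  m <- genomes$m_snps
  if (length(w_child) != m || length(w_parental) != m) {
    stop("weight vectors must have length m_snps = ", m)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- genomes$n
  C_p <- .geno_score(genomes$child, w_child) + stats::rnorm(n, 0, noise_sd)
  M_p <- .geno_score(genomes$mother, w_parental) + stats::rnorm(n, 0, noise_sd)
  F_p <- .geno_score(genomes$father, w_parental) + stats::rnorm(n, 0, noise_sd)
  F_out <- stats::rbinom(n, 1, stats::plogis(alpha + gamma * F_p))
  structure(list(C_p = C_p, M_p = M_p, F_p = F_p, F_out = F_out,
                 alpha = alpha, gamma = gamma, prevalence = mean(F_out)),
            class = "trio_phenotypes")
}

#' Per-SNP association scan (simple-regression GWAS)
#'
#' OLS of the phenotype on each SNP's allele count, with intercept, in
#' vectorised closed form; equivalent to `lm(y ~ x)` per SNP. Monomorphic
#' SNPs are dropped with a warning. Effect allele frequency is the observed
#' allele frequency.
#'
#' @param genotypes n x m allele-count matrix (e.g. `genomes$child`).
#' @param phenotype numeric vector of length n.
#' @param snp_info optional annotation data.frame as in
#'   [generate_trio_genomes()]; defaults to column names / placeholders.
#' @param chunk_size SNPs processed per block (memory control).
#' @return A [sumstats] table on the `linear` scale.
#' @export
gwas_scan <- function(genotypes, phenotype, snp_info = NULL,
                      chunk_size = 2000L) {
  stopifnot(is.matrix(genotypes), length(phenotype) == nrow(genotypes))
  n <- nrow(genotypes); m <- ncol(genotypes)
  yc <- phenotype - mean(phenotype)
  syy <- sum(yc^2)
  beta <- se <- eaf <- numeric(m)
  mono <- logical(m)
  for (start in seq(1L, m, by = chunk_size)) {
    cols <- start:min(start + chunk_size - 1L, m)
    X <- genotypes[, cols, drop = FALSE]
    storage.mode(X) <- "double"
    mx <- colMeans(X)
    sxx <- colSums(X^2) - n * mx^2
    sxy <- drop(crossprod(X, yc))
    b <- sxy / sxx
    rss <- pmax(syy - b^2 * sxx, 0)
    beta[cols] <- b
    # exact fits (zero residual) keep se positive so p stays defined
    se[cols] <- pmax(sqrt(rss / (n - 2) / sxx), .Machine$double.xmin)
    eaf[cols] <- mx / 2
    mono[cols] <- sxx <= .Machine$double.eps * n
  }
  if (is.null(snp_info)) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- sprintf("snp%05d", seq_len(m))
    snp_info <- data.frame(snp_id = ids, chrom = NA_character_,
                           pos = NA_real_, effect_allele = "A",
                           other_allele = "G", stringsAsFactors = FALSE)
  }
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) dropped", call. = FALSE)
  }
  keep <- !mono
  out <- data.frame(snp_id = snp_info$snp_id, chrom = snp_info$chrom,
                    pos = snp_info$pos,
                    effect_allele = snp_info$effect_allele,
                    other_allele = snp_info$other_allele,
                    eaf = eaf, beta = beta, se = se,
                    pvalue = NA_real_, n = n,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out$pvalue <- recompute_pvalue(out$beta, out$se)
  sumstats(out, scale = "linear", validate = FALSE)
}

#' Self-contained benchmark bundle for the whole pipeline
#'
#' Simulates trio cohorts with a sparse set of causal SNPs, runs the three
#' per-SNP scans (child phenotype, maternal phenotype and binary paternal
#' outcome, each on the index person's genotype), computes an LD r-squared
#' table from the father genotype panel for the linked SNP pairs, and
#' records the per-SNP truth `0.5 * W` that the subtraction estimator
#' targets. Each GWAS is computed on an *independent* cohort drawn from the
#' same genome design: the error-propagation step and two-sample MR both
#' assume independent input GWASs, and this mirrors the real setting of
#' combining separately published summary statistics. Under
#' `scenario = "causal"` the binary outcome depends on the paternal
#' phenotype with logistic slope `gamma`; under `"null"` the
#' exposure-outcome effect is zero while the genetic effects (and hence the
#' instruments) remain, so MR calibration can be assessed. Causal effect
#' sizes are deliberately large for desk-scale sample sizes so that
#' instruments are genome-wide detectable; each causal SNP gets an adjacent
#' linked tag SNP so clumping has real work to do.
#'
#' @param seed integer seed; the bundle is bit-reproducible from it.
#' @param scenario `"causal"` or `"null"` (exposure-outcome effect on/off).
#' @param dir optional directory: when given, the tables are also written as
#'   TSV files (`child_gwas.tsv`, `maternal_gwas.tsv`, `outcome_gwas.tsv`,
#'   `ld.tsv`, `truth.tsv`).
#' @param n,m_snps cohort and panel size.
#' @param n_causal number of causal SNPs.
#' @param w_range range of absolute causal weights (signs random).
#' @param maf_range per-SNP maf drawn uniformly from this range.
#' @param noise_sd phenotype noise SD.
#' @param alpha,gamma logistic outcome model (gamma used only when causal).
#' @param ld_tau haplotype copy probability for tag SNPs.
#' @param n_chrom synthetic chromosome count.
#' @return List of class `benchmark_bundle`: `child_gwas`, `maternal_gwas`,
#'   `outcome_gwas` ([sumstats]), `ld` (snp_a/snp_b/r2 data.frame), `truth`
#'   (snp_id/truth), and `params` (seed, scenario, causal indices, weights,
#'   gamma, alpha, ncase, ntotal, ...).
#' @export
make_benchmark_bundle <- function(seed, scenario = c("causal", "null"),
                                  dir = NULL, n = 10000, m_snps = 12000,
                                  n_causal = 15, w_range = c(0.5, 0.8),
                                  maf_range = c(0.1, 0.5), noise_sd = 1,
                                  alpha = -2.5, gamma = 0.3, ld_tau = 0.8,
                                  n_chrom = 20L) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  maf <- stats::runif(m_snps, maf_range[1], maf_range[2])
  chrom_size <- ceiling(m_snps / n_chrom)
  # causal SNPs sampled from odd offsets away from chromosome ends so each
  # can carry an adjacent tag SNP without collisions
  candidates <- which(seq_len(m_snps) %% 2L == 1L &
                        (seq_len(m_snps) - 1L) %% chrom_size != chrom_size - 1L)
  causal <- sort(sample(candidates, n_causal))
  W <- numeric(m_snps)
  W[causal] <- stats::runif(n_causal, w_range[1], w_range[2]) *
    sample(c(-1, 1), n_causal, replace = TRUE)
  ld_partner_of <- integer(m_snps)
  ld_partner_of[causal + 1L] <- causal
  gamma_eff <- if (scenario == "causal") gamma else 0

  new_cohort <- function() {
    generate_trio_genomes(m_snps, n, maf = maf, n_chrom = n_chrom,
                          ld_partner_of = ld_partner_of, ld_tau = ld_tau)
  }
  # independent cohort per GWAS: the SE-propagation step and two-sample MR
  # both assume non-overlapping input samples; cohorts are freed eagerly to
  # keep the resident set to one cohort at a time
  genomes <- new_cohort()
  snp_info <- genomes$snp_info
  phen <- generate_phenotypes(genomes, w_child = W, noise_sd = noise_sd,
                              alpha = alpha, gamma = gamma_eff)
  child_gwas <- gwas_scan(genomes$child, phen$C_p, snp_info)
  rm(genomes); gc(FALSE)

  genomes <- new_cohort()
  genomes$snp_info <- snp_info
  phen <- generate_phenotypes(genomes, w_child = W, noise_sd = noise_sd,
                              alpha = alpha, gamma = gamma_eff)
  maternal_gwas <- gwas_scan(genomes$child, phen$M_p, snp_info)
  rm(genomes); gc(FALSE)

  genomes <- new_cohort()
  genomes$snp_info <- snp_info
  phen <- generate_phenotypes(genomes, w_child = W, noise_sd = noise_sd,
                              alpha = alpha, gamma = gamma_eff)
  outcome_gwas <- gwas_scan(genomes$child, phen$F_out, snp_info)
  attr(outcome_gwas, "ncase") <- sum(phen$F_out)
  attr(outcome_gwas, "ntotal") <- n
  attr(outcome_gwas, "trait") <- "paternal binary outcome"

  pairs_idx <- cbind(causal, causal + 1L)
  ld <- data.frame(
    snp_a = snp_info$snp_id[pairs_idx[, 1]],
    snp_b = snp_info$snp_id[pairs_idx[, 2]],
    r2 = vapply(seq_len(nrow(pairs_idx)), function(i) {
      stats::cor(genomes$father[, pairs_idx[i, 1]],
                 genomes$father[, pairs_idx[i, 2]])^2
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rm(genomes); gc(FALSE)
  truth <- data.frame(snp_id = snp_info$snp_id, truth = 0.5 * W,
                      stringsAsFactors = FALSE)
  params <- list(seed = seed, scenario = scenario, n = n, m_snps = m_snps,
                 causal = causal, W = W, gamma = gamma_eff, alpha = alpha,
                 noise_sd = noise_sd, ncase = sum(phen$F_out), ntotal = n,
                 prevalence = phen$prevalence, ld_tau = ld_tau)
  bundle <- structure(list(child_gwas = child_gwas,
                           maternal_gwas = maternal_gwas,
                           outcome_gwas = outcome_gwas,
                           ld = ld, truth = truth, params = params),
                      class = "benchmark_bundle")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_sumstats(child_gwas, file.path(dir, "child_gwas.tsv"))
    write_sumstats(maternal_gwas, file.path(dir, "maternal_gwas.tsv"))
    write_sumstats(outcome_gwas, file.path(dir, "outcome_gwas.tsv"))
    utils::write.table(ld, file.path(dir, "ld.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  bundle
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("Synthetic benchmark bundle (%s): n = %d, m = %d SNPs, ",
                     "%d causal, outcome prevalence = %.3f\n"),
              p$scenario, p$n, p$m_snps, length(p$causal), p$prevalence))
  invisible(x)
}
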