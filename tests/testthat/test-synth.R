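test_that("trio genomes obey Mendelian transmission and the seed", {
  g <- generate_trio_genomes(m_snps = 5, n = 100000, maf = 0.3, seed = 31)
  expect_true(all(g$child %in% 0:2))
  for (j in 1:5) {
    expect_equal(cor(g$child[, j], g$mother[, j]), 0.5, tolerance = 0.03)
    expect_equal(cor(g$child[, j], g$father[, j]), 0.5, tolerance = 0.03)
    expect_equal(mean(g$child[, j]) / 2, 0.3, tolerance = 0.01)
  }
  g2 <- generate_trio_genomes(m_snps = 5, n = 100000, maf = 0.3, seed = 31)
  expect_identical(g$child, g2$child)
  expect_identical(g$snp_info, g2$snp_info)
  expect_error(generate_trio_genomes(3, 10, maf = 0), "maf")
  # positions advance at fixed spacing within a chromosome
  g3 <- generate_trio_genomes(10, 5, maf = 0.5, seed = 1, n_chrom = 2)
  expect_identical(unique(diff(g3$snp_info$pos[1:5])), 10000)
})

test_that("adjacent linked SNPs show the designed r2", {
  part <- c(0L, 1L, 0L, 0L)
  g <- generate_trio_genomes(4, 50000, maf = 0.3, seed = 32,
                             ld_partner_of = part, ld_tau = 0.8, n_chrom = 1)
  r2_linked <- cor(g$father[, 1], g$father[, 2])^2
  r2_free <- cor(g$father[, 3], g$father[, 4])^2
  expect_equal(r2_linked, 0.64, tolerance = 0.05)
  expect_lt(r2_free, 0.01)
  expect_error(generate_trio_genomes(4, 10, ld_partner_of = c(0L, 3L, 0L, 0L)),
               "previous SNP")
})

test_that("phenotypes are additive scores with noise; null outcome is null", {
  g <- generate_trio_genomes(3, 2000, maf = 0.4, seed = 33)
  w <- c(0.5, 0, -0.2)
  ph <- generate_phenotypes(g, w, noise_sd = 0, gamma = 0, seed = 34)
  expect_equal(ph$C_p, drop(g$child %*% w))
  expect_equal(ph$F_p, drop(g$father %*% w))
  expect_true(all(ph$F_out %in% 0:1))
  expect_equal(ph$prevalence, plogis(-2.5), tolerance = 0.25)
  expect_error(generate_phenotypes(g, w[1:2]), "length")
  # all-zero weights: phenotype is pure noise, scan z close to N(0,1)
  g2 <- generate_trio_genomes(300, 500, maf = 0.3, seed = 35)
  ph2 <- generate_phenotypes(g2, rep(0, 300), seed = 36)
  scan <- gwas_scan(g2$child, ph2$C_p, g2$snp_info)
  z <- scan$beta / scan$se
  expect_lt(abs(mean(z)), 0.2)
  expect_equal(sd(z), 1, tolerance = 0.15)
})

test_that("gwas_scan equals per-SNP lm and flags monomorphic SNPs", {
  set.seed(37)
  g <- generate_trio_genomes(4, 300, maf = 0.3, seed = 37)
  y <- rnorm(300) + 0.3 * g$child[, 2]
  scan <- gwas_scan(g$child, y, g$snp_info)
  for (j in 1:4) {
    fit <- summary(lm(y ~ g$child[, j]))$coefficients
    expect_equal(scan$beta[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(scan$se[j], fit[2, 2], tolerance = 1e-10)
  }
  expect_equal(scan$eaf, unname(colMeans(g$child)) / 2)
  expect_equal(scan$pvalue, recompute_pvalue(scan$beta, scan$se))
  # identity: phenotype equal to one SNP's genotype
  scan_id <- gwas_scan(g$child, as.numeric(g$child[, 1]), g$snp_info)
  expect_equal(scan_id$beta[1], 1, tolerance = 1e-12)
  expect_equal(scan_id$se[1], 0, tolerance = 1e-10)
  # monomorphic column dropped with a warning
  gm <- g$child; gm[, 3] <- 1L
  expect_warning(scan_m <- gwas_scan(gm, y, g$snp_info), "monomorphic")
  expect_identical(nrow(scan_m), 3L)
})

test_that("the benchmark bundle is reproducible and internally consistent", {
  b <- make_benchmark_bundle(seed = 41, scenario = "causal", n = 1500,
                             m_snps = 200, n_causal = 5, n_chrom = 4)
  b2 <- make_benchmark_bundle(seed = 41, scenario = "causal", n = 1500,
                              m_snps = 200, n_causal = 5, n_chrom = 4)
  expect_identical(b$child_gwas$beta, b2$child_gwas$beta)
  expect_identical(b$truth, b2$truth)
  expect_identical(nrow(b$child_gwas), 200L)
  expect_identical(sort(b$params$causal), which(b$truth$truth != 0))
  expect_equal(nrow(b$ld), 5L)
  expect_true(all(b$ld$r2 > 0.3))  # designed tags are in strong LD
  expect_identical(attr(b$outcome_gwas, "ncase"),
                   as.integer(b$params$ncase))
  # null scenario: same genetics switch, outcome decoupled from exposure
  bn <- make_benchmark_bundle(seed = 41, scenario = "null", n = 1500,
                              m_snps = 200, n_causal = 5, n_chrom = 4)
  expect_identical(bn$params$gamma, 0)
  expect_identical(bn$truth, b$truth)

  # round trip through the on-disk form
  dir <- withr::local_tempdir()
  bd <- make_benchmark_bundle(seed = 42, scenario = "null", dir = dir,
                              n = 500, m_snps = 50, n_causal = 2,
                              n_chrom = 2)
  expect_true(all(file.exists(file.path(dir,
    c("child_gwas.tsv", "maternal_gwas.tsv", "outcome_gwas.tsv",
      "ld.tsv", "truth.tsv")))))
  back <- read_sumstats(file.path(dir, "child_gwas.tsv"))
  expect_equal(back$beta, bd$child_gwas$beta)
})

test_that("subtracted scans recover the per-SNP truth on a small bundle", {
  b <- make_benchmark_bundle(seed = 43, scenario = "causal", n = 4000,
                             m_snps = 400, n_causal = 8, n_chrom = 4)
  pat <- suppressMessages(gwas_subtract(b$child_gwas, b$maternal_gwas))
  tr <- merge(as.data.frame(pat)[, c("snp_id", "beta", "se")], b$truth,
              by = "snp_id")
  # per-SNP recovery within 3 derived SEs at the causal SNPs
  causal <- tr[tr$truth != 0, ]
  expect_true(all(abs(causal$beta - causal$truth) < 3.5 * causal$se))
  # regression of estimate on truth has slope 1 within 3 SE
  fit <- summary(lm(beta ~ truth, data = tr))$coefficients
  expect_lt(abs(fit["truth", 1] - 1), 3 * fit["truth", 2])
})
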