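test_that("instrument selection filters on the p threshold", {
  tab <- make_table(beta = c(6, 1, 5.5), se = 1)  # p ~ 2e-9, 0.32, 4e-8
  kept <- select_instruments(tab, 5e-6)
  expect_setequal(kept$snp_id, c("rs1", "rs3"))
  expect_identical(select_instruments(tab, 1.0)$snp_id, tab$snp_id)
  expect_error(select_instruments(tab, 1e-20), "no SNPs pass")
  # default threshold is the relaxed primary one
  expect_equal(formals(select_instruments)$p_threshold, 5e-6)
})

test_that("FIQT matches a brute-force BH + quantile oracle and shrinks", {
  zs <- list(c(5, 1), c(2, 2, 2), c(-4, 0.5, 3, -1.2, 2.8))
  for (z in zs) {
    tab <- make_table(beta = z, se = 1)
    adj <- fiqt_adjust(tab)
    expect_equal(adj$beta, fiqt_oracle(z), tolerance = 1e-12)
    expect_true(all(abs(adj$beta) <= abs(z) + 1e-12))
    expect_identical(order(abs(adj$beta)), order(abs(z)))
    expect_equal(adj$beta_raw, z)
  }
  # single SNP and tied p-values are unchanged by BH
  one <- fiqt_adjust(make_table(beta = 2.2, se = 1))
  expect_equal(one$beta, 2.2, tolerance = 1e-12)
  tied <- fiqt_adjust(make_table(beta = c(2, -2, 2), se = 1))
  expect_equal(tied$beta, c(2, -2, 2), tolerance = 1e-12)
  # se scales out and back in
  scaled <- fiqt_adjust(make_table(beta = c(0.5, 0.1), se = 0.1))
  expect_equal(scaled$beta, 0.1 * fiqt_oracle(c(5, 1)), tolerance = 1e-12)
  # extreme z stays finite
  extreme <- fiqt_adjust(make_table(beta = c(45, 1), se = 1))
  expect_true(all(is.finite(extreme$beta)))
})

test_that("greedy clumping keeps index SNPs and respects window and r2", {
  tab <- make_table(beta = c(6, 5, 4.5), se = 1,
                    ids = c("lead", "near", "far"),
                    chrom = "1", pos = c(1e6, 1.005e6, 2.1e10))
  ld <- data.frame(snp_a = "lead", snp_b = "near", r2 = 0.9,
                   stringsAsFactors = FALSE)
  out <- suppressWarnings(clump(tab, ld))
  # near is in LD with the stronger lead; far is beyond any window
  expect_setequal(out$snp_id, c("lead", "far"))

  # low r2 within the window survives
  ld2 <- data.frame(snp_a = "lead", snp_b = "near", r2 = 0.0005)
  out2 <- suppressWarnings(clump(tab, ld2))
  expect_setequal(out2$snp_id, c("lead", "near", "far"))

  # distance bound: high r2 outside the window is untouched
  tab3 <- make_table(beta = c(6, 5), se = 1, ids = c("a", "b"),
                     chrom = "1", pos = c(0, 2.0e10))
  ld3 <- data.frame(snp_a = "a", snp_b = "b", r2 = 1.0)
  expect_identical(nrow(suppressWarnings(clump(tab3, ld3))), 2L)

  # genotype-panel LD source: r2 from squared allele-count correlation
  set.seed(21)
  g <- cbind(lead = rbinom(500, 2, 0.3))
  g <- cbind(g, near = ifelse(runif(500) < 0.95, g[, "lead"],
                              rbinom(500, 2, 0.3)),
             far = rbinom(500, 2, 0.3))
  out4 <- clump(tab, g)
  expect_setequal(out4$snp_id, c("lead", "far"))

  # single SNP trivially survives; strict policy rejects unknown SNPs
  expect_identical(nrow(suppressWarnings(clump(tab[1, ], ld))), 1L)
  expect_error(clump(tab, ld, missing_policy = "strict"), "absent")
})

test_that("clumped output is maximal and every removal is justified", {
  set.seed(22)
  m <- 40
  tab <- make_table(beta = rnorm(m, 5, 1), se = 1,
                    ids = sprintf("s%02d", 1:m), chrom = "1",
                    pos = sort(sample.int(5e7, m)))
  pairs <- t(combn(m, 2))
  ld <- data.frame(snp_a = sprintf("s%02d", pairs[, 1]),
                   snp_b = sprintf("s%02d", pairs[, 2]),
                   r2 = rbeta(nrow(pairs), 0.2, 2))
  out <- clump(tab, ld, r2_threshold = 0.1, window_kb = 10000)
  r2_of <- function(a, b) ld$r2[(ld$snp_a == a & ld$snp_b == b) |
                                  (ld$snp_a == b & ld$snp_b == a)]
  surv <- out$snp_id
  # no two survivors conflict
  for (i in seq_along(surv)) {
    for (j in seq_len(i - 1L)) {
      di <- abs(out$pos[i] - out$pos[j])
      if (di <= 1e7) expect_lte(r2_of(surv[i], surv[j]), 0.1)
    }
  }
  # every removed SNP conflicts with a surviving SNP of smaller p
  p_of <- setNames(recompute_pvalue(tab$beta, tab$se), tab$snp_id)
  pos_of <- setNames(tab$pos, tab$snp_id)
  gone <- setdiff(tab$snp_id, surv)
  for (s in gone) {
    conflict <- vapply(surv, function(k) {
      p_of[k] <= p_of[s] && abs(pos_of[k] - pos_of[s]) <= 1e7 &&
        r2_of(s, k) > 0.1
    }, logical(1))
    expect_true(any(conflict), info = s)
  }
})

test_that("IVW-MRE matches its formula, the Wald ratio and a WLS oracle", {
  # k = 1 reduces to the Wald ratio
  one <- data.frame(beta_a = 0.5, se_a = 0.05, beta_b = 0.2, se_b = 0.1)
  fit <- ivw_mre(one)
  expect_equal(fit$beta, 0.4)
  expect_equal(fit$se, 0.2)
  expect_equal(fit$sigma, 1)
  expect_error(ivw_mre(one[0, ]), "no instruments")
  expect_error(ivw_mre(transform(one, beta_a = 0)), "zero exposure")

  # perfect proportionality: Q = 0, sigma floored to 1
  prop <- data.frame(beta_a = c(0.1, 0.2, 0.3), se_a = 0.02,
                     beta_b = c(0.2, 0.4, 0.6), se_b = c(0.1, 0.2, 0.1))
  fitp <- ivw_mre(prop)
  expect_equal(fitp$beta, 2)
  expect_equal(fitp$Q, 0)
  expect_equal(fitp$sigma, 1)
  # with sigma floored, the SE equals the fixed-effect IVW SE
  expect_equal(fitp$se, sqrt(1 / sum(prop$beta_a^2 / prop$se_b^2)))

  # random instances against lm as a generic weighted-least-squares oracle
  set.seed(23)
  for (k in c(3, 7, 20)) {
    d <- data.frame(beta_a = rnorm(k, 0.3, 0.1), se_a = runif(k, 0.01, 0.1),
                    beta_b = rnorm(k, 0.1, 0.2), se_b = runif(k, 0.05, 0.2))
    fit <- ivw_mre(d)
    oracle <- lm(beta_b ~ 0 + beta_a, data = d, weights = 1 / d$se_b^2)
    expect_equal(fit$beta, unname(coef(oracle)), tolerance = 1e-10)
    so <- summary(oracle)
    expect_equal(fit$Q, so$sigma^2 * (k - 1), tolerance = 1e-8)
    if (so$sigma >= 1) {
      expect_equal(fit$se, so$coefficients[1, 2], tolerance = 1e-10)
    } else {
      expect_gte(fit$se, so$coefficients[1, 2])
    }
    ci <- confint(fit)
    expect_equal(unname(ci[1, 2] - ci[1, 1]), 2 * 1.959964 * fit$se,
                 tolerance = 1e-4)
  }
})

test_that("mean F is the average squared z and grows with true effects", {
  expect_equal(mean_f(make_table(beta = 5, se = 1)), 25)
  expect_equal(mean_f(make_table(beta = c(3, 4), se = 1)), 12.5)
  expect_error(mean_f(make_table(beta = 1, se = 1)[0, ]), "empty")
  # instruments drawn with true z ~ 6: E[F] = noncentrality + 1 = 37
  set.seed(24)
  z <- rnorm(4000, 6, 1)
  f <- mean_f(make_table(beta = z, se = 1))
  expect_equal(f, 37, tolerance = 0.05)
})

test_that("run_mr self-consistency: exposure regressed on itself gives slope 1", {
  set.seed(25)
  m <- 400
  z <- c(rnorm(10, 8, 0.5), rnorm(m - 10))
  expo <- make_table(beta = z * 0.05, se = 0.05, chrom = "1",
                     pos = seq_len(m) * 1e5,
                     ids = sprintf("s%03d", seq_len(m)))
  ld <- data.frame(snp_a = character(0), snp_b = character(0),
                   r2 = numeric(0))
  res <- suppressWarnings(suppressMessages(
    run_mr(expo, expo, ld, p_thresholds = c(5e-6, 0.5e-300), fiqt = FALSE)))
  expect_equal(res$beta[1], 1, tolerance = 1e-10)
  expect_equal(res$Q[1], 0, tolerance = 1e-8)
  # failing thresholds are reported without blocking others
  expect_false(is.na(res$error[2]))
  expect_identical(res$n_snps[2], 0L)
})
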