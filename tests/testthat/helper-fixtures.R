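# small in-code fixtures shared across test files

make_table <- function(beta, se = rep(0.1, length(beta)),
                       ids = sprintf("rs%d", seq_along(beta)),
                       chrom = "1", pos = seq_along(beta) * 1e5,
                       ea = "A", oa = "G", eaf = 0.3,
                       n = 1000, scale = "smd") {
  suppressWarnings(sumstats(data.frame(
    snp_id = ids, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = se, n = n, stringsAsFactors = FALSE
  ), scale = scale))
}

quiet_align <- function(...) suppressMessages(align_tables(...))

# brute-force FIQT oracle: explicit BH by sort/cummin, then normal quantile
fiqt_oracle <- function(z) {
  p <- 2 * pnorm(-abs(z))
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  p_adj <- numeric(m)
  p_adj[ord] <- adj
  sign(z) * qnorm(p_adj / 2, lower.tail = FALSE)
}
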