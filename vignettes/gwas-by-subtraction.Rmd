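---
title: "Deriving parental-phenotype GWAS summary statistics by subtraction: methods and design"
author: "gwsub package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving parental-phenotype GWAS summary statistics by subtraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwsub)
```

## The problem and the model

Parental exposures such as paternal smoking matter for offspring health, but
no GWAS of paternal smoking exists: cohort participants are the *children*,
and what has been measured against their genotypes is their own smoking and
their mothers' smoking. GWAS-by-subtraction closes the gap with an a-priori
weighted linear model (WLM) on summary statistics.

Write $\beta_{CG\_CP}$, $\beta_{CG\_MP}$, $\beta_{CG\_FP}$ for the per-SNP
association between the child's genotype and the child's, mother's and
father's phenotype. Two assumptions drive the derivation:

1. the child's genetic liability is the average of the parents' liabilities,
   $\beta_{CG\_CP} = (\beta_{FG\_FP} + \beta_{MG\_MP})/2$; and
2. the child-parent genotype association is exactly $0.5$ (Mendelian
   inheritance without assortative mating), so
   $\beta_{CG\_FP} = 0.5\,\beta_{FG\_FP}$ and
   $\beta_{CG\_MP} = 0.5\,\beta_{MG\_MP}$.

Together these give the subtraction identity

$$\beta_{CG\_FP} = \beta_{CG\_CP} - \beta_{CG\_MP}, \qquad
  se = \sqrt{se_{CG\_CP}^2 + se_{CG\_MP}^2},$$

the SE following from propagation of *independent* errors. Independence is a
real assumption: if the two input GWASs share samples and the phenotypes are
correlated, the per-SNP errors correlate and the propagated SE is
mis-calibrated (overlap deflates the derived test statistics). The
derivation also assumes the same trait architecture in parents and
offspring; the package implements the model as stated and does not attempt
to relax either assumption. Assortative mating, residual population
structure and indirect genetic effects in the input GWASs all bias the
derived statistics; none is modelled here.

`subtract_gwas()` applies the identity per SNP to allele-harmonised pairs;
`gwas_subtract()` is the two-table front end. p-values are always recomputed
from the derived $z$ (never combined from input p-values) so $z$, beta, se
and p stay mutually consistent. The derived table reports
$\min(n_{child}, n_{maternal})$ as its headline sample size — a deliberately
conservative label, since no effective-n for a WLM output is defined — and
keeps both input n columns.

## Unit rescaling

The subtraction is only meaningful when both inputs are on one scale. The
package standardises to the standardised-mean-difference (SMD) scale:

- continuous traits: divide beta and se by the phenotype SD
  (`standardize_continuous()`; the motivating lifetime-smoking analysis used
  SD = 0.6940093);
- binary traits analysed with a linear (0/1) model: divide by $p(1-p)$ with
  prevalence $p = n_{case}/n_{total}$ to reach log odds
  (`linear_to_logodds()`), then by $\pi/\sqrt{3}$, the SD of the standard
  logistic distribution, to reach SMD (`logodds_to_smd()`).

All three steps divide beta and se by the same constant, so $z$ and p are
exactly invariant, and each step is invertible. The constant $\pi/\sqrt 3$
is computed at floating precision, never a rounded decimal. Scale labels are
tracked on every table and enforced at each conversion (a `force` flag
overrides with a warning), because silently subtracting tables on different
scales is the easiest way to produce a meaningless GWAS.

## Harmonisation choices

`align_tables()` intersects on SNP id and re-expresses the second table for
the reference effect allele: swapped alleles flip the beta sign and replace
eaf by 1−eaf. Palindromic SNPs (A/T, C/G) cannot be oriented from alleles
alone; under the default `infer` policy they are kept only when both allele
frequencies fall outside the ambiguity band and on the same side of 0.5.
The band defaults to (0.30, 0.70) — the common two-sample-MR convention —
and is configurable because published analyses rarely print the exact rule
they delegated to their MR software. Indels, multi-allelic records and
duplicate ids are dropped at validation (the method operates on biallelic
common SNPs); strand-flip recovery against a reference genome is out of
scope. Every drop is counted by category.

Positions are 1-based throughout, as in conventional GWAS exports.

## Monte-Carlo validation

`run_simulation()` reproduces the estimator-bias comparison in the ADEMP
style. Per replicate of $n$ individuals: transmitted alleles
$F_i, M_i \sim \mathrm{Bernoulli}(maf)$; child genotype $C_g = F_i + M_i$;
weight $W \sim N(w_{mean}, w_{scale})$; phenotypes
$C_p = C_g W + N(0, \sigma)$, $M_p = (M_{nt} + M_i) W + N(0, \sigma)$,
$F_p = (F_i + F_{nt}) W + N(0, \sigma)$ with independent Bernoulli
non-transmitted alleles. The estimand is the child-genotype/paternal-
phenotype slope, $0.5\,W$. Two estimators are compared: the *direct*
regression of $F_p$ on $C_g$ (what a traditional paternal GWAS would do if
it existed) and the *WLM*, slope($C_p \sim C_g$) − slope($M_p \sim C_g$).
Per estimator the package reports mean bias, Monte-Carlo SE
($sd(bias)/\sqrt{reps}$, reported as missing for a single replicate) and
the normal 95% CI.

Parameter notes, decided once:

- $W \sim N(1, 0.006)$ is read with 0.006 as the **standard deviation**
  (the `rnorm` convention a native-R analysis would use); a
  `variance_parameterization` switch exposes the other reading, which at
  this magnitude is practically indistinguishable.
- The maternal genotype's non-transmitted allele is an independent
  Bernoulli(0.5) draw, mirroring the paternal construction.
- Replicate count and per-replicate $n$ are not dictated by the published
  account; the defaults reps = 1,000, n = 10,000 give a Monte-Carlo SE near
  0.001, matching the ±0.002 CI half-widths of the reported biases, and are
  configurable.
- $W$ is redrawn every replicate in `run_simulation()`; `run_grid()` holds
  it fixed within a cell while the cell's allele frequency drives all four
  allele draws, mirroring a design that swept the observed effect sizes and
  allele frequencies of genome-wide-significant smoking SNPs (the package's
  reference grid uses six-number summaries spanning betas 0.010–0.035 and
  frequencies 0.05–0.50).
- Regressions include an intercept: the simulated phenotypes are not
  mean-centred.
- One master seed spawns per-replicate substreams, so results are
  bit-reproducible and independent of evaluation order.

Both estimators are unbiased under this mechanism; the simulation
demonstrates the WLM performs like the (infeasible) direct GWAS in bias,
not that it beats it.

## QC diagnostics

`genomic_inflation()` computes $\lambda_{GC}$ = median$(z^2)$ divided by the
$\chi^2_1$ median (0.4549…). No standard error is attached: the package
reports only the point estimate, since the SE of a sample median of
dependent test statistics admits several conventions and none is implemented
here. `qq_manhattan()` writes the two standard diagnostic plots with the
genome-wide line at $5\times 10^{-8}$; a missing position column skips the
Manhattan plot but never the QQ plot. Note that $\lambda_{GC}$ is a median:
in a polygenic GWAS (or a benchmark panel with a non-trivial causal
fraction) it sits above 1 even when every test is correct.

## MR validation stage

`run_mr()` validates a derived GWAS by two-sample Mendelian randomization
against a downstream outcome, per threshold in {5e-6, 5e-7, 5e-8} (the
relaxed primary threshold trades instrument strength for count in a
low-powered derived GWAS):

1. **FIQT winner's-curse correction**, genome-wide *before* thresholding:
   each two-sided p is Benjamini–Hochberg adjusted over all m SNPs and the z
   replaced by $\mathrm{sign}(z)\,\Phi^{-1}(1 - p_{adj}/2)$, beta by
   $z_{adj} \cdot se$. Applying it genome-wide is deliberate — the
   correction depends on the full multiplicity — and shrinkage never crosses
   zero or reorders $|z|$. Selection then uses the **unadjusted** p-values
   (keeping the discovery set) while estimation uses the shrunken betas;
   both choices are switchable. Mean instrument F is computed on the
   shrunken betas, i.e. on the instrument set actually used.
2. **Greedy clumping** (r² 0.001 within 10,000 kb): lowest-p SNP indexes,
   correlated neighbours are removed; ties break on (chrom, pos, id). The
   LD source is either a reference genotype panel (r² = squared Pearson
   correlation of allele counts) or a precomputed long-format r² table;
   pairs absent from the source are treated as independent with a warning
   (`strict` makes absence an error).
3. **Harmonisation** against the outcome reuses `align_tables()` with the
   same palindrome inference.
4. **IVW with multiplicative random effects**: weighted least squares of
   outcome on exposure betas through the origin, weights $1/se_{out}^2$;
   residual scale $\sigma = \sqrt{\max(1, Q/(k-1))}$ — floored at 1 so
   underdispersion earns no credit — multiplies the fixed-effect SE. With
   one SNP this is exactly the Wald ratio.

Failures at one threshold (no instrument passes, empty harmonisation) are
reported in the result row while other thresholds still run. MR-Egger,
weighted-median, MR-PRESSO and multivariable MR are out of scope.

## Synthetic data and the benchmark bundle

`generate_trio_genomes()` draws four independent Bernoulli(maf) haplotypes
per SNP per trio and assembles child/mother/father allele counts, so
Mendelian structure (child–parent genotype correlation → 0.5) holds by
construction. SNPs sit at fixed 10 kb spacing on synthetic chromosomes so
clumping windows mean something. Optional adjacent-SNP linkage copies each
haplotype allele from the left neighbour with probability τ, giving
genotype r² ≈ τ² — real LD for the clumping stage. The generator does *not*
emulate realistic LD maps, MAF spectra or imputation artefacts; passing
tests show the pipeline's statistics behave as designed under clean
Mendelian sampling, not that real-cohort pathologies are handled.

`make_benchmark_bundle()` wires everything together: sparse causal weights,
three per-SNP scans, an LD table from the father panel, and the per-SNP
truth $0.5\,W$. Design choices:

- **Independent cohorts per GWAS.** The child-phenotype, maternal-phenotype
  and outcome GWASs each come from a fresh cohort. Sharing one cohort would
  correlate the child and maternal scans (the phenotypes are genetically
  correlated), violate the SE-propagation assumption and visibly deflate
  the derived GWAS's λ. The bundle emulates the intended two-sample
  setting.
- **Reference sizes** n = 10,000, m = 12,000 SNPs, 15 causal. The panel is
  sized so the λ sampling SD (≈ 2.33/√m ≈ 0.02) makes a [0.95, 1.05]
  calibration window meaningful; the cohort is sized to generate in about a
  minute. Null-calibration sweeps use reduced bundles
  (n = 6,000, m = 600, 12 causal).
- **Inflated effects.** Causal |W| ∈ [0.5, 0.8] per allele — far larger
  than real smoking-GWAS effects — so that a desk-scale cohort yields
  genome-wide-detectable instruments (derived-GWAS z ≈ 5–10). The bundle
  validates machinery at reduced n, not realistic per-SNP effect sizes.
- **Outcome model.** The binary paternal outcome is
  $\mathrm{Bernoulli}(\mathrm{logit}^{-1}(\alpha + \gamma F_p))$ with
  α = −2.5 (prevalence ≈ 7–8%, a plausible disease rate) and γ = 0.3 under
  the causal scenario. The outcome GWAS is emitted on the linear 0/1 scale
  with case counts in metadata, precisely so the binary rescaling chain is
  exercised downstream; after `linear_to_logodds()`, the IVW estimate
  targets γ up to the usual marginal-logistic approximation (a few percent
  at this prevalence, well inside the IVW CI at these instrument counts).
- **`scenario = "null"`** switches γ to 0 while keeping the genetic
  effects, so instruments exist but the causal effect is absent — the
  configuration needed to check MR type-I calibration. A fully null genome
  (every W = 0, λ ≈ 1 exactly) is available via `n_causal = 0`.
- Every generator is bit-reproducible from its seed; causal SNPs are placed
  away from chromosome ends so each can carry an adjacent LD tag.

## Numerical details

- p-values from normal tails are floored at the smallest positive double so
  they stay in (0, 1]; FIQT uses the upper-tail quantile form, which stays
  finite for p far below 1e-300.
- Closed-form OLS (slope, SE) is used for per-SNP scans and the simulation
  estimators; it matches `lm()` to 1e-10 and is exercised against it in the
  tests. Exact fits (zero residual) keep an epsilon-positive SE.
- `write_sumstats()` serialises numerics with 17 significant digits so
  write/read round trips are exact.
- Monomorphic SNPs, non-finite derived rows and invalid records are always
  dropped with categorised counts, never silently.

## Reference test settings

The checked-in tests run the simulation at its defaults
(1,000 × n = 10,000; under 5 s), the 6×6 grid at 250 replicates of
n = 2,000 per cell, one causal and one null full-size bundle, and twenty
reduced null bundles for MR calibration; the whole suite completes in a few
minutes on one core. Numbers quoted in the README are the output of exactly
these runs.

## Known limitations

- No modelling of sample overlap between input GWASs (the SE assumes
  independence).
- No liability-scale conversion; the binary chain assumes the
  linear-probability-model convention for 0/1 traits.
- Palindrome inference is frequency-based only; ancestry mismatch between
  tables can defeat it.
- The MR stage implements IVW-MRE only, by design.
- λ_GC is reported without a standard error.
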