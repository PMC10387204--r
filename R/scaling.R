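# Unit rescaling onto the standardised-mean-difference (SMD) scale.
# Each conversion divides beta and se by the same positive constant, so
# z = beta/se and hence p-values are invariant; eaf and n pass through.

.check_scale <- function(table, expected, force) {
  got <- attr(table, "scale")
  if (!identical(got, expected)) {
    if (force) {
      warning("table scale is '", got, "', expected '", expected,
              "'; proceeding because force = TRUE", call. = FALSE)
    } else {
      stop("table scale is '", got, "', expected '", expected, "'")
    }
  }
}

.rescale <- function(table, divisor, new_scale) {
  table$beta <- table$beta / divisor
  table$se <- table$se / divisor
  attr(table, "scale") <- new_scale
  table
}

#' Standardise a continuous-trait GWAS by the phenotype SD
#'
#' Divides beta and se by the phenotype standard deviation so effects are in
#' SD units (SMD scale). The lifetime-smoking analysis this mirrors used
#' `phenotype_sd = 0.6940093`.
#'
#' @param table a [sumstats] table on the `linear` scale.
#' @param phenotype_sd standard deviation of the phenotype, > 0.
#' @param force bypass the scale-label check with a warning.
#' @return The rescaled table with scale `smd`.
#' @export
standardize_continuous <- function(table, phenotype_sd, force = FALSE) {
  stopifnot(inherits(table, "sumstats"))
  if (!is.finite(phenotype_sd) || phenotype_sd <= 0) {
    stop("phenotype_sd must be > 0")
  }
  .check_scale(table, "linear", force)
  .rescale(table, phenotype_sd, "smd")
}

#' Convert linear-model betas on a binary trait to log odds ratios
#'
#' Linear-probability-model effects on a 0/1 trait are converted to log odds
#' ratios by dividing beta and se by `p(1 - p)`, where `p = ncase/ntotal` is
#' the trait prevalence. The maternal-smoking analysis used
#' `ncase = 121634`, `ntotal = 397732`.
#'
#' @param table a [sumstats] table on the `linear` scale (0/1 trait).
#' @param ncase,ntotal case and total counts, `0 < ncase < ntotal`; taken
#'   from the table's metadata when omitted.
#' @param force bypass the scale-label check with a warning.
#' @return The rescaled table with scale `logodds`.
#' @export
linear_to_logodds <- function(table, ncase = attr(table, "ncase"),
                              ntotal = attr(table, "ntotal"), force = FALSE) {
  stopifnot(inherits(table, "sumstats"))
  if (is.na(ncase) || is.na(ntotal) || ncase <= 0 || ncase >= ntotal) {
    stop("need 0 < ncase < ntotal (divisor p(1-p) would be zero)")
  }
  .check_scale(table, "linear", force)
  p <- ncase / ntotal
  .rescale(table, p * (1 - p), "logodds")
}

#' Convert log odds ratios to standardised mean differences
#'
#' Divides beta and se by `pi/sqrt(3)` (the SD of the standard logistic
#' distribution), the usual logistic-to-SMD conversion.
#'
#' @param table a [sumstats] table on the `logodds` scale.
#' @param force bypass the scale-label check with a warning.
#' @return The rescaled table with scale `smd`.
#' @export
logodds_to_smd <- function(table, force = FALSE) {
  stopifnot(inherits(table, "sumstats"))
  .check_scale(table, "logodds", force)
  .rescale(table, pi / sqrt(3), "smd")
}
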