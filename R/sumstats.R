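.SUMSTAT_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")
.MANDATORY_COLS <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
.SCALES <- c("linear", "logodds", "smd")

#' GWAS summary-statistic table
#'
#' Builds a validated per-SNP summary-statistic table, the common currency of
#' the subtraction pipeline. One row per SNP with the canonical columns
#' `snp_id`, `chrom`, `pos` (1-based), `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pvalue` and `n`. Rows violating the record invariants
#' (non-positive `se`, `eaf` outside `[0, 1]`, identical or non-ACGT
#' single-base alleles, duplicated `snp_id`) are dropped with a categorised
#' message; missing mandatory columns are an error.
#'
#' @param x data.frame with at least the mandatory columns (`snp_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se`); missing optional columns
#'   are filled with `NA`.
#' @param scale effect-size scale the betas are on: `"linear"` (per-unit of
#'   the raw phenotype), `"logodds"`, or `"smd"` (per phenotype SD).
#' @param trait optional trait label.
#' @param ncase,ntotal optional case and total counts for binary traits
#'   (used by [linear_to_logodds()]).
#' @param validate set to `FALSE` to skip row filtering (internal use on
#'   already-validated data).
#' @return An object of class `sumstats` (a data.frame with `scale`, `trait`,
#'   `ncase`, `ntotal` attributes).
#' @seealso [read_sumstats()], [write_sumstats()], [align_tables()]
#' @export
sumstats <- function(x, scale = c("linear", "logodds", "smd"),
                     trait = NA_character_, ncase = NA_real_,
                     ntotal = NA_real_, validate = TRUE) {
  scale <- match.arg(scale)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_mand <- setdiff(.MANDATORY_COLS, names(x))
  if (length(missing_mand) > 0L) {
    stop("mandatory column(s) missing: ", paste(missing_mand, collapse = ", "))
  }
  for (col in setdiff(.SUMSTAT_COLS, names(x))) x[[col]] <- NA
  x <- x[, .SUMSTAT_COLS]
  x$snp_id <- as.character(x$snp_id)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  if (validate) x <- .validate_rows(x)
  structure(x, class = c("sumstats", "data.frame"),
            scale = scale, trait = trait, ncase = ncase, ntotal = ntotal)
}

.validate_rows <- function(x) {
  drops <- c(unparseable = 0L, bad_se = 0L, bad_eaf = 0L, bad_allele = 0L,
             bad_pvalue = 0L, duplicate = 0L)
  keep <- rep(TRUE, nrow(x))

  bad <- is.na(x$snp_id) | is.na(x$beta) | is.na(x$se)
  drops["unparseable"] <- sum(bad & keep); keep <- keep & !bad

  bad <- !is.na(x$se) & x$se <= 0
  drops["bad_se"] <- sum(bad & keep); keep <- keep & !bad

  bad <- !is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1)
  drops["bad_eaf"] <- sum(bad & keep); keep <- keep & !bad

  single <- x$effect_allele %in% c("A", "C", "G", "T") &
    x$other_allele %in% c("A", "C", "G", "T")
  bad <- !single | (x$effect_allele == x$other_allele)
  drops["bad_allele"] <- sum(bad & keep); keep <- keep & !bad

  bad <- !is.na(x$pvalue) & (x$pvalue <= 0 | x$pvalue > 1)
  drops["bad_pvalue"] <- sum(bad & keep); keep <- keep & !bad

  dup_ids <- unique(x$snp_id[duplicated(x$snp_id)])
  bad <- x$snp_id %in% dup_ids
  drops["duplicate"] <- sum(bad & keep); keep <- keep & !bad

  if (any(drops > 0L)) {
    msg <- paste(sprintf("%s=%d", names(drops)[drops > 0L], drops[drops > 0L]),
                 collapse = ", ")
    warning(sum(drops), " record(s) dropped during validation (", msg, ")",
            call. = FALSE)
  }
  rownames(x) <- NULL
  x[keep, , drop = FALSE]
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %d SNP(s), scale = %s%s\n",
              nrow(x), attr(x, "scale"),
              if (is.na(attr(x, "trait"))) "" else
                paste0(", trait = ", attr(x, "trait"))))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more row(s)\n")
  invisible(x)
}

#' Read a GWAS summary-statistic table from delimited text
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map optional named character vector mapping source headers
#'   to canonical names, e.g. `c(BETA = "beta", SE = "se")`.
#' @param scale effect-size scale label recorded on the table.
#' @param sep field separator (default tab).
#' @inheritParams sumstats
#' @return A validated [sumstats] table.
#' @export
read_sumstats <- function(path, column_map = NULL,
                          scale = c("linear", "logodds", "smd"),
                          trait = NA_character_, ncase = NA_real_,
                          ntotal = NA_real_, sep = "\t") {
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""), comment.char = "")
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(x))
    if (anyNA(idx)) {
      stop("column_map refers to absent column(s): ",
           paste(names(column_map)[is.na(idx)], collapse = ", "))
    }
    names(x)[idx] <- unname(column_map)
  }
  sumstats(x, scale = scale, trait = trait, ncase = ncase, ntotal = ntotal)
}

#' Write a summary-statistic table as tab-separated text
#'
#' Numeric fields are serialised with enough digits that
#' `read_sumstats(write_sumstats(t))` round-trips every value exactly;
#' missing values are written as `NA`.
#'
#' @param table a [sumstats] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats"))
  out <- as.data.frame(table)
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), NA, sprintf("%.17g", v))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Two-sided normal p-value from an effect and its standard error
#'
#' p-values of derived tables are always recomputed from `beta/se` so that z,
#' beta, se and p stay mutually consistent; extreme tails are floored at the
#' smallest positive double so p stays in (0, 1].
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), all > 0.
#' @return p-value(s) in (0, 1].
#' @export
recompute_pvalue <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be finite and > 0")
  p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  pmax(p, .Machine$double.xmin)
}

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonise two summary-statistic tables to a shared effect allele
#'
#' Intersects two tables on `snp_id` and expresses both effects for the
#' reference table's effect allele. When the other table's alleles are
#' swapped relative to the reference, its beta is sign-flipped and its effect
#' allele frequency replaced by `1 - eaf`. Palindromic SNPs (A/T, C/G) cannot
#' be resolved from alleles alone: with `palindrome_policy = "infer"` they are
#' kept only when both allele frequencies are available, fall outside the
#' ambiguity band and lie on the same side of 0.5 (after nominal alignment);
#' otherwise, and always under `"drop"`, they are removed. SNPs with
#' incompatible alleles are dropped. Each drop is counted by category in a
#' message.
#'
#' @param ref reference [sumstats] table (its alleles and orientation win).
#' @param other table to align to `ref`.
#' @param palindrome_policy `"infer"` (frequency-based, the default) or
#'   `"drop"`.
#' @param ambiguity_band half-width of the ambiguous frequency region around
#'   0.5: frequencies in `(ambiguity_band, 1 - ambiguity_band)` cannot resolve
#'   a palindrome. Default 0.30, the common two-sample-MR convention.
#' @return A data.frame of class `harmonized_pairs` with columns `snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta_a`, `se_a`,
#'   `eaf_a`, `n_a`, `beta_b`, `se_b`, `eaf_b`, `n_b` and logical flags
#'   `swapped`, `palindromic`, `inferred`.
#' @export
align_tables <- function(ref, other, palindrome_policy = c("infer", "drop"),
                         ambiguity_band = 0.30) {
  stopifnot(inherits(ref, "sumstats"), inherits(other, "sumstats"))
  palindrome_policy <- match.arg(palindrome_policy)
  if (!isTRUE(all.equal(ambiguity_band, 0.5)) &&
      (ambiguity_band < 0 || ambiguity_band > 0.5)) {
    stop("ambiguity_band must lie in [0, 0.5]")
  }
  sa <- attr(ref, "scale"); sb <- attr(other, "scale")
  if (!identical(sa, sb)) {
    message("aligning tables with different effect scales (", sa, " vs ", sb,
            "); fine for exposure-outcome pairs, not for subtraction")
  }

  idx <- match(ref$snp_id, other$snp_id)
  present <- !is.na(idx)
  if (!any(present)) stop("no SNPs shared between the two tables")
  a <- as.data.frame(ref)[present, , drop = FALSE]
  b <- as.data.frame(other)[idx[present], , drop = FALSE]

  direct <- b$effect_allele == a$effect_allele &
    b$other_allele == a$other_allele
  swapped <- b$effect_allele == a$other_allele &
    b$other_allele == a$effect_allele
  pal <- .is_palindromic(a$effect_allele, a$other_allele)

  beta_b <- ifelse(swapped & !direct, -b$beta, b$beta)
  eaf_b <- ifelse(swapped & !direct, 1 - b$eaf, b$eaf)

  drop_mismatch <- !(direct | swapped)
  inferred <- rep(FALSE, nrow(a))
  drop_pal <- rep(FALSE, nrow(a))
  if (any(pal)) {
    if (palindrome_policy == "drop") {
      drop_pal <- pal
    } else {
      lo <- ambiguity_band; hi <- 1 - ambiguity_band
      resolvable <- !is.na(a$eaf) & !is.na(eaf_b) &
        (a$eaf <= lo | a$eaf >= hi) & (eaf_b <= lo | eaf_b >= hi) &
        ((a$eaf < 0.5) == (eaf_b < 0.5))
      drop_pal <- pal & !resolvable
      inferred <- pal & resolvable
    }
  }

  keep <- !(drop_mismatch | drop_pal)
  n_missing <- sum(!present)
  counts <- c(missing = n_missing, mismatch = sum(drop_mismatch),
              palindrome = sum(drop_pal))
  if (any(counts > 0L)) {
    message("align_tables dropped ", sum(counts), " SNP(s): ",
            paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  }
  if (!any(keep)) stop("no SNPs remain after harmonization")

  out <- data.frame(
    snp_id = a$snp_id, chrom = a$chrom, pos = a$pos,
    effect_allele = a$effect_allele, other_allele = a$other_allele,
    beta_a = a$beta, se_a = a$se, eaf_a = a$eaf, n_a = a$n,
    beta_b = beta_b, se_b = b$se, eaf_b = eaf_b, n_b = b$n,
    swapped = swapped & !direct, palindromic = pal, inferred = inferred,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("harmonized_pairs", "data.frame"),
            scale_a = sa, scale_b = sb)
}
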