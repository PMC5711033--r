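#' Construct a set of SNP-trait summary associations
#'
#' A `summary_assoc` object is a data frame holding one GWAS-style association
#' record per row: the effect of a SNP on a trait, its standard error, the
#' two-sided p-value, the sample size and the effect allele. Effect size and
#' standard error may be `NA`: the correlation between instrument and trait can
#' be recovered from the p-value and sample size alone (see [r_from_pn()]),
#' which is all the Steiger machinery needs.
#'
#' @param snp SNP identifiers (character).
#' @param trait Trait labels (character).
#' @param pval Two-sided p-values, each in (0, 1].
#' @param n Per-record sample sizes, each >= 4.
#' @param beta Optional effect sizes (trait units per effect allele).
#' @param se Optional standard errors of `beta` (> 0 where given).
#' @param effect_allele Optional effect allele labels.
#'
#' @return A data frame of class `summary_assoc` with columns `snp`, `trait`,
#'   `beta`, `se`, `pval`, `n`, `effect_allele`.
#' @export
#' @examples
#' summary_assoc(snp = "rs1", trait = "cg0001", pval = 1e-8, n = 600)
summary_assoc <- function(snp, trait, pval, n,
                          beta = NA_real_, se = NA_real_,
                          effect_allele = NA_character_) {
  out <- data.frame(
    snp = as.character(snp),
    trait = as.character(trait),
    beta = as.numeric(beta),
    se = as.numeric(se),
    pval = as.numeric(pval),
    n = as.numeric(n),
    effect_allele = as.character(effect_allele),
    stringsAsFactors = FALSE
  )
  validate_summary_assoc(out)
  class(out) <- c("summary_assoc", "data.frame")
  out
}

validate_summary_assoc <- function(x, rows = seq_len(nrow(x))) {
  bad_p <- which(!is.finite(x$pval) | x$pval <= 0 | x$pval > 1)
  if (length(bad_p) > 0) {
    stop("p-values must lie in (0, 1]; offending row(s): ",
         paste(rows[bad_p], collapse = ", "), call. = FALSE)
  }
  bad_n <- which(!is.finite(x$n) | x$n < 4)
  if (length(bad_n) > 0) {
    stop("sample sizes must be >= 4 (Fisher z needs N - 3 > 0); offending row(s): ",
         paste(rows[bad_n], collapse = ", "), call. = FALSE)
  }
  bad_se <- which(!is.na(x$se) & x$se <= 0)
  if (length(bad_se) > 0) {
    stop("standard errors must be > 0 where provided; offending row(s): ",
         paste(rows[bad_se], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Default column-name mapping for summary-statistic tables
#'
#' Maps the canonical record fields onto the column names used in a particular
#' file. Override entries to load other dialects, e.g.
#' `summary_dialect(pval = "P", n = "N", snp = "SNP")`.
#'
#' @param snp,trait,beta,se,pval,n,effect_allele Column names in the file.
#' @return Named character vector mapping field -> file column.
#' @export
summary_dialect <- function(snp = "snp", trait = "trait", beta = "beta",
                            se = "se", pval = "pval", n = "n",
                            effect_allele = "effect_allele") {
  c(snp = snp, trait = trait, beta = beta, se = se, pval = pval, n = n,
    effect_allele = effect_allele)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a summary-statistic table
#'
#' Reads a delimited text file (tab or comma, auto-detected) with a header
#' line into a [summary_assoc()] data frame. Required columns are `pval` and
#' `n` (plus `snp` and `trait` identifiers); `beta`, `se` and `effect_allele`
#' are optional and filled with `NA` when absent from the file.
#'
#' @param path Path to a delimited text file with header.
#' @param dialect Column-name mapping, see [summary_dialect()].
#' @return A `summary_assoc` data frame, one record per input row.
#' @export
read_summary_table <- function(path, dialect = summary_dialect()) {
  raw <- utils::read.table(path, header = TRUE, sep = detect_delim(path),
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("snp", "trait", "pval", "n")
  missing_cols <- required[!dialect[required] %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("required column(s) not found in ", path, ": ",
         paste(dialect[missing_cols], collapse = ", "),
         " (adjust the dialect mapping)", call. = FALSE)
  }
  pick <- function(field, default) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else default
  }
  nr <- nrow(raw)
  out <- data.frame(
    snp = as.character(pick("snp", NA)),
    trait = as.character(pick("trait", NA)),
    beta = suppressWarnings(as.numeric(pick("beta", rep(NA_real_, nr)))),
    se = suppressWarnings(as.numeric(pick("se", rep(NA_real_, nr)))),
    pval = suppressWarnings(as.numeric(pick("pval", rep(NA_real_, nr)))),
    n = suppressWarnings(as.numeric(pick("n", rep(NA_real_, nr)))),
    effect_allele = as.character(pick("effect_allele", rep(NA_character_, nr))),
    stringsAsFactors = FALSE
  )
  unparseable <- which(is.na(out$pval) | is.na(out$n))
  if (length(unparseable) > 0) {
    stop("unparseable pval/n field(s) in ", path, "; offending row(s): ",
         paste(unparseable, collapse = ", "), call. = FALSE)
  }
  validate_summary_assoc(out)
  class(out) <- c("summary_assoc", "data.frame")
  out
}

#' Write a summary-statistic table
#'
#' Writes a `summary_assoc` table as tab-delimited text with all floating
#' point fields printed at 10 significant digits, so that a read/write
#' round-trip reproduces the numeric fields at the declared precision.
#'
#' @param x A `summary_assoc` data frame.
#' @param path Output file path.
#' @export
write_summary_table <- function(x, path) {
  out <- as.data.frame(x)
  for (col in c("beta", "se", "pval", "n")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA,
                         formatC(out[[col]], digits = 10, format = "g"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Recover a correlation magnitude from a p-value and sample size
#'
#' Inverts the two-sided t-test of a simple regression slope: with
#' `t = qt(1 - pval/2, n - 2)`, the implied correlation magnitude is
#' `|r| = t / sqrt(t^2 + n - 2)`. This is the route by which GWAS summary
#' statistics (p, N) are placed on the correlation scale required by the
#' Steiger test when only summary data are available.
#'
#' @param pval Two-sided p-value(s) in (0, 1].
#' @param n Sample size(s), >= 4.
#' @return Correlation magnitude(s) in `[0, 1)`.
#' @export
#' @examples
#' r_from_pn(5e-8, 1000)
r_from_pn <- function(pval, n) {
  if (any(!is.finite(pval) | pval <= 0 | pval > 1)) {
    stop("pval must lie in (0, 1]", call. = FALSE)
  }
  if (any(!is.finite(n) | n < 4)) {
    stop("n must be >= 4", call. = FALSE)
  }
  tval <- stats::qt(pval / 2, df = n - 2, lower.tail = FALSE)
  tval / sqrt(tval^2 + n - 2)
}

#' Observed correlation triple for the Steiger test
#'
#' Bundles the correlations between the instrument and the two measured
#' traits, together with the sample size(s). Exactly one of `n` (one-sample
#' mode: all three variables measured on the same individuals, `r_xy`
#' available) or `n1`/`n2` (two-sample mode: the two instrument-trait
#' correlations estimated in independent cohorts, `r_xy` unknown) must be
#' supplied.
#'
#' @param r_gx Correlation between the instrument and the measured exposure.
#' @param r_gy Correlation between the instrument and the measured outcome.
#' @param r_xy Correlation between the two trait measurements (one-sample only).
#' @param n Common sample size (one-sample mode).
#' @param n1,n2 Per-trait sample sizes (two-sample mode).
#' @return An object of class `observed_correlations`.
#' @export
observed_correlations <- function(r_gx, r_gy, r_xy = NULL, n = NULL,
                                  n1 = NULL, n2 = NULL) {
  one_sample <- !is.null(n)
  two_sample <- !is.null(n1) || !is.null(n2)
  if (one_sample == two_sample) {
    stop("supply exactly one of n (one-sample) or n1 and n2 (two-sample)",
         call. = FALSE)
  }
  if (two_sample && (is.null(n1) || is.null(n2))) {
    stop("two-sample mode needs both n1 and n2", call. = FALSE)
  }
  for (r in c(r_gx, r_gy, r_xy)) {
    if (!is.finite(r) || abs(r) > 1) {
      stop("correlations must lie in [-1, 1]", call. = FALSE)
    }
  }
  obj <- list(
    r_gx = r_gx, r_gy = r_gy, r_xy = r_xy,
    n = n, n1 = n1, n2 = n2,
    mode = if (one_sample) "one_sample" else "two_sample"
  )
  structure(obj, class = "observed_correlations")
}

#' @export
print.observed_correlations <- function(x, ...) {
  cat("Observed correlations (", x$mode, ")\n", sep = "")
  cat(sprintf("  r_gx = %.4f, r_gy = %.4f", x$r_gx, x$r_gy))
  if (!is.null(x$r_xy)) cat(sprintf(", r_xy = %.4f", x$r_xy))
  cat("\n")
  if (x$mode == "one_sample") {
    cat("  n =", x$n, "\n")
  } else {
    cat("  n1 =", x$n1, ", n2 =", x$n2, "\n")
  }
  invisible(x)
}

#' Compute the observed correlation triple from individual-level data
#'
#' @param g Genotype vector (additively coded 0/1/2).
#' @param x,y Numeric trait vectors of the same length as `g`.
#' @return An [observed_correlations()] object in one-sample mode.
#' @export
correlations_from_individual <- function(g, x, y) {
  n <- length(g)
  if (length(x) != n || length(y) != n) {
    stop("g, x and y must have equal length", call. = FALSE)
  }
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  for (v in list(g = g, x = x, y = y)) {
    if (stats::var(v) == 0) {
      stop("degenerate input: a variable has zero variance", call. = FALSE)
    }
  }
  observed_correlations(
    r_gx = stats::cor(g, x),
    r_gy = stats::cor(g, y),
    r_xy = stats::cor(x, y),
    n = n
  )
}

#' Harmonise effect alleles between two association records
#'
#' Records for the same SNP reported against different effect alleles have
#' the outcome record's effect sign flipped so both refer to the exposure
#' record's effect allele. Correlation magnitudes (all the Steiger test uses)
#' are unaffected; only reported effect signs change.
#'
#' @param exposure,outcome Single-row `summary_assoc` records for one SNP.
#' @return A list with elements `exposure` and `outcome`, harmonised.
#' @export
harmonise_effects <- function(exposure, outcome) {
  if (exposure$snp != outcome$snp) {
    stop("records refer to different SNPs: ", exposure$snp, " vs ",
         outcome$snp, call. = FALSE)
  }
  if (!is.na(exposure$effect_allele) && !is.na(outcome$effect_allele) &&
      exposure$effect_allele != outcome$effect_allele) {
    outcome$beta <- -outcome$beta
    outcome$effect_allele <- exposure$effect_allele
  }
  list(exposure = exposure, outcome = outcome)
}
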