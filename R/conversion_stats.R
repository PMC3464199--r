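#' Estimate gene-conversion frequency from 3:1 tetrad counts
#'
#' The raw frequency is `n_31 / n_tetrads` (conversions toward the
#' fluorescent allele per locus per meiosis). Because 1:3 tetrads
#' (conversions toward the non-fluorescent allele) cannot be scored
#' reliably -- a non-fluorescent grain may reflect pollen-development
#' defects -- the adjusted frequency doubles the observed 3:1 count to
#' account for both conversion directions. Meioses-per-conversion is
#' `n_tetrads / (2 * n_31)` rounded half-up to the nearest integer, and
#' is `NA` when no conversions were observed.
#'
#' @param counts a counts data.frame (see [tetrad_counts()]).
#' @return A data.frame with one row per input row: `label`, `n_31`,
#'   `n_tetrads`, `raw_frequency`, `adjusted_frequency`,
#'   `meioses_per_conversion`.
#' @seealso [pool_counts()] for the pooled genome-wide estimate.
#' @export
#' @examples
#' estimate_frequency(tetrad_counts("424-GC1", 147848, 79))
#' # adjusted 1.07e-3, one conversion in every 936 meioses
estimate_frequency <- function(counts) {
  counts <- validate_counts(counts)
  if (any(counts$n_tetrads == 0))
    stop_domain("n_tetrads must be positive")
  raw <- counts$n_31 / counts$n_tetrads
  adj <- 2 * raw
  if (any(adj > 1))
    warning("adjusted frequency exceeds 1; the doubling adjustment is ",
            "only meaningful for rare conversions", call. = FALSE)
  mpc <- ifelse(counts$n_31 > 0,
                round_half_up(counts$n_tetrads / (2 * counts$n_31)),
                NA_real_)
  data.frame(label = counts$label,
             n_31 = counts$n_31, n_tetrads = counts$n_tetrads,
             raw_frequency = raw, adjusted_frequency = adj,
             meioses_per_conversion = mpc,
             stringsAsFactors = FALSE)
}

#' Pool counts across loci and estimate the genome-wide frequency
#'
#' Sums 3:1 counts and tetrad totals across loci, then applies
#' [estimate_frequency()] to the pooled table. On the seven genome-wide
#' test loci this gives the genome-wide average of 3.53e-4 conversions
#' per locus per meiosis (1 conversion per locus in every 2,833 meioses).
#'
#' @param counts a counts data.frame with at least one row.
#' @param label label for the pooled record.
#' @return A one-row estimate data.frame (see [estimate_frequency()]).
#' @export
#' @examples
#' pool_counts(gc_counts())
pool_counts <- function(counts, label = "total") {
  counts <- validate_counts(counts)
  if (nrow(counts) == 0) stop_domain("cannot pool an empty counts table")
  pooled <- tetrad_counts(label,
                          n_tetrads = sum(counts$n_tetrads),
                          n_31 = sum(counts$n_31),
                          n_13 = sum(counts$n_13),
                          n_40 = sum(counts$n_40),
                          n_04 = sum(counts$n_04))
  estimate_frequency(pooled)
}

#' G-test of independence on a 2x2 contingency table
#'
#' Tests whether the success proportion differs between two groups using
#' the log-likelihood-ratio (G) statistic on the table
#' `[[k1, n1-k1], [k2, n2-k2]]`:
#' `G = 2 * sum(O * ln(O / E))` with expected counts from the marginals
#' and the convention `0 * ln(0/E) = 0`. The p-value is the upper tail
#' of the chi-square distribution with 1 df. No continuity correction is
#' applied by default; `correction = "williams"` divides G by the
#' Williams factor `q`.
#'
#' A table with an all-zero success margin (`k1 = k2 = 0`) carries no
#' information about independence: G = 0, p = 1, flagged `degenerate`.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @param correction `"none"` (default) or `"williams"`.
#' @return An object of class `"g_test"`: a list with `g_statistic`,
#'   `df`, `p_value`, `degenerate`, `table`, `correction`.
#' @export
#' @examples
#' g_test_independence(17, 148886, 17, 150910)  # p ~ 0.97
g_test_independence <- function(k1, n1, k2, n2,
                                correction = c("none", "williams")) {
  correction <- match.arg(correction)
  ks <- c(k1, k2); ns <- c(n1, n2)
  if (any(is.na(ks)) || any(is.na(ns)))
    stop_domain("counts must not be NA")
  if (any(ns <= 0)) stop_domain("trial counts must be positive")
  if (any(ks < 0) || any(ks > ns))
    stop_domain("successes must satisfy 0 <= k <= n")

  O <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE,
              dimnames = list(c("group1", "group2"),
                              c("success", "failure")))
  degenerate <- any(colSums(O) == 0)
  if (degenerate) {
    g <- 0
  } else {
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    terms <- ifelse(O == 0, 0, O * log(O / E))
    g <- 2 * sum(terms)
    if (correction == "williams") {
      n <- sum(O)
      q <- 1 + (sum(n / rowSums(O)) - 1) * (sum(n / colSums(O)) - 1) / (6 * n)
      g <- g / q
    }
  }
  g <- max(g, 0)  # guard against tiny negative rounding residue
  structure(list(g_statistic = g, df = 1L,
                 p_value = stats::pchisq(g, df = 1, lower.tail = FALSE),
                 degenerate = degenerate, table = O,
                 correction = correction),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat("G-test of independence (2x2",
      if (x$correction == "williams") ", Williams-corrected" else "", ")\n",
      sep = "")
  cat(sprintf("  G = %.4f, df = %d, p = %s\n", x$g_statistic, x$df,
              format(x$p_value, digits = 4)))
  if (x$degenerate)
    cat("  note: degenerate table (all-zero margin); test uninformative\n")
  invisible(x)
}

#' Pairwise G-test matrix across loci
#'
#' Runs [g_test_independence()] on the raw 3:1 counts of every pair of
#' loci. Raw (not doubled) counts are used: doubling both margins
#' inflates G roughly twofold and does not correspond to the scored
#' observations.
#'
#' @param counts a counts data.frame with at least two rows.
#' @inheritParams g_test_independence
#' @return An object of class `"gc_pairwise"`: list with symmetric
#'   matrices `p_value` and `g_statistic` (diagonal `NA`), plus
#'   `labels`.
#' @export
#' @examples
#' m <- pairwise_g_matrix(gc_counts(include_intra = TRUE))
#' m$p_value["1369-GC1", "1369-GC2"]  # ~0.94: no intra-locus variation
pairwise_g_matrix <- function(counts, correction = c("none", "williams")) {
  correction <- match.arg(correction)
  counts <- validate_counts(counts)
  n <- nrow(counts)
  if (n < 2) stop_domain("need at least two loci for pairwise comparison")
  if (anyDuplicated(counts$label))
    stop_domain("duplicate locus labels")
  p <- g <- matrix(NA_real_, n, n, dimnames = list(counts$label, counts$label))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      res <- g_test_independence(counts$n_31[i], counts$n_tetrads[i],
                                 counts$n_31[j], counts$n_tetrads[j],
                                 correction = correction)
      p[i, j] <- p[j, i] <- res$p_value
      g[i, j] <- g[j, i] <- res$g_statistic
    }
  }
  structure(list(p_value = p, g_statistic = g, labels = counts$label),
            class = "gc_pairwise")
}

#' @export
print.gc_pairwise <- function(x, ...) {
  cat("Pairwise G-tests of conversion-frequency independence\n")
  fmt <- x$p_value
  fmt[] <- format_p_printed(x$p_value)
  fmt[is.na(x$p_value)] <- "-"
  print(as.data.frame(fmt), ...)
  invisible(x)
}

#' Compare each locus against the pooled total
#'
#' G-test of each locus' raw 3:1 counts against the pool of all loci
#' (including the locus itself). This is a reconstruction: the exact
#' procedure behind the published locus-vs-total column is not stated
#' and is not reproduced by this (or the self-excluded) comparison, so
#' these p-values should be read as indicative only.
#'
#' @param counts a counts data.frame.
#' @param pool optional counts data.frame to pool as the reference
#'   (default: `counts` itself).
#' @return data.frame with `label`, `g_statistic`, `p_value`.
#' @export
versus_pooled <- function(counts, pool = counts) {
  counts <- validate_counts(counts)
  pool <- validate_counts(pool)
  tot_k <- sum(pool$n_31); tot_n <- sum(pool$n_tetrads)
  res <- lapply(seq_len(nrow(counts)), function(i)
    g_test_independence(counts$n_31[i], counts$n_tetrads[i], tot_k, tot_n))
  data.frame(label = counts$label,
             g_statistic = vapply(res, `[[`, numeric(1), "g_statistic"),
             p_value = vapply(res, `[[`, numeric(1), "p_value"),
             stringsAsFactors = FALSE)
}

#' Compare a false-positive control against a reference locus
#'
#' G-test of a control count set (reversion or misgrouping control,
#' typically with zero 3:1 tetrads) against a scored locus, with a
#' one-line report of both frequencies. Scoring 0/45,000 control
#' tetrads against the lowest-frequency test locus (13/149,965) gives
#' p = 0.0090, showing the false-positive rate is significantly below
#' the observed conversion frequency.
#'
#' @param control,reference one-row counts data.frames.
#' @return A `"g_test"` object with an extra `report` string.
#' @export
#' @examples
#' control_comparison(control_counts()[1, ],
#'                    gc_counts()[gc_counts()$label == "1659-GC1", ])
control_comparison <- function(control, reference) {
  control <- validate_counts(control)
  reference <- validate_counts(reference)
  if (nrow(control) != 1 || nrow(reference) != 1)
    stop_domain("control and reference must each be a single count record")
  res <- g_test_independence(control$n_31, control$n_tetrads,
                             reference$n_31, reference$n_tetrads)
  res$report <- sprintf(
    "control %s: %d/%d (raw %s) vs %s: %d/%d (raw %s), G = %.3f, p = %s",
    control$label, control$n_31, control$n_tetrads,
    format_sci3(control$n_31 / control$n_tetrads),
    reference$label, reference$n_31, reference$n_tetrads,
    format_sci3(reference$n_31 / reference$n_tetrads),
    res$g_statistic, format(res$p_value, digits = 4))
  res
}

#' Regress conversion frequency on SNP position
#'
#' Ordinary least squares of adjusted conversion frequency on the SNP
#' position within the test-locus coding sequence (relative to the
#' transcriptional start site), probing for conversion polarity along
#' the gene. `r_squared` is the squared Pearson correlation; the
#' p-value is the two-sided t-test on the slope with `n - 2` df. On the
#' eight sequenced-and-scored alleles this is flat: r^2 = 0.038,
#' p = 0.645.
#'
#' @param snp_position numeric vector of SNP positions (>= 1).
#' @param adjusted_frequency matching vector of adjusted frequencies.
#' @return An object of class `"gc_regression"`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`, and the underlying `fit`.
#' @export
#' @examples
#' a <- merge(nftl_alleles(), gc_counts(include_intra = TRUE),
#'            by.x = "allele_name", by.y = "label")
#' e <- estimate_frequency(tetrad_counts(a$allele_name, a$n_tetrads, a$n_31))
#' position_regression(a$snp_position, e$adjusted_frequency)
position_regression <- function(snp_position, adjusted_frequency) {
  if (length(snp_position) != length(adjusted_frequency))
    stop_domain("position and frequency vectors must have equal length")
  if (length(snp_position) < 3)
    stop_domain("need at least 3 points for the regression")
  if (any(snp_position < 1)) stop_domain("SNP positions must be positive")
  if (stats::var(snp_position) == 0)
    stop_domain("all SNP positions identical; slope undefined")
  if (stats::var(adjusted_frequency) == 0) {
    # constant response: flat line, no explained variance, no evidence
    return(structure(list(slope = 0, intercept = adjusted_frequency[1],
                          r_squared = 0, p_value = 1,
                          n = length(snp_position), fit = NULL),
                     class = "gc_regression"))
  }
  fit <- stats::lm(adjusted_frequency ~ snp_position)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 p_value = unname(stats::coef(s)[2, 4]),
                 n = length(snp_position), fit = fit),
            class = "gc_regression")
}

#' @export
print.gc_regression <- function(x, ...) {
  cat("Regression of adjusted conversion frequency on SNP position\n")
  cat(sprintf("  n = %d, slope = %s per nt, intercept = %s\n",
              x$n, format_sci3(x$slope), format_sci3(x$intercept)))
  cat(sprintf("  r^2 = %.3f, p = %.3f\n", x$r_squared, x$p_value))
  invisible(x)
}
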