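#' Re-run the full packaged analysis
#'
#' Runs every stage of the analysis on the packaged fixtures -- per-locus
#' and pooled frequency estimates, the pairwise G-test matrix, the
#' locus-vs-pooled reconstruction, the false-positive control
#' comparisons, the SNP-position regression, the tract-length
#' reconciliation, and the three-color CO/NCO classification -- and
#' diffs each recomputed quantity against the published point estimates
#' bundled with the fixtures.
#'
#' @param dir optional output directory; when given, TSV/JSON artifacts
#'   are written (`estimates.tsv`, `pairwise_p.tsv`, `regression.json`,
#'   `tract.json`, `classes.tsv`, `diff.tsv`).
#' @return A list of class `"gc_reproduction"` with elements
#'   `estimates`, `pairwise`, `versus_pooled`, `controls`, `regression`,
#'   `tract`, `classes`, and `diff` (a data.frame with one row per
#'   checked number and a logical `match` column).
#' @export
#' @examples
#' rep <- reproduce_study()
#' all(rep$diff$match)
reproduce_study <- function(dir = NULL) {
  counts7 <- gc_counts()
  counts8 <- gc_counts(include_intra = TRUE)

  est <- estimate_frequency(counts7)
  pooled <- pool_counts(counts7)
  estimates <- rbind(est, pooled)

  pw <- pairwise_g_matrix(counts8)
  vsp <- versus_pooled(counts8, pool = counts7)

  ctl <- control_counts()
  ref1659 <- counts8[counts8$label == "1659-GC1", ]
  controls <- list(
    reversion = control_comparison(ctl[ctl$label == "reversion-control", ],
                                   ref1659),
    misgrouping = control_comparison(
      ctl[ctl$label == "misgrouping-control", ], ref1659))

  alle <- nftl_alleles(sequenced_only = TRUE)
  merged <- merge(alle, counts8, by.x = "allele_name", by.y = "label")
  est8 <- estimate_frequency(tetrad_counts(merged$allele_name,
                                           merged$n_tetrads, merged$n_31))
  reg <- position_regression(merged$snp_position, est8$adjusted_frequency)

  tract <- tract_length(pooled$adjusted_frequency)
  co_nco <- expected_co_nco_ratio()
  classes <- summarize_classes(conversion_tetrads())

  pub <- published_values()
  fmtnum <- function(x) format(x, digits = 15, trim = TRUE)
  rows <- list()
  add <- function(quantity, published, computed, match) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, published = as.character(published),
      computed = as.character(computed), match = match,
      stringsAsFactors = FALSE)
  }
  for (lab in estimates$label) {
    r <- estimates[estimates$label == lab, ]
    add(paste0("adjusted_frequency:", lab),
        format_sci3(pub$adjusted_frequency[[lab]]),
        format_sci3(r$adjusted_frequency),
        format_sci3(pub$adjusted_frequency[[lab]]) ==
          format_sci3(r$adjusted_frequency))
    add(paste0("meioses_per_conversion:", lab),
        pub$meioses_per_conversion[[lab]], fmtnum(r$meioses_per_conversion),
        pub$meioses_per_conversion[[lab]] == r$meioses_per_conversion)
  }
  printed <- pub$pairwise_printed
  for (i in seq_len(nrow(printed) - 1)) {
    for (j in seq(i + 1, ncol(printed))) {
      pval <- pw$p_value[rownames(printed)[i], colnames(printed)[j]]
      add(paste0("pairwise_p:", rownames(printed)[i], ":",
                 colnames(printed)[j]),
          printed[i, j], format_p_printed(pval),
          printed_p_match(printed[i, j], pval))
    }
  }
  add("regression_r_squared", pub$r_squared, fmtnum(reg$r_squared),
      round_half_up(reg$r_squared * 1000) / 1000 == pub$r_squared)
  add("regression_p", pub$regression_p, fmtnum(reg$p_value),
      round_half_up(reg$p_value * 1000) / 1000 == pub$regression_p)
  add("expected_conversions", paste(pub$expected_conversions, collapse = "-"),
      paste(tract$expected_conversions, collapse = "-"),
      all(tract$expected_conversions == pub$expected_conversions))
  add("per_nt_frequency",
      paste(format_sci3(pub$per_nt_frequency), collapse = "-"),
      paste(format_sci3(tract$per_nt_frequency), collapse = "-"),
      all(format_sci3(tract$per_nt_frequency) ==
            format_sci3(pub$per_nt_frequency)))
  add("tract_length", paste(pub$tract_length, collapse = "-"),
      paste(tract$tract_length, collapse = "-"),
      all(tract$tract_length == pub$tract_length))
  add("tract_length_mean", pub$tract_length_mean, fmtnum(tract$tract_length_mean),
      tract$tract_length_mean == pub$tract_length_mean)
  add("co_gc_count", pub$co_count, classes[["CO_GC"]],
      classes[["CO_GC"]] == pub$co_count)
  add("nco_gc_count", pub$nco_count, classes[["NCO_GC"]],
      classes[["NCO_GC"]] == pub$nco_count)
  add("ambiguous_count", pub$ambiguous_count, classes[["AMBIGUOUS"]],
      classes[["AMBIGUOUS"]] == pub$ambiguous_count)
  add("control_p (reconstruction: 0/45000 vs 1659-GC1)", pub$control_p,
      fmtnum(controls$reversion$p_value),
      round_half_up(controls$reversion$p_value * 1e6) / 1e6 == pub$control_p)
  diff <- do.call(rbind, rows)

  out <- structure(list(estimates = estimates, pairwise = pw,
                        versus_pooled = vsp, controls = controls,
                        regression = reg, tract = tract,
                        classes = classes, diff = diff),
                   class = "gc_reproduction")
  if (!is.null(dir)) write_reproduction(out, dir)
  out
}

write_reproduction <- function(rep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(rep$estimates, file.path(dir, "estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pm <- rep$pairwise$p_value
  utils::write.table(cbind(label = rownames(pm), as.data.frame(pm)),
                     file.path(dir, "pairwise_p.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(slope = rep$regression$slope, intercept = rep$regression$intercept,
         r_squared = rep$regression$r_squared,
         p_value = rep$regression$p_value, n = rep$regression$n),
    file.path(dir, "regression.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(expected_conversions = as.list(rep$tract$expected_conversions),
         per_nt_frequency = as.list(rep$tract$per_nt_frequency),
         tract_length = as.list(rep$tract$tract_length),
         tract_length_mean = rep$tract$tract_length_mean),
    file.path(dir, "tract.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(class = names(rep$classes), count = as.integer(rep$classes)),
    file.path(dir, "classes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(rep$diff, file.path(dir, "diff.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @export
print.gc_reproduction <- function(x, ...) {
  cat("Packaged-analysis reproduction\n")
  pooled <- x$estimates[x$estimates$label == "total", ]
  cat(sprintf("  pooled: %s adjusted (1 per %d meioses)\n",
              format_sci3(pooled$adjusted_frequency),
              pooled$meioses_per_conversion))
  cat(sprintf("  regression: r2=%.3f p=%.3f\n",
              x$regression$r_squared, x$regression$p_value))
  cat(sprintf("  tract: %d-%d bp (average %d)\n",
              x$tract$tract_length[["low"]], x$tract$tract_length[["high"]],
              x$tract$tract_length_mean))
  cat(sprintf("  classes: %d CO, %d NCO, %d ambiguous\n",
              x$classes[["CO_GC"]], x$classes[["NCO_GC"]],
              x$classes[["AMBIGUOUS"]]))
  cat(sprintf("  checks passing: %d/%d\n", sum(x$diff$match), nrow(x$diff)))
  invisible(x)
}
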