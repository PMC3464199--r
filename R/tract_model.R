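#' Inputs for the genome-wide tract-length reconciliation model
#'
#' Constants linking the observed per-locus conversion frequency to
#' genome-scale expectations: the sequenced Arabidopsis genome size and
#' an upper bound including the unsequenced centromeres and rDNA arrays;
#' the per-meiosis DSB count range inferred from RAD51 focus counts; the
#' fraction of heteroduplex events restored (rather than converted) by
#' mismatch repair; and the number of crossovers per meiosis.
#'
#' @param genome_min,genome_max genome size bounds in nucleotides.
#' @param dsb_min,dsb_max DSBs per meiosis bounds.
#' @param restoration_fraction fraction of heteroduplex events restored
#'   by MMR (default 0.5, i.e. conversion:restoration = 50:50).
#' @param co_per_meiosis crossovers per meiosis.
#' @return A validated list of class `"tract_model_inputs"`.
#' @export
tract_model_inputs <- function(genome_min = 119146348,
                               genome_max = 141146348,
                               dsb_min = 120, dsb_max = 222,
                               restoration_fraction = 0.5,
                               co_per_meiosis = 9) {
  if (genome_min <= 0 || genome_max < genome_min)
    stop_domain("need 0 < genome_min <= genome_max")
  if (dsb_min < 0 || dsb_max < dsb_min)
    stop_domain("need 0 <= dsb_min <= dsb_max")
  if (restoration_fraction < 0 || restoration_fraction > 1)
    stop_domain("restoration_fraction must be in [0, 1]")
  structure(list(genome_min = genome_min, genome_max = genome_max,
                 dsb_min = dsb_min, dsb_max = dsb_max,
                 restoration_fraction = restoration_fraction,
                 co_per_meiosis = co_per_meiosis),
            class = "tract_model_inputs")
}

#' Expected genome-wide conversions per meiosis
#'
#' If every DSB forms a heteroduplex tract and MMR restores a fraction
#' of them, the expected number of conversion events per meiosis is
#' `DSBs * (1 - restoration_fraction)`: 60-111 under the defaults.
#'
#' @param inputs a [tract_model_inputs()].
#' @return Integer vector `c(low, high)` (bounds rounded half-up).
#' @export
expected_conversions <- function(inputs = tract_model_inputs()) {
  conv <- c(inputs$dsb_min, inputs$dsb_max) * (1 - inputs$restoration_fraction)
  stats::setNames(round_half_up(conv), c("low", "high"))
}

#' Expected per-nucleotide conversion frequency
#'
#' Expected conversion events per nucleotide per meiosis, bounded by
#' pairing the low conversion count with the large genome estimate and
#' the high count with the small genome: 4.25e-7 to 9.32e-7 under the
#' defaults.
#'
#' @inheritParams expected_conversions
#' @return Numeric vector `c(low, high)`.
#' @export
per_nt_frequency <- function(inputs = tract_model_inputs()) {
  conv <- c(inputs$dsb_min, inputs$dsb_max) * (1 - inputs$restoration_fraction)
  c(low = conv[1] / inputs$genome_max,
    high = conv[2] / inputs$genome_min)
}

#' Conversion tract length implied by an observed per-locus frequency
#'
#' A single-SNP assay detects a conversion whenever the tract covers the
#' SNP, so the observed per-locus frequency is the per-nucleotide
#' frequency multiplied by the tract length. Inverting:
#' `tract = f_observed / per_nt_frequency`. The low per-nucleotide bound
#' gives the long-tract bound and vice versa. With the pooled adjusted
#' frequency (2*186/1,054,024) and default constants this reconciles the
#' observed and expected frequencies at 379-830 bp (average 605 bp).
#'
#' @param f_observed observed adjusted per-locus conversion frequency
#'   (> 0); use the full-precision pooled estimate, not a rounded one.
#' @inheritParams expected_conversions
#' @return A list of class `"tract_estimate"`: `expected_conversions`,
#'   `per_nt_frequency`, `tract_length` (integer bounds, rounded
#'   half-up), `tract_length_mean` (rounded midpoint of the unrounded
#'   bounds), and `f_observed`.
#' @export
#' @examples
#' f <- pool_counts(gc_counts())$adjusted_frequency
#' tract_length(f)
tract_length <- function(f_observed, inputs = tract_model_inputs()) {
  if (length(f_observed) != 1 || is.na(f_observed) || f_observed <= 0)
    stop_domain("f_observed must be a single positive frequency")
  fr <- per_nt_frequency(inputs)
  lo <- f_observed / fr[["high"]]
  hi <- f_observed / fr[["low"]]
  structure(list(expected_conversions = expected_conversions(inputs),
                 per_nt_frequency = fr,
                 tract_length = c(low = round_half_up(lo),
                                  high = round_half_up(hi)),
                 tract_length_mean = round_half_up((lo + hi) / 2),
                 f_observed = f_observed, inputs = inputs),
            class = "tract_estimate")
}

#' @export
print.tract_estimate <- function(x, ...) {
  cat("Tract-length reconciliation\n")
  cat(sprintf("  observed per-locus frequency: %s\n",
              format_sci3(x$f_observed)))
  cat(sprintf("  expected conversions per meiosis: %d-%d\n",
              x$expected_conversions[["low"]],
              x$expected_conversions[["high"]]))
  cat(sprintf("  expected per-nt frequency: %s-%s\n",
              format_sci3(x$per_nt_frequency[["low"]]),
              format_sci3(x$per_nt_frequency[["high"]])))
  cat(sprintf("  implied tract length: %d-%d bp (average %d bp)\n",
              x$tract_length[["low"]], x$tract_length[["high"]],
              x$tract_length_mean))
  invisible(x)
}

#' Expected crossover:non-crossover balance
#'
#' With a fixed number of crossovers per meiosis, the remaining DSBs
#' should resolve as non-crossovers, so the expected balance is
#' `1 : (DSBs - COs) / COs`. Under the defaults the denominators are
#' 12.3-23.7, i.e. roughly 1:12 at the low end -- in stark contrast to
#' the observed 11 CO-associated conversions per NCO-associated one.
#' (Note the arithmetic upper denominator is 213/9 = 23.7; a commonly
#' quoted 1:20 upper bound understates it.)
#'
#' @inheritParams expected_conversions
#' @return Numeric vector `c(low, high)` of NCO-per-CO denominators.
#' @export
expected_co_nco_ratio <- function(inputs = tract_model_inputs()) {
  if (inputs$co_per_meiosis <= 0)
    stop_domain("co_per_meiosis must be positive")
  if (inputs$dsb_min <= inputs$co_per_meiosis)
    stop_domain("dsb_min must exceed co_per_meiosis")
  nco <- c(inputs$dsb_min, inputs$dsb_max) - inputs$co_per_meiosis
  stats::setNames(nco / inputs$co_per_meiosis, c("low", "high"))
}
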