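#' Marker layout for three-color tetrad classification
#'
#' Describes which phenotype channel carries the heterozygous
#' fluorescent/non-fluorescent test locus and which channels carry the
#' hemizygous flanking transgenes. The flanking markers must be in
#' coupling with the fluorescent test allele (present on the same
#' homolog), the configuration used for the DsRed - eYFP - AmCyan
#' interval on chromosome 5. Set both flanks to `NA` for a two-color
#' assay without crossover information.
#'
#' @param test channel of the test locus (default `"yellow"`).
#' @param flank_left,flank_right channels of the flanking hemizygous
#'   markers (default `"red"` and `"cyan"`), or `NA`.
#' @return A list of class `"marker_layout"`.
#' @export
marker_layout <- function(test = "yellow", flank_left = "red",
                          flank_right = "cyan") {
  chans <- c(test, flank_left, flank_right)
  chans <- chans[!is.na(chans)]
  if (anyDuplicated(chans))
    stop_domain("marker layout channels must be distinct")
  structure(list(test = test, flank_left = flank_left,
                 flank_right = flank_right,
                 has_flanks = !is.na(flank_left) && !is.na(flank_right)),
            class = "marker_layout")
}

#' Conversion classes
#'
#' The classes assigned by [classify_tetrad()]:
#' `NO_GC` (test channel 2:2), `GC_31` (3:1 without flanking
#' information), `GC_13` (1:3, reported but never counted as a
#' conversion), `CO_GC` / `NCO_GC` (3:1 with recombinant / parental
#' flanking markers), `AMBIGUOUS` (unscorable signal prevents a call),
#' `ABERRANT` (segregation incompatible with a single conversion event,
#' e.g. 4:0 test channel, non-2:2 flanking markers, or a double-crossover
#' flanking pattern, which is flagged rather than guessed).
#'
#' @return Character vector of the class labels in canonical order.
#' @export
conversion_classes <- function() {
  c("NO_GC", "GC_31", "GC_13", "CO_GC", "NCO_GC", "AMBIGUOUS", "ABERRANT")
}

#' Classify one tetrad as CO- or NCO-associated conversion
#'
#' Applies the flanking-marker logic of the three-color assay to one
#' tetrad. A conversion tetrad (3:1 at the test channel) is associated
#' with a crossover when the flanking hemizygous markers experienced
#' exchange -- the tetrad contains one red-only and one cyan-only grain
#' -- and with a non-crossover when every grain shows a parental
#' flanking pair (both flanks present or both absent). Unscorable
#' flanking signal on a test-positive grain makes the tetrad
#' `AMBIGUOUS`.
#'
#' @param tetrad a 4-row phenotype data.frame for a single tetrad (see
#'   [read_tetrad_phenotypes()]).
#' @param layout a [marker_layout()].
#' @return A single class label (see [conversion_classes()]).
#' @export
#' @examples
#' t1 <- data.frame(tetrad_id = "t", grain = 1:4,
#'                  red    = c(1, 0, 1, 0),
#'                  yellow = c(1, 1, 1, 0),
#'                  cyan   = c(1, 1, 0, 0))
#' classify_tetrad(t1)  # "CO_GC"
classify_tetrad <- function(tetrad, layout = marker_layout()) {
  if (nrow(tetrad) != 4)
    stop_domain("a tetrad must have exactly 4 grains")
  y <- tetrad[[layout$test]]
  if (is.null(y)) stop_domain("test channel '", layout$test, "' not found")
  if (any(is.na(y))) return("AMBIGUOUS")
  ny <- sum(y == 1)
  if (ny == 2) return("NO_GC")
  if (ny == 1) return("GC_13")
  if (ny %in% c(0, 4)) return("ABERRANT")

  # test channel 3:1
  if (!layout$has_flanks) return("GC_31")
  red <- tetrad[[layout$flank_left]]
  cyan <- tetrad[[layout$flank_right]]
  ypos <- y == 1
  if (any(is.na(red[ypos])) || any(is.na(cyan[ypos]))) return("AMBIGUOUS")
  # hemizygous flanks must themselves segregate 2:2
  ok22 <- function(v) sum(v == 1, na.rm = TRUE) <= 2 &&
    sum(v == 0, na.rm = TRUE) <= 2
  if (!ok22(red) || !ok22(cyan)) return("ABERRANT")

  det <- !is.na(red) & !is.na(cyan)
  parental <- red == cyan
  if (all(parental[det])) {
    if (all(det)) return("NCO_GC")
    return("AMBIGUOUS")  # an undetermined grain could hide a recombinant
  }
  red_only <- det & red == 1 & cyan == 0
  cyan_only <- det & red == 0 & cyan == 1
  if (sum(red_only) == 1 && sum(cyan_only) == 1) return("CO_GC")
  "ABERRANT"  # more than one recombinant pair: double-CO-like pattern
}

#' Classify all tetrads in a phenotype table
#'
#' @param phenotypes a long tetrad-phenotype data.frame.
#' @inheritParams classify_tetrad
#' @return A data.frame with `tetrad_id` and `class`, in first-appearance
#'   order of the tetrads.
#' @export
classify_tetrads <- function(phenotypes, layout = marker_layout()) {
  phenotypes <- validate_phenotypes(phenotypes)
  ids <- unique(phenotypes$tetrad_id)
  pieces <- split(phenotypes, factor(phenotypes$tetrad_id, levels = ids))
  data.frame(
    tetrad_id = ids,
    class = vapply(pieces, classify_tetrad, character(1), layout = layout),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize conversion classes
#'
#' Counts tetrads per conversion class and reports the CO:NCO ratio
#' among classified conversions. At the three-color `1659-GC1` interval,
#' 13 conversions split into 11 CO-associated, 1 NCO-associated and 1
#' ambiguous.
#'
#' @param phenotypes a long tetrad-phenotype data.frame, or the output
#'   of [classify_tetrads()].
#' @inheritParams classify_tetrad
#' @return A named integer vector over [conversion_classes()] with
#'   attributes `co_nco_ratio` (CO count / NCO count; `NA` when no NCO)
#'   and `n_tetrads`.
#' @export
#' @examples
#' summarize_classes(conversion_tetrads())
summarize_classes <- function(phenotypes, layout = marker_layout()) {
  cls <- if (is.data.frame(phenotypes) && "class" %in% names(phenotypes) &&
             !"grain" %in% names(phenotypes)) {
    phenotypes$class
  } else {
    classify_tetrads(phenotypes, layout)$class
  }
  counts <- table(factor(cls, levels = conversion_classes()))
  out <- stats::setNames(as.integer(counts), names(counts))
  ratio <- if (out[["NCO_GC"]] > 0) out[["CO_GC"]] / out[["NCO_GC"]] else
    NA_real_
  attr(out, "co_nco_ratio") <- ratio
  attr(out, "n_tetrads") <- length(cls)
  out
}
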