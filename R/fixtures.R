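#' Non-fluorescent tagged line (NFTL) allele records
#'
#' The 17 EMS-derived non-fluorescent alleles of single-copy FTL
#' transgenes used as gene-conversion test loci. Fifteen alleles were
#' sequenced; two (`567-GC2`, `567-GC3`) were neither sequenced nor used
#' further and carry `NA` mutation fields. The SNP position is the
#' 1-based nucleotide within the fluorophore coding sequence, parsed from
#' the mutation code (`G95A` -> 95). All sequenced mutations are
#' G->A or C->T transitions, the canonical EMS signature.
#'
#' @param sequenced_only if `TRUE`, drop the two unsequenced alleles.
#' @return A data.frame with columns `allele_name`, `chromosome`,
#'   `transgene_position` (1-based genomic nucleotide of the transgene
#'   insertion, shared by alleles of the same locus), `fluorophore`
#'   (`yfp`, `dsred` or `amcyan`), `mutation`, `snp_position`,
#'   `ref_base`, `alt_base`, `aa_change`.
#' @seealso [gc_counts()] for the scored tetrad counts.
#' @export
#' @examples
#' a <- nftl_alleles()
#' a[a$allele_name == "1659-GC1", "snp_position"]  # 383
nftl_alleles <- function(sequenced_only = FALSE) {
  df <- data.frame(
    allele_name = c("567-GC1", "567-GC2", "567-GC3",
                    "3282-GC1", "3282-GC2", "3282-GC3", "3282-GC4",
                    "3411-GC1", "1369-GC1", "1369-GC2",
                    "424-GC1", "424-GC2", "424-GC3", "424-GC4",
                    "1273-GC1", "1273-GC2", "1659-GC1"),
    chromosome = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 3L, 3L,
                   4L, 4L, 4L, 4L, 5L, 5L, 5L),
    transgene_position = c(rep(3905441L, 3), rep(25652977L, 4),
                           18957093L, 6472617L, 6472617L,
                           rep(1365848L, 4), 18164269L, 18164269L,
                           23080567L),
    fluorophore = c(rep("yfp", 3), rep("amcyan", 4), "yfp",
                    "dsred", "dsred", rep("yfp", 4),
                    "dsred", "dsred", "yfp"),
    mutation = c("G95A", NA, NA, "G118A", "C224T", "G383A", "G118A",
                 "G203A", "G308A", "G428A",
                 "G174A", "C188T", "C617T", "C332T",
                 "G92A", "C223T", "G383A"),
    aa_change = c("G32D", NA, NA, "G40R", "T75I", "G128E", "G40R",
                  "G68D", "G103D", "W143X",
                  "W58X", "T63I", "S206F", "A11V",
                  "G31D", "H75Y", "G128D"),
    stringsAsFactors = FALSE
  )
  parsed <- parse_mutation(df$mutation)
  df$snp_position <- parsed$position
  df$ref_base <- parsed$ref
  df$alt_base <- parsed$alt
  df <- df[c("allele_name", "chromosome", "transgene_position",
             "fluorophore", "mutation", "snp_position",
             "ref_base", "alt_base", "aa_change")]
  if (sequenced_only) df <- df[!is.na(df$mutation), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# "G95A" -> list(ref = "G", position = 95, alt = "A")
parse_mutation <- function(code) {
  ok <- !is.na(code) & grepl("^[ACGT][0-9]+[ACGT]$", code)
  if (any(!ok & !is.na(code)))
    stop_domain("malformed mutation code: ",
                paste(code[!ok & !is.na(code)], collapse = ", "))
  list(
    ref = ifelse(ok, substr(code, 1, 1), NA_character_),
    position = ifelse(ok, as.integer(sub("^[ACGT]([0-9]+)[ACGT]$", "\\1", code)),
                      NA_integer_),
    alt = ifelse(ok, substring(code, nchar(code)), NA_character_)
  )
}

#' Scored gene-conversion tetrad counts
#'
#' The genome-wide tetrad screen: for each test locus, the number of
#' tetrads scored and the number showing a 3:1
#' fluorescent:non-fluorescent segregation (a conversion toward the
#' fluorescent allele). The seven genome-wide loci total 186 conversions
#' in 1,054,024 tetrads. `1369-GC2` is a second allele of the `1369`
#' locus (SNPs 120 bp apart) scored for the intra-locus comparison and is
#' excluded from the genome-wide pool.
#'
#' 1:3, 4:0 and 0:4 classes were not tallied in the published counts and
#' are recorded as 0; 1:3 tetrads are never added to conversion counts
#' (the doubling adjustment in [estimate_frequency()] accounts for them).
#'
#' @param include_intra include the `1369-GC2` intra-locus allele
#'   (default `FALSE`, i.e. the seven-locus genome-wide set).
#' @return A counts data.frame with columns `label`, `chromosome`,
#'   `n_31`, `n_tetrads`, `n_13`, `n_40`, `n_04`.
#' @seealso [estimate_frequency()], [pairwise_g_matrix()]
#' @export
#' @examples
#' sum(gc_counts()$n_31)       # 186
#' sum(gc_counts()$n_tetrads)  # 1054024
gc_counts <- function(include_intra = FALSE) {
  df <- data.frame(
    label = c("567-GC1", "3282-GC1", "3411-GC1", "1369-GC1",
              "1369-GC2", "424-GC1", "1273-GC1", "1659-GC1"),
    chromosome = c(1L, 1L, 2L, 3L, 3L, 4L, 5L, 5L),
    n_31 = c(17L, 17L, 30L, 16L, 16L, 79L, 14L, 13L),
    n_tetrads = c(148886L, 150910L, 150706L, 155280L,
                  150916L, 147848L, 150429L, 149965L),
    n_13 = 0L, n_40 = 0L, n_04 = 0L,
    stringsAsFactors = FALSE
  )
  if (!include_intra) df <- df[df$label != "1369-GC2", , drop = FALSE]
  rownames(df) <- NULL
  validate_counts(df)
}

#' Experimental control counts
#'
#' The two false-positive controls: a plant homozygous for the
#' non-fluorescent `3282-GC1` allele (reversion control) and a plant
#' hemizygous for the `567` FTL (tetrad misgrouping control). Each was
#' scored over 45,000 tetrads with zero 3:1 events.
#'
#' @return A counts data.frame with one row per control.
#' @seealso [control_comparison()]
#' @export
control_counts <- function() {
  validate_counts(data.frame(
    label = c("reversion-control", "misgrouping-control"),
    chromosome = c(1L, 1L),
    n_31 = c(0L, 0L),
    n_tetrads = c(45000L, 45000L),
    n_13 = 0L, n_40 = 0L, n_04 = 0L,
    stringsAsFactors = FALSE
  ))
}

#' Three-color conversion tetrads (synthetic reconstruction)
#'
#' The 13 conversion tetrads observed at the `1659-GC1` test locus in the
#' three-color (DsRed - eYFP - AmCyan) interval: 11 crossover-associated,
#' 1 non-crossover-associated, and 1 with an AmCyan signal too weak to
#' score. The original microscopy images are not available, so the
#' packaged file is a synthetic reconstruction of the reported phenotype
#' patterns (grain orders randomized), suitable for exercising the
#' classifier but not a primary data deposit.
#'
#' @return A long tetrad-phenotype data.frame (see
#'   [read_tetrad_phenotypes()]).
#' @seealso [classify_tetrads()], [summarize_classes()]
#' @export
conversion_tetrads <- function() {
  path <- system.file("extdata", "synthetic_three_color_tetrads.tsv",
                      package = "tetradgc", mustWork = TRUE)
  read_tetrad_phenotypes(path)
}

# Published point estimates used by reproduce_study() to diff its own
# recomputation against the original report of these data.
published_values <- function() {
  list(
    adjusted_frequency = c("567-GC1" = 2.28e-4, "3282-GC1" = 2.25e-4,
                           "3411-GC1" = 3.98e-4, "1369-GC1" = 2.06e-4,
                           "424-GC1" = 1.07e-3, "1273-GC1" = 1.86e-4,
                           "1659-GC1" = 1.73e-4, total = 3.53e-4),
    meioses_per_conversion = c("567-GC1" = 4379, "3282-GC1" = 4439,
                               "3411-GC1" = 2512, "1369-GC1" = 4853,
                               "424-GC1" = 936, "1273-GC1" = 5372,
                               "1659-GC1" = 5768, total = 2833),
    r_squared = 0.038, regression_p = 0.645,
    expected_conversions = c(60, 111),
    per_nt_frequency = c(4.25e-7, 9.32e-7),
    tract_length = c(379, 830), tract_length_mean = 605,
    co_count = 11, nco_count = 1, ambiguous_count = 1,
    control_p = 0.008998,
    pairwise_printed = pairwise_printed_values()
  )
}

# The printed pairwise P-value matrix (locus-vs-locus cells only), in
# publication row order, as formatted strings at printed precision.
pairwise_printed_values <- function() {
  labs <- c("567-GC1", "3282-GC1", "3411-GC1", "1369-GC1",
            "1369-GC2", "424-GC1", "1273-GC1", "1659-GC1")
  m <- matrix(NA_character_, 8, 8, dimnames = list(labs, labs))
  m["567-GC1", c("3282-GC1", "3411-GC1", "1369-GC1", "1369-GC2",
                 "424-GC1", "1273-GC1", "1659-GC1")] <-
    c("0.97", "0.06", "0.77", "0.83", "3E-11", "0.57", "0.45")
  m["3282-GC1", c("3411-GC1", "1369-GC1", "1369-GC2",
                  "424-GC1", "1273-GC1", "1659-GC1")] <-
    c("0.06", "0.80", "0.86", "2E-11", "0.60", "0.48")
  m["3411-GC1", c("1369-GC1", "1369-GC2", "424-GC1",
                  "1273-GC1", "1659-GC1")] <-
    c("0.03", "0.04", "1E-6", "0.02", "0.01")
  m["1369-GC1", c("1369-GC2", "424-GC1", "1273-GC1", "1659-GC1")] <-
    c("0.94", "3E-12", "0.78", "0.64")
  m["1369-GC2", c("424-GC1", "1273-GC1", "1659-GC1")] <-
    c("8E-12", "0.72", "0.59")
  m["424-GC1", c("1273-GC1", "1659-GC1")] <- c("8E-13", "3E-13")
  m["1273-GC1", "1659-GC1"] <- "0.85"
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}
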