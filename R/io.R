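#' Construct a tetrad-counts record
#'
#' @param label locus/condition label.
#' @param n_tetrads total tetrads scored.
#' @param n_31 tetrads with 3:1 fluorescent:non-fluorescent segregation.
#' @param n_13,n_40,n_04 optional counts for the remaining non-2:2
#'   classes; stored but never added to conversion counts.
#' @param chromosome optional chromosome (1-5).
#' @return A one-row validated counts data.frame.
#' @export
#' @examples
#' tetrad_counts("424-GC1", 147848, 79, chromosome = 4)
tetrad_counts <- function(label, n_tetrads, n_31,
                          n_13 = 0L, n_40 = 0L, n_04 = 0L,
                          chromosome = NA_integer_) {
  validate_counts(data.frame(
    label = as.character(label),
    chromosome = as.integer(chromosome),
    n_31 = as.integer(n_31), n_tetrads = as.integer(n_tetrads),
    n_13 = as.integer(n_13), n_40 = as.integer(n_40),
    n_04 = as.integer(n_04),
    stringsAsFactors = FALSE
  ))
}

validate_counts <- function(df) {
  for (col in c("n_13", "n_40", "n_04"))
    if (is.null(df[[col]])) df[[col]] <- 0L
  if (is.null(df$chromosome)) df$chromosome <- NA_integer_
  df[c("n_13", "n_40", "n_04")][is.na(df[c("n_13", "n_40", "n_04")])] <- 0L
  num <- c("n_31", "n_tetrads", "n_13", "n_40", "n_04")
  for (col in num) {
    if (any(is.na(df[[col]])))
      stop_domain("malformed or missing numeric value in column '", col, "'")
    if (any(df[[col]] < 0))
      stop_domain("negative count in column '", col, "'")
  }
  over <- with(df, n_31 + n_13 + n_40 + n_04 > n_tetrads)
  if (any(over))
    stop_domain("class counts exceed total tetrads for: ",
                paste(df$label[over], collapse = ", "))
  chr <- df$chromosome[!is.na(df$chromosome)]
  if (length(chr) && !all(chr %in% 1:5))
    stop_domain("chromosome must be in 1..5")
  df[c("label", "chromosome", num)]
}

#' Read / write a tetrad counts table
#'
#' Tab-separated, UTF-8, "." decimal mark. Required columns: `label`,
#' `n_31`, `n_tetrads`; optional: `chromosome`, `n_13`, `n_40`, `n_04`
#' (empty cells read as 0).
#'
#' @param path file path.
#' @return `read_counts_table()`: a validated counts data.frame;
#'   `write_counts_table()`: `path`, invisibly. The two functions are
#'   inverse on valid tables.
#' @export
read_counts_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  req <- c("label", "n_31", "n_tetrads")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop_domain("counts table is missing required column(s): ",
                paste(missing_cols, collapse = ", "))
  for (col in c("n_31", "n_tetrads", "n_13", "n_40", "n_04", "chromosome")) {
    if (is.null(df[[col]])) next
    raw <- trimws(df[[col]])
    raw[raw == ""] <- NA
    val <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & (is.na(val) | val != floor(val))
    if (any(bad))
      stop_domain("malformed numeric value(s) in column '", col, "': ",
                  paste(unique(raw[bad]), collapse = ", "))
    df[[col]] <- as.integer(val)
  }
  validate_counts(df)
}

#' @param counts a counts data.frame as returned by [read_counts_table()]
#'   or [gc_counts()].
#' @rdname read_counts_table
#' @export
write_counts_table <- function(counts, path) {
  counts <- validate_counts(counts)
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write tetrad phenotype tables
#'
#' Long-format TSV with columns `tetrad_id`, `grain` (1-4), and one
#' column per fluorescence channel (`red`, `yellow`, `cyan`) with values
#' `0` (absent), `1` (present) or `NA` (unscorable signal -- distinct
#' from absent; e.g. fluorescence too weak to call). Every `tetrad_id`
#' must have exactly 4 grains.
#'
#' @param path file path.
#' @return `read_tetrad_phenotypes()`: a data.frame with integer channel
#'   columns (`NA` = unscorable); `write_tetrad_phenotypes()`: `path`,
#'   invisibly.
#' @export
read_tetrad_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  req <- c("tetrad_id", "grain", "red", "yellow", "cyan")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop_domain("tetrad table is missing required column(s): ",
                paste(missing_cols, collapse = ", "))
  for (col in c("red", "yellow", "cyan")) {
    raw <- trimws(df[[col]])
    raw[is.na(raw)] <- "NA"
    bad <- !raw %in% c("0", "1", "NA", "")
    if (any(bad))
      stop_domain("unknown channel token(s) in column '", col, "': ",
                  paste(unique(raw[bad]), collapse = ", "))
    raw[raw %in% c("NA", "")] <- NA
    df[[col]] <- as.integer(raw)
  }
  df$grain <- as.integer(df$grain)
  validate_phenotypes(df[req])
}

validate_phenotypes <- function(df) {
  sizes <- table(df$tetrad_id)
  bad <- names(sizes)[sizes != 4L]
  if (length(bad))
    stop_domain("tetrad(s) without exactly 4 grains: ",
                paste(bad, collapse = ", "))
  if (any(is.na(df$grain)) || any(!df$grain %in% 1:4))
    stop_domain("grain index must be 1..4")
  df
}

#' @param phenotypes a tetrad phenotype data.frame.
#' @rdname read_tetrad_phenotypes
#' @export
write_tetrad_phenotypes <- function(phenotypes, path) {
  validate_phenotypes(phenotypes)
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
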