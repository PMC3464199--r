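# internal helpers

# Half-up rounding: the published tables round .5 away from zero
# (155280/32 = 4852.5 is printed 4853), unlike base round().
round_half_up <- function(x) floor(x + 0.5)

# "1.07E-03"-style scientific notation at 3 significant figures.
format_sci3 <- function(x) {
  out <- toupper(sprintf("%.2E", x))
  out[is.na(x)] <- NA_character_
  out
}

# P-values at the printed precision of the pairwise tables: two decimals
# half-up for p >= 0.001, one-significant-figure E-notation below, and a
# floor marker below 1e-15.
format_p_printed <- function(p) {
  fmt1 <- function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 1e-15) return("<1E-15")
    if (x >= 0.001) return(sprintf("%.2f", round_half_up(x * 100) / 100))
    e <- floor(log10(x))
    m <- round_half_up(x / 10^e)
    if (m == 10) { m <- 1; e <- e + 1 }
    sprintf("%dE-%d", m, -e)
  }
  vapply(p, fmt1, character(1))
}

# Agreement with a value printed at unknown rounding convention: within
# one unit in the last printed digit ("0.02" -> +/-0.01, "3E-11" -> +/-1e-11).
printed_p_match <- function(printed, value) {
  target <- as.numeric(sub("^<", "", printed))
  ulp <- if (grepl("E", printed)) {
    10^floor(log10(target))
  } else {
    dec <- nchar(sub("^[^.]*\\.?", "", printed))
    10^(-dec)
  }
  abs(value - target) <= ulp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
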