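#' Parameters for the forward meiosis simulator
#'
#' The generative model behind the tetrad assay: a heterozygous
#' FTL/NFTL meiocyte enters meiosis with four chromatids (two carrying
#' the fluorescent test allele, two the non-fluorescent allele; any
#' hemizygous flanking transgenes ride on the fluorescent homolog). Each
#' meiosis draws a number of SPO11-induced DSBs, each at a uniform
#' genomic position on a uniform chromatid. A DSB is repaired off a
#' non-sister chromatid with probability `p_homolog` (sister repair is
#' phenotypically silent), resolves as a crossover (DSBR) with
#' probability `p_co` and otherwise as a non-crossover (SDSA), and lays
#' down a heteroduplex tract containing the break with uniform offset,
#' so the probability that the tract covers any given nucleotide is
#' exactly `tract_mean / genome_length`. When the tract covers the test
#' locus and the two chromatids carry different alleles, mismatch repair
#' converts (copies the template allele onto the broken chromatid) with
#' probability `p_conversion` and restores otherwise. A crossover
#' exchanges all sequence distal to the break between the two
#' participating chromatids, which is what moves hemizygous flanking
#' markers between homologs.
#'
#' Defaults are the baseline study conditions: the sequenced Arabidopsis
#' genome (119,146,348 nt), Poisson DSBs with mean 171 (midpoint of the
#' 120-222 RAD51-focus range), geometric tracts with mean 605 bp (the
#' reconciliation estimate), 50:50 conversion:restoration by MMR,
#' `p_co = 9/171` (about 9 crossovers per meiosis when every DSB engages
#' the homolog), a 1e-7 per-grain reversion rate (upper end of measured
#' mitotic rates at transgene loci) and no tetrad misgrouping (the
#' misgrouping control observed none in 45,000 tetrads).
#'
#' @param genome_length simulated genome (chromosome) length in nt.
#' @param dsb_mean expected (`dsb_law = "poisson"`) or fixed
#'   (`dsb_law = "fixed"`) number of DSBs per meiosis.
#' @param dsb_law DSB count law.
#' @param test_locus 1-based position of the heterozygous test SNP.
#' @param flank_left,flank_right positions of hemizygous flanking
#'   markers in coupling with the fluorescent allele, or `NA` for a
#'   two-color assay.
#' @param tract_mean mean heteroduplex tract length in bp.
#' @param tract_law tract-length law: `"geometric"` (on 1, 2, ...),
#'   `"fixed"`, or `"gamma"` (rounded, floored at 1 bp).
#' @param tract_shape shape parameter for the gamma law.
#' @param p_homolog probability a DSB is repaired off the homolog
#'   rather than the sister chromatid.
#' @param p_co probability a homolog-repaired DSB resolves as a
#'   crossover.
#' @param p_conversion probability MMR converts rather than restores a
#'   covered mismatch (1 - restoration fraction).
#' @param reversion_rate per-grain probability that a non-fluorescent
#'   test allele scores fluorescent.
#' @param misgrouping_rate per-tetrad probability of replacement by four
#'   meiotically unrelated grains.
#' @param label label used for emitted count records.
#' @param seed default seed for [simulate_experiment()].
#' @return A validated list of class `"simulation_params"`.
#' @export
simulation_params <- function(genome_length = 119146348,
                              dsb_mean = 171,
                              dsb_law = c("poisson", "fixed"),
                              test_locus = round_half_up(genome_length / 2),
                              flank_left = NA, flank_right = NA,
                              tract_mean = 605,
                              tract_law = c("geometric", "fixed", "gamma"),
                              tract_shape = 2,
                              p_homolog = 1, p_co = 9 / 171,
                              p_conversion = 0.5,
                              reversion_rate = 1e-7,
                              misgrouping_rate = 0,
                              label = "sim", seed = NULL) {
  dsb_law <- match.arg(dsb_law)
  tract_law <- match.arg(tract_law)
  probs <- c(p_homolog = p_homolog, p_co = p_co,
             p_conversion = p_conversion, reversion_rate = reversion_rate,
             misgrouping_rate = misgrouping_rate)
  if (any(probs < 0 | probs > 1))
    stop_domain("probabilities must be in [0, 1]: ",
                paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (genome_length < tract_mean || tract_mean < 1)
    stop_domain("need genome_length >= tract_mean >= 1")
  if (test_locus < 1 || test_locus > genome_length)
    stop_domain("test_locus must lie within the genome")
  if (dsb_mean < 0) stop_domain("dsb_mean must be non-negative")
  if (is.na(flank_left) != is.na(flank_right))
    stop_domain("set both flanking markers or neither")
  if (!is.na(flank_left) &&
      !(flank_left < test_locus && test_locus < flank_right))
    stop_domain("need flank_left < test_locus < flank_right")
  structure(list(genome_length = genome_length, dsb_mean = dsb_mean,
                 dsb_law = dsb_law, test_locus = test_locus,
                 flank_left = flank_left, flank_right = flank_right,
                 tract_mean = tract_mean, tract_law = tract_law,
                 tract_shape = tract_shape, p_homolog = p_homolog,
                 p_co = p_co, p_conversion = p_conversion,
                 reversion_rate = reversion_rate,
                 misgrouping_rate = misgrouping_rate,
                 label = label, seed = seed),
            class = "simulation_params")
}

#' First-order expected segregation rates under the simulator's model
#'
#' A DSB produces a scorable conversion at the test locus when it is
#' repaired off the homolog, its tract covers the SNP (probability
#' `tract_mean / genome_length` by construction), and MMR converts. The
#' broken chromatid carries the non-fluorescent allele half the time, so
#' 3:1 and 1:3 tetrads each arise at half the total rate:
#' `p_31 = dsb_mean * p_homolog * (tract_mean / genome_length) *
#' p_conversion / 2`. Exact to first order in the per-meiosis event
#' rate (multi-conversion tetrads are quadratically rare).
#'
#' @param params a [simulation_params()].
#' @return List with `p_31`, `p_13`, and `adjusted_frequency` (the
#'   expectation of the doubled 3:1 estimator, `2 * p_31`).
#' @export
expected_segregation_rates <- function(params) {
  rate <- params$dsb_mean * params$p_homolog *
    (params$tract_mean / params$genome_length) * params$p_conversion
  list(p_31 = rate / 2, p_13 = rate / 2, adjusted_frequency = rate)
}

#' Simulate a scored tetrad experiment
#'
#' Forward-simulates `n_tetrads` meioses under the DSBR/SDSA model of
#' [simulation_params()] and scores the resulting pollen tetrads the way
#' the microscope assay would: per-tetrad fluorescent:non-fluorescent
#' segregation classes at the test channel, optional per-grain
#' three-channel phenotypes, and a ground-truth event log.
#'
#' The implementation draws all DSBs vectorized, then replays -- in draw
#' order -- only the events that can change the tracked loci (homolog
#' repair with a tract covering the test SNP, or a crossover proximal to
#' a tracked marker); all other events are phenotypically silent.
#' Reversion noise flips non-fluorescent grains at the test channel;
#' misgrouped tetrads are replaced by four grains drawn independently
#' from the population marginals (each channel present with probability
#' 1/2).
#'
#' @param params a [simulation_params()].
#' @param n_tetrads number of meioses to simulate.
#' @param seed RNG seed (defaults to `params$seed`); identical
#'   seed + parameters give identical output.
#' @param keep_phenotypes emit the per-grain phenotype table (default:
#'   only for runs up to 50,000 tetrads; counts are always emitted).
#' @param events `"relevant"` (default; ground truth for every event
#'   that could affect tracked loci), `"all"` (every DSB -- large), or
#'   `"none"`.
#' @return A list of class `"gc_simulation"`: `counts` (one-row counts
#'   data.frame), `phenotypes` (long data.frame or `NULL`), `events`
#'   (data.frame or `NULL`), `params`, `seed`, `n_tetrads`.
#' @export
#' @examples
#' p <- simulation_params(genome_length = 1e6, dsb_mean = 2,
#'                        dsb_law = "fixed", tract_mean = 5000,
#'                        tract_law = "fixed", reversion_rate = 0)
#' sim <- simulate_experiment(p, 20000, seed = 1)
#' sim$counts
simulate_experiment <- function(params, n_tetrads,
                                seed = params$seed,
                                keep_phenotypes = NULL,
                                events = c("relevant", "all", "none")) {
  stopifnot(inherits(params, "simulation_params"))
  events <- match.arg(events)
  n <- as.integer(n_tetrads)
  if (is.na(n) || n < 1) stop_domain("n_tetrads must be >= 1")
  if (is.null(keep_phenotypes)) keep_phenotypes <- n <= 50000
  if (!is.null(seed)) set.seed(seed)

  G <- params$genome_length
  tl <- params$test_locus
  has_flanks <- !is.na(params$flank_left)
  loci <- if (has_flanks) c(params$flank_left, tl, params$flank_right) else tl
  it <- if (has_flanks) 2L else 1L
  nl <- length(loci)
  base_state <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, nl)

  ndsb <- if (params$dsb_law == "poisson") stats::rpois(n, params$dsb_mean)
          else rep.int(as.integer(round(params$dsb_mean)), n)
  M <- sum(ndsb)

  yc <- rep.int(2L, n)            # fluorescent grains per tetrad
  fl <- fr <- if (has_flanks) rep.int(2L, n) else NULL
  states <- list()
  ev <- NULL

  if (M > 0) {
    tet <- rep.int(seq_len(n), ndsb)
    pos <- sample.int(G, M, replace = TRUE)
    broken <- sample.int(4L, M, replace = TRUE)
    homolog <- stats::runif(M) < params$p_homolog
    templ <- (broken <= 2L) * 2L + sample.int(2L, M, replace = TRUE)
    co <- stats::runif(M) < params$p_co
    len <- switch(params$tract_law,
      fixed = rep.int(as.integer(round(params$tract_mean)), M),
      geometric = 1L + stats::rgeom(M, 1 / params$tract_mean),
      gamma = pmax(1, round_half_up(
        stats::rgamma(M, shape = params$tract_shape,
                      rate = params$tract_shape / params$tract_mean))))
    off <- floor(stats::runif(M) * len)
    tr_start <- pos - off
    tr_end <- tr_start + len - 1
    covers <- tr_start <= tl & tl <= tr_end
    relevant <- homolog & (covers | (co & pos < max(loci)))
    ridx <- which(relevant)

    mmr <- rep.int("no_mismatch", length(ridx))
    if (length(ridx)) {
      rtet <- tet[ridx]
      groups <- split(seq_along(ridx), rtet)
      states <- vector("list", length(groups))
      names(states) <- names(groups)
      rb <- broken[ridx]; rm_ <- templ[ridx]; rco <- co[ridx]
      rcov <- covers[ridx]; rpos <- pos[ridx]
      for (k in seq_along(groups)) {
        st <- base_state
        # Phase 1 -- heteroduplex formation and mismatch repair. All DSBs
        # invade and form heteroduplex before any junction is resolved,
        # so mismatches are evaluated against the pre-resolution allele
        # configuration (changed only by earlier conversions).
        for (i in groups[[k]]) {
          b <- rb[i]; m <- rm_[i]
          if (rcov[i] && st[b, it] != st[m, it]) {
            if (stats::runif(1) < params$p_conversion) {
              st[b, it] <- st[m, it]
              mmr[i] <- "converted"
            } else mmr[i] <- "restored"
          }
        }
        # Phase 2 -- crossover resolution: exchange all sequence distal
        # to each CO break between the two participating chromatids.
        for (i in groups[[k]]) {
          if (rco[i]) {
            b <- rb[i]; m <- rm_[i]
            dl <- loci > rpos[i]
            if (any(dl)) {
              tmp <- st[b, dl]
              st[b, dl] <- st[m, dl]
              st[m, dl] <- tmp
            }
          }
        }
        states[[k]] <- st
      }
      utet <- as.integer(names(groups))
      yc[utet] <- vapply(states, function(s) sum(s[, it]), integer(1))
      if (has_flanks) {
        fl[utet] <- vapply(states, function(s) sum(s[, 1L]), integer(1))
        fr[utet] <- vapply(states, function(s) sum(s[, nl]), integer(1))
      }
    }

    if (events == "relevant" && length(ridx)) {
      ev <- data.frame(
        tetrad = tet[ridx], dsb_position = pos[ridx],
        broken_chromatid = broken[ridx] - 1L,
        template = "homolog",
        pathway = ifelse(co[ridx], "CO", "NCO"),
        tract_start = tr_start[ridx], tract_end = tr_end[ridx],
        covered_test_locus = covers[ridx], mmr_outcome = mmr,
        stringsAsFactors = FALSE)
    } else if (events == "all") {
      mmr_all <- rep.int("no_mismatch", M)
      mmr_all[ridx] <- mmr
      ev <- data.frame(
        tetrad = tet, dsb_position = pos,
        broken_chromatid = broken - 1L,
        template = ifelse(homolog, "homolog", "sister"),
        pathway = ifelse(co, "CO", "NCO"),
        tract_start = tr_start, tract_end = tr_end,
        covered_test_locus = covers, mmr_outcome = mmr_all,
        stringsAsFactors = FALSE)
    }
  } else if (events == "relevant" || events == "all") {
    ev <- data.frame(tetrad = integer(), dsb_position = integer(),
                     broken_chromatid = integer(), template = character(),
                     pathway = character(), tract_start = numeric(),
                     tract_end = numeric(), covered_test_locus = logical(),
                     mmr_outcome = character(), stringsAsFactors = FALSE)
  }

  phen <- NULL
  if (keep_phenotypes) {
    # random chromatid-to-grain assignment within each tetrad
    ord <- order(rep(seq_len(n), each = 4L), stats::runif(4L * n))
    cfg <- ((ord - 1L) %% 4L) + 1L          # chromatid in each grain slot
    Y <- cfg <= 2L
    R <- if (has_flanks) cfg <= 2L else rep(NA, 4L * n)
    C <- if (has_flanks) cfg <= 2L else rep(NA, 4L * n)
    for (nm in names(states)) {
      u <- as.integer(nm)
      slots <- (4L * (u - 1L) + 1L):(4L * u)
      st <- states[[nm]]
      Y[slots] <- st[cfg[slots], it]
      if (has_flanks) {
        R[slots] <- st[cfg[slots], 1L]
        C[slots] <- st[cfg[slots], nl]
      }
    }
    if (params$reversion_rate > 0) {
      rv <- !Y & stats::runif(4L * n) < params$reversion_rate
      Y[rv] <- TRUE
    }
    if (params$misgrouping_rate > 0) {
      mg <- stats::runif(n) < params$misgrouping_rate
      if (any(mg)) {
        slots <- which(rep(mg, each = 4L))
        Y[slots] <- stats::runif(length(slots)) < 0.5
        if (has_flanks) {
          R[slots] <- stats::runif(length(slots)) < 0.5
          C[slots] <- stats::runif(length(slots)) < 0.5
        }
      }
    }
    yc <- as.integer(rowSums(matrix(Y, n, 4L, byrow = TRUE)))
    phen <- data.frame(
      tetrad_id = sprintf("t%07d", rep(seq_len(n), each = 4L)),
      grain = rep(1:4, n),
      red = as.integer(R), yellow = as.integer(Y), cyan = as.integer(C),
      stringsAsFactors = FALSE)
  } else {
    if (params$reversion_rate > 0) {
      nf <- 4L - yc
      total_nf <- sum(nf)
      k <- stats::rbinom(1, total_nf, params$reversion_rate)
      if (k > 0) {
        sl <- sample.int(total_nf, k)
        tid <- findInterval(sl - 0.5, c(0, cumsum(nf)))
        yc <- yc + tabulate(tid, nbins = n)
      }
    }
    if (params$misgrouping_rate > 0) {
      mg <- which(stats::runif(n) < params$misgrouping_rate)
      if (length(mg)) yc[mg] <- stats::rbinom(length(mg), 4L, 0.5)
    }
  }

  counts <- tetrad_counts(params$label, n_tetrads = n,
                          n_31 = sum(yc == 3L), n_13 = sum(yc == 1L),
                          n_40 = sum(yc == 4L), n_04 = sum(yc == 0L))
  structure(list(counts = counts, phenotypes = phen, events = ev,
                 params = params, seed = seed, n_tetrads = n),
            class = "gc_simulation")
}

#' @export
print.gc_simulation <- function(x, ...) {
  cat(sprintf("Simulated tetrad experiment: %d tetrads (seed %s)\n",
              x$n_tetrads, format(x$seed %||% "unset")))
  print(x$counts)
  invisible(x)
}

#' Simulate a single tetrad with a full event log
#'
#' One meiosis under the forward model, returning the 4-grain phenotype
#' and the complete per-DSB event log (including phenotypically silent
#' sister-repair events).
#'
#' @inheritParams simulate_experiment
#' @return List with `phenotype` (4-row data.frame) and `events`.
#' @export
simulate_tetrad <- function(params, seed = params$seed) {
  sim <- simulate_experiment(params, 1L, seed = seed,
                             keep_phenotypes = TRUE, events = "all")
  list(phenotype = sim$phenotypes, events = sim$events)
}

#' Recover programmed parameters from a simulated experiment
#'
#' Closes the loop between the simulator and the estimators: runs
#' [estimate_frequency()] on the simulated counts, compares the
#' estimate with the closed-form expectation of
#' [expected_segregation_rates()], and inverts the observed frequency
#' through [tract_length()] (with the simulation's own genome size,
#' effective DSB count and restoration fraction) to recover the
#' programmed mean tract length.
#'
#' @param sim a `"gc_simulation"` object.
#' @param params ground-truth parameters (default: those stored in
#'   `sim`).
#' @return A list with `estimate`, `expected` (closed-form rates),
#'   `z_31` (standardized deviation of the observed 3:1 frequency),
#'   `adjusted_relative_error`, `tract_recovered`,
#'   `tract_relative_error`, and `insufficient_events` (`TRUE` when no
#'   3:1 tetrads were observed, in which case the recovery errors are
#'   `NA`).
#' @export
recover_parameters <- function(sim, params = sim$params) {
  stopifnot(inherits(sim, "gc_simulation"))
  est <- estimate_frequency(sim$counts)
  exp_rates <- expected_segregation_rates(params)
  N <- est$n_tetrads
  p31 <- exp_rates$p_31
  z31 <- if (p31 > 0)
    (est$n_31 / N - p31) / sqrt(p31 * (1 - p31) / N) else NA_real_
  if (est$n_31 == 0) {
    return(list(estimate = est, expected = exp_rates, z_31 = z31,
                adjusted_relative_error = NA_real_,
                tract_recovered = NA_real_,
                tract_relative_error = NA_real_,
                insufficient_events = TRUE))
  }
  eff_dsb <- params$dsb_mean * params$p_homolog
  inputs <- tract_model_inputs(
    genome_min = params$genome_length, genome_max = params$genome_length,
    dsb_min = eff_dsb, dsb_max = eff_dsb,
    restoration_fraction = 1 - params$p_conversion)
  tr <- tract_length(est$adjusted_frequency, inputs)
  list(estimate = est, expected = exp_rates, z_31 = z31,
       adjusted_relative_error =
         est$adjusted_frequency / exp_rates$adjusted_frequency - 1,
       tract_recovered = tr$tract_length_mean,
       tract_relative_error = tr$tract_length_mean / params$tract_mean - 1,
       insufficient_events = FALSE)
}
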