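small_params <- function(...) {
  args <- utils::modifyList(
    list(genome_length = 1e6, dsb_mean = 2, dsb_law = "fixed",
         tract_mean = 5000, tract_law = "fixed", p_homolog = 1,
         p_co = 0.5, p_conversion = 0.5, reversion_rate = 0),
    list(...))
  do.call(simulation_params, args)
}

test_that("tract placement covers a point with probability L/G (enumeration)", {
  # brute-force enumeration over every (position, offset) pair on a tiny
  # genome: tract = [pos - off, pos - off + L - 1]
  G <- 100; L <- 10; t <- 50
  hits <- 0
  for (pos in 1:G) for (off in 0:(L - 1)) {
    s <- pos - off
    if (s <= t && t <= s + L - 1) hits <- hits + 1
  }
  expect_equal(hits / (G * L), L / G)
})

test_that("simulation is reproducible from its seed", {
  p <- small_params()
  a <- simulate_experiment(p, 2000, seed = 99)
  b <- simulate_experiment(p, 2000, seed = 99)
  expect_identical(a$counts, b$counts)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$events, b$events)
  c2 <- simulate_experiment(p, 2000, seed = 100)
  expect_false(identical(a$phenotypes, c2$phenotypes))
})

test_that("without DSBs or noise every channel segregates 2:2", {
  p <- simulation_params(genome_length = 1e6, dsb_mean = 0,
                         dsb_law = "fixed", test_locus = 5e5,
                         flank_left = 4e5, flank_right = 6e5,
                         reversion_rate = 0)
  sim <- simulate_experiment(p, 10000, seed = 1)
  expect_equal(sim$counts$n_31, 0)
  expect_equal(sim$counts$n_13, 0)
  expect_equal(sim$counts$n_40, 0)
  expect_equal(sim$counts$n_04, 0)
  expect_equal(nrow(sim$events), 0)
  ph <- sim$phenotypes
  expect_equal(nrow(ph), 40000)
  expect_true(all(tapply(ph$yellow, ph$tetrad_id, sum) == 2))
  expect_true(all(tapply(ph$red, ph$tetrad_id, sum) == 2))
})

test_that("full restoration suppresses conversion entirely", {
  p <- small_params(p_conversion = 0)
  sim <- simulate_experiment(p, 20000, seed = 2, keep_phenotypes = FALSE)
  expect_equal(sim$counts$n_31, 0)
  expect_equal(sim$counts$n_13, 0)
  expect_true(any(sim$events$mmr_outcome == "restored"))
  expect_false(any(sim$events$mmr_outcome == "converted"))
})

test_that("observed conversion classes match the closed-form expectation", {
  p <- small_params()
  n <- 50000
  sim <- simulate_experiment(p, n, seed = 11, keep_phenotypes = FALSE)
  rates <- expected_segregation_rates(p)
  # total conversions within 3 binomial SE
  p_tot <- 2 * rates$p_31
  obs <- sim$counts$n_31 + sim$counts$n_13
  expect_lt(abs(obs - n * p_tot), 3 * sqrt(n * p_tot * (1 - p_tot)))
  # geometric tracts keep mean coverage L/G
  pg <- small_params(tract_law = "geometric", tract_mean = 2000,
                     dsb_mean = 5, p_co = 0.05)
  simg <- simulate_experiment(pg, n, seed = 12, keep_phenotypes = FALSE)
  rg <- expected_segregation_rates(pg)
  obs_g <- simg$counts$n_31 + simg$counts$n_13
  expect_lt(abs(obs_g - n * 2 * rg$p_31),
            3 * sqrt(n * 2 * rg$p_31 * (1 - 2 * rg$p_31)))
})

test_that("3:1 and 1:3 classes are symmetric in expectation", {
  p <- small_params(dsb_mean = 4, tract_mean = 10000)
  sim <- simulate_experiment(p, 60000, seed = 21, keep_phenotypes = FALSE)
  n31 <- sim$counts$n_31; n13 <- sim$counts$n_13
  expect_gt(n31 + n13, 200)
  chi <- stats::chisq.test(c(n31, n13), p = c(0.5, 0.5))
  expect_gt(chi$p.value, 0.01)
})

test_that("misgrouped tetrads follow the re-association binomial", {
  p <- small_params(dsb_mean = 0, misgrouping_rate = 1)
  n <- 40000
  sim <- simulate_experiment(p, n, seed = 31, keep_phenotypes = FALSE)
  # each grain fluorescent with marginal probability 1/2:
  # P(3:1) = 4 * p^3 * (1-p) = 0.25
  expect_lt(abs(sim$counts$n_31 - 0.25 * n), 3 * sqrt(n * 0.25 * 0.75))
  expect_lt(abs(sim$counts$n_40 - 0.0625 * n),
            3 * sqrt(n * 0.0625 * (1 - 0.0625)))
})

test_that("measured mitotic reversion rates cannot explain the signal", {
  p <- simulation_params(genome_length = 1e6, dsb_mean = 0,
                         dsb_law = "fixed", reversion_rate = 1e-7)
  sim <- simulate_experiment(p, 45000, seed = 41, keep_phenotypes = FALSE)
  # expected 3:1 mimics: 2 * 45000 * 1e-7 = 0.009, i.e. essentially none
  expect_lte(sim$counts$n_31, 1)
})

test_that("a single simulated tetrad exposes the full event log", {
  p <- small_params(p_homolog = 0.5, dsb_mean = 6)
  out <- simulate_tetrad(p, seed = 5)
  expect_equal(nrow(out$phenotype), 4)
  expect_equal(nrow(out$events), 6)
  expect_true(all(out$events$template %in% c("homolog", "sister")))
  expect_true(any(out$events$template == "sister"))
  # tract interval always contains the break
  with(out$events, {
    expect_true(all(tract_start <= dsb_position &
                      dsb_position <= tract_end))
  })
})

test_that("parameter recovery closes the loop with the estimator", {
  # programmed adjusted conversion frequency: 2*0.5*(1000/1e6)*0.5 = 5e-4
  p <- simulation_params(genome_length = 1e6, dsb_mean = 2,
                         dsb_law = "fixed", tract_mean = 1000,
                         tract_law = "fixed", p_homolog = 0.5,
                         p_conversion = 0.5, p_co = 0.1,
                         reversion_rate = 0)
  sim <- simulate_experiment(p, 2e5, seed = 51, keep_phenotypes = FALSE,
                             events = "none")
  rec <- recover_parameters(sim)
  expect_false(rec$insufficient_events)
  expect_lt(abs(rec$z_31), 3)
  expect_lt(abs(rec$tract_relative_error), 0.2)

  none <- simulate_experiment(small_params(dsb_mean = 0), 100, seed = 1,
                              keep_phenotypes = FALSE)
  rec0 <- recover_parameters(none)
  expect_true(rec0$insufficient_events)
  expect_true(is.na(rec0$tract_recovered))
})

test_that("simulation parameters are validated", {
  expect_error(simulation_params(p_co = 1.2), "probabilities")
  expect_error(simulation_params(tract_mean = 0), "tract_mean")
  expect_error(simulation_params(test_locus = 0), "test_locus")
  expect_error(simulation_params(flank_left = 10), "both flanking")
  expect_error(simulation_params(genome_length = 1e6, test_locus = 5e5,
                                 flank_left = 6e5, flank_right = 7e5),
               "flank_left < test_locus")
})
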