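test_that("configuration validation and seed requirement", {
  expect_error(simulation_config(n_cells = 10), "seed")
  expect_error(simulation_config(n_cells = 0, seed = 1), "n_cells")
  expect_error(simulation_config(chase_times = -5, seed = 1),
               "chase_times")
  cfg <- simulation_config(n_cells = 10, seed = 1)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$chase_times, c(0, 144))
})

test_that("no divisions happen by time zero and min cycle is respected", {
  cfg <- simulation_config(n_cells = 500, chase_times = c(0, 40),
                           seed = 3)
  cells <- simulate_divisions(cfg)
  expect_true(all(cells$divisions[cells$chase_time == 0] == 0))
  ## bulk min cycle 15 h: at most floor(40/15) = 2 divisions by 40 h
  expect_true(all(cells$divisions[cells$chase_time == 40] <= 2))
})

test_that("single-population exponential cycling matches Poisson counts", {
  m <- division_time_model(0, 1, 10)
  p <- suppressWarnings(mixture_params(m, m, 0))
  cfg <- simulation_config(n_cells = 1e5, params = p,
                           chase_times = 30, seed = 11,
                           measurement_cv = 0)
  cells <- simulate_divisions(cfg)
  emp <- tabulate(cells$divisions + 1L, nbins = 16) / nrow(cells)
  pois <- dpois(0:15, 3)
  expect_lt(0.5 * sum(abs(emp - pois)) + 0.5 * ppois(15, 3,
                                                     lower.tail = FALSE),
            0.01)
})

test_that("readout halves intensity per division and clamps at the floor", {
  cfg <- simulation_config(n_cells = 4, seed = 2, measurement_cv = 0,
                           autofluorescence_floor = 0)
  cells <- data.frame(cell_id = 1:4, population = "bulk",
                      chase_time = 144, divisions = c(0L, 3L, 1L, 2L))
  out <- simulate_readout(cells, cfg)
  i0 <- out$true_intensity * 2^out$divisions
  expect_equal(out$measured_intensity, i0 / 2^c(0, 3, 1, 2))
  expect_equal(out$true_intensity[2], i0[2] / 8)

  cfg2 <- simulation_config(n_cells = 4, seed = 2, measurement_cv = 0.2,
                            autofluorescence_floor = 1e6)
  out2 <- simulate_readout(cells, cfg2)
  expect_true(all(out2$measured_intensity >= 1e6))
})

test_that("population assignment is a Bernoulli draw of the slow fraction", {
  ex <- small_experiment()
  lineages <- ex$cells[!duplicated(ex$cells$cell_id), ]
  a <- ex$config$params$slow_fraction
  n <- ex$config$n_cells
  expect_lt(abs(mean(lineages$population == "slow") - a),
            3 * sqrt(a / n))
})

test_that("simulation is reproducible and export round-trips", {
  cfg <- simulation_config(n_cells = 300, seed = 17)
  ex1 <- simulate_dye_dilution(cfg)
  ex2 <- simulate_dye_dilution(cfg)
  expect_identical(ex1$cells, ex2$cells)

  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  f1 <- export_experiment(ex1, d1)
  f2 <- export_experiment(ex2, d2)
  expect_identical(unname(tools::md5sum(f1$events)),
                   unname(tools::md5sum(f2$events)))

  ev <- read_events(f1$events[["144"]])
  raw <- utils::read.csv(f1$events[["144"]])
  expect_equal(ev$intensities, raw$intensity)
  expect_equal(length(ev), cfg$n_cells)

  truth <- read_ground_truth(f1$truth[["144"]])
  expect_equal(nrow(truth), cfg$n_cells)
  expect_true(all(truth$population %in% c("bulk", "slow")))
  expect_true(all(truth$divisions >= 0))
})

test_that("cell-level sampling favors deeply divided lineages", {
  ex <- small_experiment()
  smp <- sample_cells(ex)
  lin <- ex$cells
  t6 <- max(ex$config$chase_times)
  expect_gt(mean(smp$divisions[smp$chase_time == t6]),
            mean(lin$divisions[lin$chase_time == t6]))
  expect_identical(sample_cells(ex), smp)  # seeded
})

test_that("generation fractions of lineages match the renewal counts", {
  ex <- small_experiment()
  p <- ex$config$params
  t6 <- max(ex$config$chase_times)
  ef <- empirical_generation_fractions(ex, t6)
  mf <- mixture_generation_fractions(
    generation_distribution(p$bulk, t6),
    generation_distribution(p$slow, t6),
    p$slow_fraction)
  expect_lt(tv_fracs(ef, mf), 0.02)
})

test_that("label-retaining slow cells dominate the top intensity decile", {
  cfg <- simulation_config(n_cells = 3e4,
                           params = mixture_params(
                             division_time_model(15, 2, 4),
                             division_time_model(60, 2, 10), 0.02),
                           seed = 23)
  ex <- simulate_dye_dilution(cfg)
  d6 <- ex$cells[ex$cells$chase_time == 144, ]
  top <- d6[d6$measured_intensity >=
              quantile(d6$measured_intensity, 0.9), ]
  enrichment <- mean(top$population == "slow") / 0.02
  expect_gte(enrichment, 5)
})
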