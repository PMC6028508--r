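make_truth <- function() default_mixture()

noiseless_observed <- function(params = make_truth(), chase_time = 144,
                               step = 0.25) {
  init <- initial_intensity_model(log_mean = log(1e4), log_sd = 0.38)
  bins <- intensity_bins(100, exp(log(1e4) + 3.1 * 0.38), 256)
  obs <- forward_model(params, init, chase_time, bins, step = step)
  obs$total_events <- 1e6  # exact densities: suppress small-sample warning
  list(obs = obs, init = init, bins = bins)
}

test_that("objective vanishes at the generating parameters", {
  p <- make_truth()
  x <- noiseless_observed(p)
  for (loss in c("hellinger", "density"))
    expect_lt(dilution_objective(p, x$obs, x$init, 144, step = 0.25,
                                 loss = loss), 1e-14)
})

test_that("objective is constant in alpha for identical components", {
  m <- division_time_model(15, 2, 4)
  x <- noiseless_observed()
  same <- function(a) structure(list(bulk = m, slow = m,
                                     slow_fraction = a),
                                class = "mixture_params")
  o1 <- dilution_objective(same(0.1), x$obs, x$init, 144, step = 0.25)
  o2 <- dilution_objective(same(0.4), x$obs, x$init, 144, step = 0.25)
  expect_equal(o1, o2, tolerance = 1e-12)
})

test_that("perturbing the bulk scale strictly increases the objective", {
  p <- make_truth()
  x <- noiseless_observed(p)
  worse <- mixture_params(
    division_time_model(p$bulk$min_cycle_time, p$bulk$shape,
                        1.5 * p$bulk$scale),
    p$slow, p$slow_fraction)
  expect_gt(dilution_objective(worse, x$obs, x$init, 144, step = 0.25),
            dilution_objective(p, x$obs, x$init, 144, step = 0.25))
})

test_that("out-of-bounds parameters get a finite penalty", {
  x <- noiseless_observed()
  bad <- suppressWarnings(
    mixture_params(division_time_model(1, 2, 4),      # t_b below bounds
                   division_time_model(60, 2, 10), 0.02))
  v <- dilution_objective(bad, x$obs, x$init, 144, step = 0.25,
                          bounds = default_bounds())
  expect_true(is.finite(v))
  expect_gt(v, 1)
})

test_that("noiseless self-consistency recovers the parameters", {
  p <- make_truth()
  x <- noiseless_observed(p)
  fit <- fit_dye_dilution(
    x$obs, x$init, 144,
    config = fit_config(n_starts = 2, max_iterations = 2000,
                        tolerance = 1e-9, seed = 4))
  expect_true(fit$converged)
  expect_lt(abs(slow_fraction(fit) - 0.015) / 0.015, 0.2)
  expect_lt(abs(mean(fit$params$bulk) - mean(p$bulk)) / mean(p$bulk), 0.1)
  expect_lt(abs(mean(fit$params$slow) - mean(p$slow)) / mean(p$slow), 0.1)
  ## nested two-population objective cannot lose to its submodel
  expect_lte(fit$objective, fit$single_population$objective)
  expect_true(two_population_support(fit))
  ## the ordering convention holds on the returned parameters
  expect_gte(mean(fit$params$slow), mean(fit$params$bulk))
})

test_that("fitting is deterministic given the seed", {
  x <- noiseless_observed()
  cfg <- fit_config(n_starts = 2, max_iterations = 150, seed = 9)
  f1 <- fit_dye_dilution(x$obs, x$init, 144, cfg)
  f2 <- fit_dye_dilution(x$obs, x$init, 144, cfg)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$per_start, f2$per_start)
})

test_that("fit methods expose the usual modelling surface", {
  x <- noiseless_observed()
  fit <- fit_dye_dilution(x$obs, x$init, 144,
                          fit_config(n_starts = 1, max_iterations = 200,
                                     seed = 2))
  expect_named(coef(fit), c("bulk_t", "bulk_sigma", "bulk_lambda",
                            "slow_t", "slow_sigma", "slow_lambda",
                            "alpha"))
  pr <- predict(fit)
  expect_s3_class(pr, "intensity_histogram")
  expect_equal(sum(pr$density * pr$bins$dlog), 1, tolerance = 1e-9)
  expect_equal(residuals(fit), x$obs$density - pr$density)
  expect_output(print(summary(fit)), "Per-start")
  grDevices::pdf(NULL)
  expect_invisible(plot(fit))
  grDevices::dev.off()
  g <- lrc_gate(fit)
  expect_true(g > x$bins$floor && g < x$bins$ceiling)
  sim <- simulate(fit, seed = 3, n_cells = 500)
  expect_s3_class(sim, "dd_experiment")
  expect_equal(sim$config$params$slow_fraction,
               fit$params$slow_fraction)
})

test_that("slow fraction accessor respects convention and identifiability", {
  p <- mixture_params(division_time_model(15, 2, 4),
                      division_time_model(60, 2, 10), 0.015)
  expect_equal(slow_fraction(p), 0.015)
  m <- division_time_model(20, 2, 5)
  degenerate <- structure(list(bulk = m, slow = m, slow_fraction = 0.2),
                          class = "mixture_params")
  expect_warning(v <- slow_fraction(degenerate), "identifiable")
  expect_true(is.na(v))
  ## constructor enforces the ordering by swapping
  expect_warning(
    sw <- mixture_params(division_time_model(60, 2, 10),
                         division_time_model(15, 2, 4), 0.98),
    "swapped")
  expect_equal(sw$slow_fraction, 0.02)
  expect_equal(mean(sw$slow), 80)
})

test_that("quantile gating is exact at the edges", {
  g <- gate_high_retainers(1:1000, gate_quantile = 0.99)
  expect_equal(length(g$high), 10L)
  expect_equal(g$threshold, 991)
  expect_equal(length(g$high) + length(g$bulk), 1000L)

  ties <- gate_high_retainers(rep(5, 100), gate_quantile = 0.5)
  expect_equal(length(ties$high), 100L)  # ties break toward High

  expect_equal(length(gate_high_retainers(1:50,
                                          gate_value = 100)$high), 0L)
  expect_equal(length(gate_high_retainers(1:50,
                                          gate_quantile = 1)$high), 0L)
  expect_equal(length(gate_high_retainers(1:50,
                                          gate_quantile = 0)$high), 50L)
  expect_error(gate_high_retainers(numeric(0), gate_quantile = 0.5),
               "no events")
  expect_error(gate_high_retainers(1:5, gate_quantile = 0.5,
                                   gate_value = 2), "exactly one")
})

test_that("truth-labelled events are enriched in the high gate", {
  cfg <- simulation_config(n_cells = 3e4,
                           params = mixture_params(
                             division_time_model(15, 2, 4),
                             division_time_model(60, 2, 10), 0.02),
                           seed = 31)
  ex <- simulate_dye_dilution(cfg)
  d6 <- ex$cells[ex$cells$chase_time == 144, ]
  g <- gate_high_retainers(d6$measured_intensity, gate_quantile = 0.99)
  frac_slow_high <- mean(d6$population[g$is_high] == "slow")
  expect_gte(frac_slow_high / 0.02, 5)
})

test_that("fixed parameters are held constant during the fit", {
  x <- noiseless_observed()
  fit <- fit_dye_dilution(
    x$obs, x$init, 144,
    fit_config(n_starts = 1, max_iterations = 150, seed = 3,
               fixed = c(bulk_lambda = 2, slow_lambda = 2)))
  co <- coef(fit)
  expect_equal(unname(co["bulk_lambda"]), 2)
  expect_equal(unname(co["slow_lambda"]), 2)
})
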