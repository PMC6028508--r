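test_that("bin axis construction enforces its contracts", {
  b <- intensity_bins(100, 30000, 64)
  expect_equal(length(b$edges), 65L)
  expect_true(all(diff(b$log_edges) > 0))
  expect_equal(diff(b$log_edges), rep(b$dlog, 64), tolerance = 1e-12)
  expect_error(intensity_bins(0, 100), "floor")
  expect_error(intensity_bins(100, 50), "ceiling")
  expect_error(intensity_bins(1, 100, n_bins = 8), "32")
})

test_that("histograms are normalized, clamp extremes, and accept weights", {
  b <- intensity_bins(10, 1e5, 64)
  set.seed(1)
  x <- c(rlnorm(5000, log(1000), 1), 1e-3, 1e9)  # beyond both limits
  h <- build_histogram(x, b)
  expect_equal(sum(h$density * b$dlog), 1, tolerance = 1e-9)
  expect_true(all(h$density >= 0))
  expect_equal(h$total_events, 5002L)

  hidden <- build_histogram(rep(500, 1000), b)
  expect_equal(sum(hidden$density > 0), 1L)  # identical events, one bin
  expect_equal(sum(hidden$density * b$dlog), 1, tolerance = 1e-12)

  ## doubling an event's weight equals duplicating the event
  hw <- build_histogram(c(100, 200, 400), b, weights = c(1, 2, 1))
  hd <- build_histogram(c(100, 200, 200, 400), b)
  expect_equal(hw$density, hd$density, tolerance = 1e-12)

  expect_error(build_histogram(rep(5, 10), b), "floor")
})

test_that("zero divisions leave the initial distribution unchanged", {
  init <- initial_intensity_model(log_mean = log(1e4), log_sd = 0.35)
  bins <- intensity_bins(100, 6e4, 128)
  p <- mixture_params(division_time_model(15, 2, 4),
                      division_time_model(60, 2, 10), 0)
  pred <- forward_model(p, init, chase_time = 0, bins)
  expected <- diff(pnorm(bins$log_edges, log(1e4), 0.35))
  expected[1] <- expected[1] + pnorm(bins$log_edges[1], log(1e4), 0.35)
  expected[128] <- expected[128] +
    pnorm(bins$log_edges[129], log(1e4), 0.35, lower.tail = FALSE)
  expected <- expected / bins$dlog / sum(expected)
  expect_equal(pred$density, expected, tolerance = 1e-9)
})

test_that("one deterministic division shifts the log-density by log 2", {
  init <- initial_intensity_model(log_mean = log(1e4), log_sd = 0.3)
  bins <- intensity_bins(50, 6e4, 256)
  one_div <- cfsedilution:::predict_intensity_weights(c(0, 1), init, bins)
  ## oracle: mass of the halved lognormal in each bin
  expected <- diff(pnorm(bins$log_edges + log(2), log(1e4), 0.3))
  expected[1] <- expected[1] + pnorm(bins$log_edges[1] + log(2),
                                     log(1e4), 0.3)
  expected <- expected / bins$dlog
  expected <- expected / (sum(expected) * bins$dlog)
  expect_equal(one_div$density, expected, tolerance = 1e-9)
})

test_that("predictions integrate to one for random occupancies", {
  set.seed(3)
  init <- initial_intensity_model(log_mean = 9, log_sd = 0.4)
  bins <- intensity_bins(80, 3e4, 256)
  for (i in 1:10) {
    w <- rgamma(8, 1); w <- w / sum(w)
    h <- cfsedilution:::predict_intensity_weights(w, init, bins)
    expect_equal(sum(h$density * bins$dlog), 1, tolerance = 1e-9)
  }
})

test_that("mixing is bin-wise with the trivial endpoints exact", {
  init <- initial_intensity_model(log_mean = 9, log_sd = 0.4)
  bins <- intensity_bins(80, 3e4, 128)
  b <- cfsedilution:::predict_intensity_weights(c(1, 0), init, bins)
  s <- cfsedilution:::predict_intensity_weights(c(0, 1), init, bins)
  expect_equal(mix_intensities(b, s, 0)$density, b$density)
  expect_equal(mix_intensities(b, s, 1)$density, s$density)
  expect_equal(mix_intensities(b, s, 0.5)$density,
               (b$density + s$density) / 2, tolerance = 1e-12)
  other <- intensity_bins(80, 3e4, 64)
  s2 <- cfsedilution:::predict_intensity_weights(c(0, 1), init, other)
  expect_error(mix_intensities(b, s2, 0.5), "axes")
})

test_that("forward model is deterministic and alpha-invariant when components match", {
  init <- initial_intensity_model(log_mean = log(1e4), log_sd = 0.35)
  bins <- intensity_bins(100, 6e4, 128)
  m <- division_time_model(15, 2, 4)
  same <- structure(list(bulk = m, slow = m, slow_fraction = 0.3),
                    class = "mixture_params")
  h1 <- forward_model(same, init, 96, bins)
  same2 <- structure(list(bulk = m, slow = m, slow_fraction = 0.7),
                     class = "mixture_params")
  h2 <- forward_model(same2, init, 96, bins)
  expect_equal(h1$density, h2$density, tolerance = 1e-12)
  expect_identical(forward_model(same, init, 96, bins)$density, h1$density)
})

test_that("bulk mean log-intensity decreases with chase time", {
  init <- initial_intensity_model(log_mean = log(1e4), log_sd = 0.35)
  bins <- intensity_bins(1, 6e4, 256)  # low floor: no pile-up distortion
  m <- division_time_model(15, 2, 4)
  p <- mixture_params(m, division_time_model(60, 2, 10), 0)
  means <- sapply(c(24, 48, 72, 96, 120, 144), function(tt)
    mean_log_intensity(forward_model(p, init, tt, bins)))
  expect_true(all(diff(means) < 1e-8))
})

test_that("slow cells are enriched at high intensity after one bulk cycle", {
  init <- initial_intensity_model(log_mean = log(1e4), log_sd = 0.35)
  bins <- intensity_bins(100, 6e4, 256)
  bulk <- division_time_model(15, 2, 4)
  slow <- division_time_model(60, 2, 10)
  for (tt in c(24, 72, 144)) {
    hb <- predict_intensity(generation_distribution(bulk, tt), init, bins)
    hs <- predict_intensity(generation_distribution(slow, tt), init, bins)
    mode_bin <- which.max(diff(pnorm(bins$log_edges, log(1e4), 0.35)))
    keep <- seq(mode_bin, bins$n_bins)
    keep <- keep[hb$density[keep] > 1e-10 & hs$density[keep] > 1e-10]
    ratio <- hs$density[keep] / hb$density[keep]
    expect_true(all(diff(ratio) >= -1e-6 * pmax(ratio[-1], 1)))
  }
})

test_that("scaling all intensities shifts predictions by the same factor", {
  m <- division_time_model(15, 2, 4)
  p <- mixture_params(m, division_time_model(60, 2, 10), 0.02)
  cc <- 3.7
  init1 <- initial_intensity_model(log_mean = 9, log_sd = 0.35)
  init2 <- initial_intensity_model(log_mean = 9 + log(cc), log_sd = 0.35)
  bins1 <- intensity_bins(80, 3e4, 128)
  bins2 <- intensity_bins(80 * cc, 3e4 * cc, 128)
  h1 <- forward_model(p, init1, 144, bins1)
  h2 <- forward_model(p, init2, 144, bins2)
  expect_equal(h1$density, h2$density, tolerance = 1e-9)
})

test_that("histograms survive a text round trip", {
  set.seed(5)
  b <- intensity_bins(10, 1e4, 64)
  h <- build_histogram(rlnorm(2000, log(300), 0.8), b)
  f <- tempfile(fileext = ".tsv")
  write_histogram(h, f)
  h2 <- read_histogram(f)
  expect_equal(h2$density, h$density, tolerance = 1e-6)
  expect_equal(h2$bins$log_centers, h$bins$log_centers, tolerance = 1e-6)
})
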