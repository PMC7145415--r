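test_that("population PSTH conserves the spike count", {
  empty <- population_psth(list(), bin = 100, t_range = c(0, 1000))
  expect_true(all(empty$counts == 0))
  one_bin <- population_psth(rep(list(500), 100), bin = 100,
                             t_range = c(0, 1000))
  expect_equal(sum(one_bin$counts), 100)
  expect_equal(max(one_bin$counts), 100)
  r <- withr::with_seed(2, runif(5000, 0, 2000))
  ps <- population_psth(data.frame(t = r), bin = 37, t_range = c(0, 2000))
  expect_equal(sum(ps$counts), 5000)
  expect_error(population_psth(list(), bin = 0), "positive")
})

test_that("Gaussian rate kernels integrate to the spike count", {
  tg <- seq(-1000, 2000, by = 1)
  r1 <- gaussian_rate(500, sigma = 100, t_grid = tg)
  expect_equal(max(r1), 1 / (100 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(tg[which.max(r1)], 500)
  expect_equal(sum(r1) * 1, 1, tolerance = 1e-3)
  expect_true(all(gaussian_rate(numeric(0), 100, tg) == 0))
  rn <- gaussian_rate(c(100, 400, 401), sigma = 50, t_grid = tg)
  expect_equal(sum(rn), 3, tolerance = 1e-3)
})

test_that("sustainedness index separates flat, sustained and peaked traces", {
  t <- seq(0, 2000, by = 1)
  flat <- rep(-51, length(t))
  expect_equal(sustainedness_index(t, flat, c(500, 1500)), 0)
  sustained <- ifelse(t >= 500 & t < 1500, -46, -51)
  expect_equal(sustainedness_index(t, sustained, c(500, 1500)), 1)
  peak <- ifelse(t >= 700 & t < 800, -44, -51)
  expect_equal(sustainedness_index(t, peak, c(500, 1500)), 0.1)
  expect_error(sustainedness_index(t, flat, c(-10, 500)), "outside")
})

test_that("IPSP detection recovers injected events with known timing", {
  dt <- 0.5
  t <- seq(0, 10000, by = dt)
  v <- rep(-51, length(t)) + 0.3 * sin(2 * pi * t / 4000)  # slow drift
  truth <- seq(400, 9600, by = 400)
  for (ts in truth)
    v <- v - 1.5 * mbggn:::dblexp_kernel(t - ts, 5, 30)
  found <- detect_ipsps(t, v, min_amplitude = 0.5, refractory = 20)
  # recall: each true event matched within 20 ms of its trough
  tp <- vapply(truth, function(x) min(abs(found - x)), numeric(1))
  expect_gte(mean(tp < 20), 0.95)
  # trough occurs after onset; timing error of matched events < 5 ms
  trough_offset <- 30 * 5 / 25 * log(30 / 5)
  match_err <- abs(tp - trough_offset)
  expect_lt(median(match_err), 5)
  expect_length(detect_ipsps(t, rep(-51, length(t))), 0)
  expect_error(detect_ipsps(c(0, 1), c(0, 0), refractory = 20),
               "shorter")
})

test_that("dynamic-range slopes normalize against the reference curve", {
  amps <- seq(0.1, 1, by = 0.1)
  counts <- c(0, 0, 5, 15, 25, 35, 45, 55, 30, 10)
  s <- dynamic_range_slope(amps, counts)
  expect_equal(s$normalized, 1)
  s2 <- dynamic_range_slope(amps, counts * 2, ref_slope = s$slope)
  expect_equal(s2$normalized, 2, tolerance = 1e-9)
  expect_error(dynamic_range_slope(amps, rep(0, 10)), "no nonzero")
  expect_error(dynamic_range_slope(c(1, 2, 3), c(0, 0, 4)),
               "fewer than 3")
})

test_that("KC/GGN local correlation behaves on synthetic populations", {
  dv <- withr::with_seed(8, runif(200, 2, 10))
  counts_neg <- withr::with_seed(9, rpois(200, pmax(0.1, 10 - dv)))
  expect_lt(kc_ggn_local_correlation(counts_neg, dv), -0.3)
  shuffled <- sample(counts_neg)
  expect_lt(abs(kc_ggn_local_correlation(shuffled, dv)), 0.2)
  expect_error(kc_ggn_local_correlation(rep(1, 200), dv),
               "zero-variance")
  expect_error(kc_ggn_local_correlation(1:5, 1:5), "at least 10")
})

test_that("simulation results round-trip losslessly through the container", {
  res <- simulation_result(
    t = seq(0, 10, by = 0.5),
    ggn = list(Vm = rnorm(21)),
    kc = list(spikes = data.frame(kc = 1:3, t = c(1, 2, 3))),
    config = list(dt = 0.5, n_kc = 3),
    seed = list(network = 1))
  expect_match(res$provenance$config_hash, "^[0-9a-f]{8}$")
  path <- withr::local_tempfile(fileext = ".rds")
  save_result(res, path)
  back <- load_result(path)
  expect_identical(back$ggn$Vm, res$ggn$Vm)
  expect_identical(back$kc$spikes, res$kc$spikes)
  save_result(back, path)
  expect_identical(load_result(path)$ggn$Vm, res$ggn$Vm)
})
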