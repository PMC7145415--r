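kcp <- kc_params()

test_that("the KC rests near -70 mV and is silent without input", {
  sim <- simulate_kc(kcp, duration = 600)
  expect_equal(tail(sim$v, 1), -70, tolerance = 3)
  expect_length(sim$spikes, 0)
  # hyperpolarizing step: below rest, still silent
  hyp <- simulate_kc(kcp, duration = 800,
                     current = function(t) ifelse(t >= 200 & t < 600,
                                                  -0.02, 0))
  expect_lt(min(hyp$v), -75)
  expect_length(hyp$spikes, 0)
})

test_that("KC spike count rises with drive, then collapses near saturation", {
  amps <- c(0.05, 0.1, 0.2, 0.4, 0.7, 1.3)
  counts <- vapply(amps, function(a) {
    s <- simulate_kc(kcp, duration = 2200,
                     current = function(t) ifelse(t >= 200 & t < 2000,
                                                  a, 0))
    length(s$spikes)
  }, numeric(1))
  expect_equal(counts[1], 0)            # subthreshold
  imax <- which.max(counts)
  expect_gt(imax, 2)                    # a rising branch exists
  expect_lt(imax, length(amps))         # and then a decline
  expect_lt(counts[length(amps)], counts[imax] / 4)
})

test_that("KC integration is robust to halving dt and is deterministic", {
  step <- function(t) ifelse(t >= 300 & t < 1300, 0.3, 0)
  s1 <- simulate_kc(kcp, dt = 0.025, duration = 1500, current = step)
  s2 <- simulate_kc(kcp, dt = 0.0125, duration = 1500, current = step)
  expect_lte(abs(length(s1$spikes) - length(s2$spikes)), 1)
  s3 <- simulate_kc(kcp, dt = 0.025, duration = 1500, current = step)
  expect_identical(s1$spikes, s3$spikes)
  expect_error(simulate_kc(kcp, dt = 0.1), "dt must be")
})

test_that("KC spiking needs strong synchronized input", {
  # equal conductance-time delivered in 10 ms vs spread over 500 ms
  sync <- simulate_kc(kcp, duration = 900,
                      g_exc = function(t) ifelse(t >= 200 & t < 210,
                                                 0.005, 0))
  spread <- simulate_kc(kcp, duration = 900,
                        g_exc = function(t) ifelse(t >= 200 & t < 700,
                                                   1e-4, 0))
  expect_gt(length(sync$spikes), 0)
  expect_length(spread$spikes, 0)
})

test_that("IG is silent without drive and its f-I curve is monotone", {
  sim <- simulate_ig(ig_params(), duration = 2000)
  expect_length(sim$spikes, 0)
  rates <- vapply(c(4, 5, 7, 10, 15), function(I)
    length(simulate_ig(ig_params(i_base = I),
                       duration = 5000)$spikes) / 5, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[length(rates)], rates[1])
})

test_that("IG current calibration reaches and verifies target rates", {
  cur <- calibrate_ig_current(ig_params(), target_rate = 7, tol = 0.5)
  rate <- length(simulate_ig(ig_params(i_base = cur),
                             duration = 10000)$spikes) / 10
  expect_equal(rate, 7, tolerance = 0.5)
  # doubling the target needs strictly more current
  cur14 <- calibrate_ig_current(ig_params(), target_rate = 14, tol = 0.5)
  expect_gt(cur14, cur)
  # target zero: a current below rheobase
  cur0 <- calibrate_ig_current(ig_params(), target_rate = 0, tol = 0.5)
  expect_lte(length(simulate_ig(ig_params(i_base = cur0),
                                duration = 5000)$spikes) / 5, 0.5)
  expect_error(calibrate_ig_current(ig_params(), target_rate = 1000,
                                    tol = 0.5, bracket = c(0, 5)),
               "bracket")
})
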