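test_that("graded release saturates between 0 and gbar", {
  gp <- graded_synapse(gbar = 2e-3, V_half = -45, slope = 3, tau = 4)
  dt <- 0.1
  low <- graded_release(rep(-90, 2000), gp, dt)
  high <- graded_release(rep(0, 2000), gp, dt)
  expect_lt(tail(low, 1), 1e-3 * gp$gbar + 1e-12)
  expect_equal(tail(high, 1), gp$gbar, tolerance = 1e-6)
  # -50 -> -45 step with V_half -45, slope 3: steady values from the
  # Boltzmann closed form
  vpre <- c(rep(-50, 4000), rep(-45, 4000))
  g <- graded_release(vpre, gp, dt)
  expect_equal(g[4000], gp$gbar / (1 + exp(5 / 3)), tolerance = 1e-3)
  expect_equal(tail(g, 1), 0.5 * gp$gbar, tolerance = 1e-3)
  # bounded state for arbitrary finite traces
  wild <- graded_release(sin(seq(0, 50, by = 0.01)) * 200, gp, dt)
  expect_true(all(wild >= 0 & wild <= gp$gbar))
  expect_error(graded_release(c(0, NaN), gp, dt), "finite")
})

test_that("spike-triggered conductances superpose peak-normalized kernels", {
  sp <- spike_synapse(weight = 2e-3, tau_rise = 1, tau_decay = 5,
                      delay = 3)
  dt <- 0.025
  expect_true(all(spike_conductance(numeric(0), sp, dt, 50) == 0))
  g1 <- spike_conductance(10, sp, dt, 80)
  tp <- 5 * 1 / 4 * log(5)
  t <- seq(0, 80, by = dt)
  expect_equal(max(g1), sp$weight, tolerance = 1e-3)
  expect_equal(t[which.max(g1)], 10 + 3 + tp, tolerance = 0.05)
  g2 <- spike_conductance(c(10, 30), sp, dt, 80)
  expect_equal(g2, g1 + spike_conductance(30, sp, dt, 80),
               tolerance = 1e-12)
  expect_true(all(g2 >= 0))
  expect_error(spike_synapse(tau_rise = 5, tau_decay = 1), "tau_decay")
})

test_that("lognormal weight sampling honours mean, sd and seed", {
  spec <- weight_spec("lognormal", mean = 1, sd = 1)
  w <- sample_weights(spec, 1e5, seed = 7)
  expect_true(all(w > 0))
  expect_gt(mean(w), 0.99); expect_lt(mean(w), 1.01)
  expect_gt(sd(w), 0.97); expect_lt(sd(w), 1.03)
  expect_identical(w, sample_weights(spec, 1e5, seed = 7))
  expect_false(identical(w, sample_weights(spec, 1e5, seed = 8)))
  cw <- sample_weights(weight_spec("uniform-constant", mean = 0.4), 10)
  expect_identical(cw, rep(0.4, 10))
  expect_error(weight_spec("lognormal", mean = -1), "positive")
})

test_that("the equivalent synapse reproduces many delayed unit synapses", {
  unit <- spike_synapse(weight = 1e-5, tau_rise = 1, tau_decay = 5)
  dt <- 0.1
  # degenerate aggregation equals the unit kernel
  agg1 <- equivalent_synapse(1, c(0, 0), unit)
  k1 <- aggregate_kernel_trace(agg1, dt, duration = 60)
  expect_equal(k1, unit$weight *
                 mbggn:::dblexp_kernel(seq(0, 60, by = dt), 1, 5),
               tolerance = 1e-9)
  # conductance-time conservation
  agg <- equivalent_synapse(1000, c(0, 60), unit)
  ka <- aggregate_kernel_trace(agg, dt, duration = 200)
  expect_equal(sum(ka) * dt, 1000 * sum(k1) * dt, tolerance = 0.01)
  # 1000 explicitly delayed unit synapses vs the aggregate (stratified
  # delays: one per equal slice of the window)
  delays <- withr::with_seed(5, (0:999 + runif(1000)) * 60 / 1000)
  t <- seq(0, 200, by = dt)
  explicit <- numeric(length(t))
  for (d in delays)
    explicit <- explicit + unit$weight *
      mbggn:::dblexp_kernel(t - d, 1, 5)
  rms <- sqrt(mean((explicit - ka)^2)) / max(ka)
  expect_lt(rms, 0.02)
})
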