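test_that("fixed-scheme population bookkeeping matches the stated fractions", {
  rf <- rates_fixed(pn_config())
  counts <- table(rf$class)
  expect_equal(unname(counts["excited"]), 166)
  expect_equal(unname(counts["inhibited"]), 64)
  expect_equal(sum(counts[c("excited", "inhibited", "spontaneous")]), 639)
})

test_that("fixed-scheme rate functions follow the odor structure", {
  cfg <- pn_config()
  rf <- rates_fixed(cfg)
  exc <- which(rf$class == "excited")[1]
  inh <- which(rf$class == "inhibited")[1]
  # outside the odor window the excited PN fires at the spontaneous rate
  expect_equal(pn_rate(rf, exc, c(0.1, 2.0)), c(2.6, 2.6))
  expect_equal(pn_rate(rf, inh, 0.8), 0)       # silenced during odor
  expect_true(all(pn_rate(rf, exc, seq(0.5, 1.5, by = 1e-3)) >= 0))
  # time-average of the modulated rate over whole LFP cycles
  tt <- seq(0.5, 1.5, by = 1e-4)
  avg <- mean(pn_rate(rf, exc, tt[-length(tt)]))
  expect_equal(avg, 20, tolerance = 0.01)
})

test_that("shifting scheme groups, recruitment and activity bound", {
  cfg <- pn_config(scheme = "shifting")
  rs <- rates_shifting(cfg, seed = 3)
  expect_setequal(setdiff(unique(rs$group), "unresponsive"),
                  c("EEI", "EIE", "IEI", "IIE"))
  gsz <- lengths(rs$members)
  expect_true(all(gsz == gsz[1]))
  expect_equal(mean(rs$group == "unresponsive"), 0.3, tolerance = 0.02)
  # activation fraction across the first four LFP cycles of an E epoch
  members <- rs$members[[1]]            # group EEI: epoch 1 excitatory
  for (cyc in 0:3) {
    t_probe <- 0.5 + cyc * 0.05 + 0.012   # mid-cycle, rate > 0 if active
    active <- vapply(members, function(i) pn_rate(rs, i, t_probe) > 0,
                     logical(1))
    expect_equal(mean(active), 0.7 + 0.1 * cyc, tolerance = 0.02)
  }
  # instantaneous excited fraction never exceeds ~35%
  for (t_probe in seq(0.51, 1.49, by = 0.11)) {
    frac <- mean(vapply(seq_len(cfg$n_pn), function(i)
      pn_rate(rs, i, t_probe) > cfg$spont_rate, logical(1)))
    expect_lte(frac, 0.35 + 1e-9)
  }
})

test_that("Poisson sampling is seeded, sorted and respects zero rates", {
  cfg <- pn_config()
  rf <- rates_fixed(cfg)
  s1 <- sample_poisson(rf, seed = 9, duration = 2)
  s2 <- sample_poisson(rf, seed = 9, duration = 2)
  expect_identical(s1$trains, s2$trains)
  silent <- which(rf$class == "silent")
  expect_true(all(lengths(s1$trains[silent]) == 0))
  expect_true(all(vapply(s1$trains, function(x) !is.unsorted(x),
                         logical(1))))
  expect_true(all(unlist(s1$trains) >= 0 & unlist(s1$trains) <= 2))
})

test_that("empirical rates and Fano factor match the Poisson model", {
  # spontaneous-only configuration: odor window outside the simulation
  cfg <- pn_config(n_pn = 200, frac_spontaneous = 1, frac_excited = 0,
                   frac_inhibited = 0, odor_window = c(900, 901))
  tr <- sample_poisson(rates_fixed(cfg), seed = 21, duration = 100)
  counts <- lengths(tr$trains)
  rate <- sum(counts) / (200 * 100)
  se <- sqrt(2.6 / (200 * 100))
  expect_lt(abs(rate - 2.6), 3 * se)
  # Fano factor of 1 s counts across trains pooled over disjoint windows
  bins <- unlist(lapply(tr$trains, function(s) tabulate(ceiling(s), 100)))
  expect_equal(var(bins) / mean(bins), 1, tolerance = 0.1)
})

test_that("odor-evoked population rate is modulated at the LFP frequency", {
  cfg <- pn_config(n_pn = 200, frac_excited = 1, frac_spontaneous = 1,
                   frac_inhibited = 0, odor_window = c(0, 1))
  rf <- rates_fixed(cfg)
  tr <- sample_poisson(rf, seed = 4, duration = 1)
  sp <- unlist(tr$trains)
  bin_s <- 0.005
  counts <- tabulate(ceiling(sp / bin_s), 200)
  spec <- rate_spectrum(counts, bin_s)
  band <- spec[spec$freq >= 5 & spec$freq <= 90, ]
  expect_equal(band$freq[which.max(band$power)], 20, tolerance = 1.01)
})
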