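bio_default <- biophysics()

test_that("an unstimulated model rests at the resting potential", {
  cm <- small_model()
  v <- steady_state(cm)
  expect_equal(v, rep(-51, length(v)), tolerance = 1e-10)
})

test_that("clamped cylinder matches the closed-form cable solution", {
  m <- make_cylinder(n = 101, L_um = 2000, d_um = 2)
  cm <- compartmentalize(m, bio_default, max_elec_len = 0.02)
  v <- steady_state(cm, stimulus_set(
    clamps = list(list(comp = 1, command = -40))))
  lam <- mbggn:::lambda_um(2, bio_default)
  x <- cm$pos[, 1]
  analytic <- -51 + 11 * cosh((2000 - x) / lam) / cosh(2000 / lam)
  idx <- round(seq(5, length(v), length.out = 10))
  expect_equal(v[idx], analytic[idx], tolerance = 0.01 * 11)
})

test_that("Hines solve equals a dense solve on small trees", {
  m <- generate_synthetic_ggn(seed = 3, total_length_um = 700,
                              max_path_um = 400, segment_um = 30)
  cs <- compartmentalize(m, bio_default)
  n <- length(cs$parent)
  expect_lte(n, 60)
  G <- matrix(0, n, n)
  for (i in 2:n) {
    p <- cs$parent[i]
    G[i, p] <- G[p, i] <- -cs$g_ax[i]
    G[i, i] <- G[i, i] + cs$g_ax[i]
    G[p, p] <- G[p, p] + cs$g_ax[i]
  }
  diag(G) <- diag(G) + cs$g_leak
  rhs <- cs$g_leak * -51
  rhs[n] <- rhs[n] + 0.1
  vd <- solve(G, rhs)
  vh <- steady_state(cs, stimulus_set(
    injections = list(list(comp = n, current = 0.1))))
  expect_equal(vh, vd, tolerance = 1e-9)
})

test_that("clamps are exact and passive transfer is reciprocal", {
  cm <- small_model()
  n <- length(cm$parent)
  v <- steady_state(cm, stimulus_set(
    clamps = list(list(comp = 5, command = -40))))
  expect_identical(v[5], -40)
  a <- 3L; b <- n - 2L
  vA <- steady_state(cm, stimulus_set(
    injections = list(list(comp = a, current = 0.2))))
  vB <- steady_state(cm, stimulus_set(
    injections = list(list(comp = b, current = 0.2))))
  expect_equal(vA[b] - -51, vB[a] - -51, tolerance = 1e-10)
  expect_error(stimulus_set(clamps = list(list(comp = 1, command = -40),
                                          list(comp = 1, command = -30))),
               "at most one clamp")
})

test_that("attenuation maps obey the passive maximum principle", {
  cm <- small_model()
  site <- region_entry_comp(cm, "ALPHA_LOBE")
  # command at rest: no deflection anywhere
  dv0 <- attenuation_map(cm, site, -51)
  expect_true(all(abs(unlist(dv0)) < 1e-10))
  dv <- attenuation_map(cm, site, -40)
  all_dv <- unlist(dv)
  expect_true(all(all_dv > 0))
  expect_true(all(all_dv <= 11 + 1e-9))
  # monotone decay with distance on an unbranched cable
  cyl <- compartmentalize(make_cylinder(n = 81, L_um = 3000, d_um = 1),
                          bio_default, 0.05)
  vc <- steady_state(cyl, stimulus_set(
    clamps = list(list(comp = 2, command = -40))))
  expect_true(all(diff(vc[-1]) <= 1e-12))
})

test_that("transient integration matches RC charging and steady state", {
  # single compartment: cylinder collapses to one comp + root
  m <- make_cylinder(n = 2, L_um = 40, d_um = 10)
  cm <- compartmentalize(m, bio_default)
  tr <- cable_transient(cm, stimulus_set(
    injections = list(list(comp = 1, current = 0.05))),
    dt = 0.1, duration = 200, record = 1:2)
  tau <- bio_default$RM * bio_default$Cm   # ms
  R_tot <- 1 / sum(cm$g_leak)              # MOhm-scale (uS^-1)
  # both comps are strongly coupled; lump them for the closed form
  analytic <- -51 + 0.05 * R_tot * (1 - exp(-tr$t / tau))
  expect_equal(tr$v[, 1], analytic, tolerance = 0.01 * max(abs(analytic + 51)))
  # constant clamp run to ~10 tau converges on the steady state
  cms <- small_model()
  stim <- stimulus_set(clamps = list(list(
    comp = region_entry_comp(cms, "ALPHA_LOBE"), command = -40)))
  vss <- steady_state(cms, stim)
  rec <- c(1L, length(cms$parent))
  trs <- cable_transient(cms, stim, dt = 0.5, duration = 10 * tau,
                         record = rec)
  expect_equal(tail(trs$v, 1)[1, ], vss[rec], tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("cable transient detects divergence and bad input", {
  cm <- small_model()
  expect_error(cable_transient(cm, dt = -1), "positive")
  expect_error(cable_transient(cm, record = 10^6), "not in model")
})
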