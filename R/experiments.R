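# Scripted, seeded reproductions of the simulation experiments: passive
# signal attenuation, distributed synaptic drive, resistivity sweeps, the
# single-KC dynamic-range loop, full-network heterogeneity conditions,
# iterative ablation of high-spike-rate KCs, and the IG wiring variants.

#' Voltage-clamp attenuation experiment
#'
#' Clamps the stem of the alpha-lobe branch (from the -51 mV holding
#' potential to the command, -40 mV by default) and reports the
#' steady-state depolarization of terminal compartments grouped by
#' region. With the default biophysics, alpha-lobe signals attenuate to
#' a few millivolts in the calyces but remain strong enough to support
#' graded transmission.
#'
#' @param model `compartmental_model` of a labeled GGN.
#' @param command clamp command, mV.
#' @param clamp_site clamped compartment (default: first alpha-lobe
#'   compartment on the path from the root).
#' @return list with `dv` (per-region depolarizations, mV),
#'   `clamp_site`, `command`.
#' @export
exp_clamp_attenuation <- function(model, command = -40,
                                  clamp_site = NULL) {
  if (is.null(clamp_site))
    clamp_site <- region_entry_comp(model, "ALPHA_LOBE")
  dv <- attenuation_map(model, clamp_site, command)
  list(dv = dv, clamp_site = clamp_site, command = command)
}

# ramping nonhomogeneous Poisson train: rate r0 -> 0 over ramp_ms
ramp_poisson <- function(r0, ramp_ms) {
  # thinning against the initial rate
  cand <- sort(runif(rpois(1, r0 * ramp_ms / 1000), 0, ramp_ms))
  cand[runif(length(cand)) < (1 - cand / ramp_ms)]
}

#' Distributed synaptic input experiment
#'
#' Drives `n_syn` excitatory synapses at random alpha-lobe compartments
#' with independent Poisson trains whose rate decreases linearly from 20
#' to 0 spikes/s over 500 ms, and records terminal-compartment voltages
#' throughout the tree. Reports the peak depolarization and peak time
#' per region: calyceal peaks are both smaller and later than alpha-lobe
#' peaks.
#'
#' @param model `compartmental_model`.
#' @param n_syn number of synapses.
#' @param weight synaptic peak conductance, uS.
#' @param seed integer seed.
#' @param dt time step, ms.
#' @param duration simulated time, ms.
#' @param rate0 initial per-synapse rate, spikes/s.
#' @param ramp_ms rate ramp duration, ms.
#' @param max_per_region recorded terminal compartments per region.
#' @return list with per-region `peak_dv` (mV) and `peak_t` (ms),
#'   region-mean depolarization traces (`mean_dv`), the time each
#'   region-mean trace first crosses half its peak (`rise_t`, ms), the
#'   recorded traces and their compartments.
#' @export
exp_distributed_input <- function(model, n_syn = 500, weight = 5e-4,
                                  seed = 1, dt = 0.1, duration = 1000,
                                  rate0 = 20, ramp_ms = 500,
                                  max_per_region = 30) {
  alpha <- which(model$region == "ALPHA_LOBE")
  if (!length(alpha)) stop("model has no alpha-lobe compartments")
  n_steps <- as.integer(ceiling(duration / dt))
  ev <- with_seed(seed, {
    syn_comp <- sample(alpha, n_syn, replace = TRUE)
    step_list <- lapply(seq_len(n_syn), function(s)
      as.integer(round(ramp_poisson(rate0, ramp_ms) / dt)))
    list(step = unlist(step_list),
         comp = rep(syn_comp, lengths(step_list)))
  })
  ord <- order(ev$step)
  # recorded terminals, a few per region
  term <- which(model$terminal)
  rec <- unlist(lapply(split(term, model$region[term]),
                       function(ix) head(ix, max_per_region)))
  res <- engine_run_cpp(
    cable = list(parent = model$parent, g_ax = model$g_ax,
                 g_leak = model$g_leak, C = model$C,
                 E_rest = model$bio$E_rest, frozen = FALSE),
    kcs = list(n_kc = 0L, params = numeric(0), v0 = -70, exc_tau_r = 1,
               exc_tau_d = 5, e_exc = 0, graded_gbar = numeric(0),
               graded_assign = integer(0), graded_vhalf = -45,
               graded_slope = 3, graded_tau = 4, graded_erev = -80,
               i_amp = numeric(0), i_on_step = 0L, i_off_step = 0L),
    pn = list(ev_step = integer(0), ev_kc = integer(0),
              ev_w = numeric(0)),
    kc_ggn = list(mode = 2L, target = integer(0), w = numeric(0),
                  delay_steps = integer(0), tau_r = 1, tau_d = 5,
                  e_rev = 0, kernel = numeric(0)),
    ext = list(ev_step = ev$step[ord], ev_comp = ev$comp[ord],
               ev_w = rep(weight, length(ord)), tau_r = 1, tau_d = 5,
               e_rev = 0),
    ig = list(has = FALSE, a = 0, b = 0, c = 0, d = 0, i_base = 0,
              comp = 1L, ggn_ig_gbar = 0, e_ggn_ig = -80, ig_ggn_w = 0,
              ig_ggn_tau = 10, e_ig_ggn = -80, kc_ig_w = numeric(0),
              kc_ig_delay_steps = 0L, pn_ig_steps = integer(0),
              pn_ig_w = 0, syn_tau_r = 1, syn_tau_d = 5),
    control = list(dt = dt, n_steps = n_steps, record_every = 1L,
                   record_comps = rec, odor_on_step = 0L,
                   odor_off_step = 0L, kc_record = integer(0)))
  dv <- sweep(res$ggn_v, 2, model$bio$E_rest)
  peak_i <- apply(dv, 2, which.max)
  peak <- dv[cbind(peak_i, seq_along(rec))]
  reg <- model$region[rec]
  # region-mean traces and the time each crosses half its own peak:
  # a robust readout of propagation delay into distal regions
  regions <- unique(reg)
  mean_dv <- vapply(regions, function(r)
    rowMeans(dv[, reg == r, drop = FALSE]), numeric(nrow(dv)))
  colnames(mean_dv) <- regions
  rise_t <- vapply(regions, function(r) {
    tr <- mean_dv[, r]
    if (max(tr) <= 0) return(NA_real_)
    res$t[which(tr >= max(tr) / 2)[1]]
  }, numeric(1))
  list(peak_dv = split(peak, reg),
       peak_t = split(res$t[peak_i], reg),
       mean_dv = mean_dv, rise_t = rise_t,
       t = res$t, dv = dv, comps = rec)
}

#' Membrane/axial resistivity sweep
#'
#' Repeats the voltage-clamp attenuation experiment over a grid of RA
#' and RM values, reporting the median calyceal terminal depolarization
#' at each grid point. Median attenuation worsens (smaller
#' depolarization) as RA grows and improves as RM grows.
#'
#' @param morph labeled [morphology].
#' @param ra_values axial resistivities, Ohm cm.
#' @param rm_values membrane resistivities, kOhm cm^2.
#' @param command clamp command, mV.
#' @param max_elec_len compartment rule (fraction of lambda).
#' @return list with `median_dv` matrix (RA x RM, mV) plus the grids.
#' @export
exp_rm_ra_sweep <- function(morph, ra_values = c(30, 100, 300),
                            rm_values = c(11, 33, 100), command = -40,
                            max_elec_len = 0.1) {
  med <- matrix(NA_real_, length(ra_values), length(rm_values),
                dimnames = list(RA = ra_values, RM = rm_values))
  for (i in seq_along(ra_values)) {
    for (j in seq_along(rm_values)) {
      bio <- biophysics(RM = rm_values[j], RA = ra_values[i])
      model <- compartmentalize(morph, bio, max_elec_len)
      dv <- exp_clamp_attenuation(model, command)$dv
      med[i, j] <- median(c(dv$CALYX_LATERAL, dv$CALYX_MEDIAL))
    }
  }
  list(median_dv = med, ra_values = ra_values, rm_values = rm_values)
}

#' Single-KC dynamic-range experiment
#'
#' Drives one KC with step currents (0.5-3 s) of increasing amplitude in
#' three configurations: isolated; with tonic graded inhibition from a
#' resting GGN ("spontaneous inhibition", loop cut); and in a closed
#' loop in which every KC spike reaches GGN's alpha-lobe branch through
#' 50,000 equivalent excitatory synapses with delays spread uniformly
#' over 0-60 ms, and graded feedback returns from a calyceal
#' compartment. Feedback inhibition raises the spiking threshold,
#' extends spiking over a wider current range, and flattens the rising
#' branch of the input-response curve.
#'
#' @param model `compartmental_model` of the GGN (closed loop only).
#' @param amplitudes step-current amplitudes, nA (increasing).
#' @param configs subset of `c("isolated", "spontaneous_inhibition",
#'   "closed_loop")`.
#' @param graded graded GGN->KC synapse for this experiment; the
#'   default places half-activation at -45 mV with a 3 mV slope so the
#'   resting GGN (-51 mV) releases a tonic baseline conductance, the
#'   baseline inhibition that raises the KC's spiking threshold.
#' @param n_syn,delay_range equivalent-synapse aggregation of the
#'   KC->GGN projection.
#' @param unit_w unit KC->GGN synapse peak conductance, uS.
#' @param step_window `c(on, off)` of the current step, ms.
#' @param duration simulated time, ms.
#' @param dt time step, ms.
#' @return list with `amplitudes`, `counts` (config x amplitude spike
#'   counts), and `slopes` (normalized rising-branch slopes).
#' @export
exp_kc_dynamic_range <- function(model = NULL,
                                 amplitudes = c(0.05, 0.1, 0.15, 0.2,
                                                0.25, 0.3, 0.4, 0.5,
                                                0.7, 1.0, 1.3, 1.6),
                                 configs = c("isolated",
                                             "spontaneous_inhibition",
                                             "closed_loop"),
                                 graded = graded_synapse(
                                   gbar = 0.05, V_half = -45, slope = 3),
                                 n_syn = 50000,
                                 delay_range = c(0, 60), unit_w = 1e-5,
                                 step_window = c(500, 3000),
                                 duration = 3200, dt = 0.025) {
  stopifnot(!is.unsorted(amplitudes))
  kcp <- kc_params()
  gs <- graded
  counts <- matrix(0L, length(configs), length(amplitudes),
                   dimnames = list(configs, NULL))
  count_in_window <- function(sp)
    sum(sp >= step_window[1] & sp < step_window[2])
  step_fun <- function(amp) function(t)
    ifelse(t >= step_window[1] & t < step_window[2], amp, 0)
  tonic_g <- gs$gbar * graded_sinf(-51, gs)
  for (ci in seq_along(configs)) {
    cfg <- configs[ci]
    for (ai in seq_along(amplitudes)) {
      amp <- amplitudes[ai]
      if (cfg == "isolated") {
        sim <- simulate_kc(kcp, dt, duration, current = step_fun(amp))
        counts[ci, ai] <- count_in_window(sim$spikes)
      } else if (cfg == "spontaneous_inhibition") {
        sim <- simulate_kc(kcp, dt, duration, current = step_fun(amp),
                           g_inh = tonic_g, E_inh = gs$E_rev)
        counts[ci, ai] <- count_in_window(sim$spikes)
      } else {
        if (is.null(model))
          stop("closed_loop configuration needs a GGN model")
        sim <- run_single_kc_loop(model, kcp, gs, amp, step_window,
                                  duration, dt, n_syn, delay_range,
                                  unit_w)
        counts[ci, ai] <- count_in_window(sim$kc_spikes)
      }
    }
  }
  iso <- if ("isolated" %in% configs)
    dynamic_range_slope(amplitudes, counts["isolated", ])$slope
  else NULL
  slopes <- lapply(setNames(configs, configs), function(cfg) {
    tryCatch(dynamic_range_slope(amplitudes, counts[cfg, ],
                                 ref_slope = iso)$normalized,
             error = function(e) NA_real_)
  })
  list(amplitudes = amplitudes, counts = counts, slopes = slopes)
}

# one KC coupled to the GGN cable through the equivalent aggregate
# kernel, with graded feedback from a calyceal compartment
run_single_kc_loop <- function(model, kcp, gs, amp, step_window,
                               duration, dt, n_syn, delay_range,
                               unit_w) {
  agg <- equivalent_synapse(n_syn, delay_range,
                            spike_synapse(weight = unit_w, E_rev = 0))
  kernel <- aggregate_kernel_trace(agg, dt)
  target <- region_entry_comp(model, "ALPHA_LOBE")
  calyx <- which(model$region %in% c("CALYX_LATERAL", "CALYX_MEDIAL"))
  assign_comp <- calyx[ceiling(length(calyx) / 2)]
  n_steps <- as.integer(ceiling(duration / dt))
  res <- engine_run_cpp(
    cable = list(parent = model$parent, g_ax = model$g_ax,
                 g_leak = model$g_leak, C = model$C,
                 E_rest = model$bio$E_rest, frozen = FALSE),
    kcs = list(n_kc = 1L, params = unclass(kcp), v0 = -70,
               exc_tau_r = 1, exc_tau_d = 5, e_exc = 0,
               graded_gbar = gs$gbar, graded_assign = assign_comp,
               graded_vhalf = gs$V_half, graded_slope = gs$slope,
               graded_tau = gs$tau, graded_erev = gs$E_rev,
               i_amp = amp,
               i_on_step = as.integer(round(step_window[1] / dt)),
               i_off_step = as.integer(round(step_window[2] / dt))),
    pn = list(ev_step = integer(0), ev_kc = integer(0),
              ev_w = numeric(0)),
    kc_ggn = list(mode = 1L, target = target, w = 1,
                  delay_steps = 0L, tau_r = 1, tau_d = 5, e_rev = 0,
                  kernel = kernel),
    ext = empty_ext(),
    ig = list(has = FALSE, a = 0, b = 0, c = 0, d = 0, i_base = 0,
              comp = 1L, ggn_ig_gbar = 0, e_ggn_ig = -80, ig_ggn_w = 0,
              ig_ggn_tau = 10, e_ig_ggn = -80, kc_ig_w = numeric(0),
              kc_ig_delay_steps = 0L, pn_ig_steps = integer(0),
              pn_ig_w = 0, syn_tau_r = 1, syn_tau_d = 5),
    control = list(dt = dt, n_steps = n_steps, record_every = 40L,
                   record_comps = c(target, assign_comp),
                   odor_on_step = 0L, odor_off_step = 0L,
                   kc_record = 1L))
  list(kc_spikes = res$kc_spike_t, t = res$t, ggn_v = res$ggn_v,
       kc_v = res$kc_v[, 1])
}

#' Full-network heterogeneity experiment
#'
#' Runs one cell of the weight-scheme x PN-scheme design (with an
#' optional PN->KC delay-diversity control) and summarizes the GGN
#' response and KC population activity: sustainedness index of the
#' low-pass-filtered GGN trace, KC synchrony index (largest 50 ms-bin
#' share of odor-window spikes), spiking-KC fraction, and the per-KC
#' spike-count histogram over the odor + off windows.
#'
#' @param model `compartmental_model` of the GGN.
#' @param weight_scheme `"homogeneous"` or `"lognormal"`.
#' @param pn_scheme `"fixed"` or `"shifting"`.
#' @param seed integer seed.
#' @param n_kc number of KCs (conductance-scaled to the full 50,000).
#' @param delay_diversity add normal(7.5, 3) ms PN->KC delays.
#' @param config optional pre-built [network_config()] overriding the
#'   scheme arguments except weights/delays.
#' @param pn optional [pn_config()] (scheme field is overridden).
#' @return list with the `simulation_result` and `metrics`.
#' @export
exp_full_network <- function(model, weight_scheme = "lognormal",
                             pn_scheme = "shifting", seed = 1,
                             n_kc = 5000, delay_diversity = FALSE,
                             config = NULL, pn = NULL) {
  family <- if (weight_scheme == "homogeneous") "uniform-constant"
  else "lognormal"
  if (is.null(config))
    config <- network_config(n_kc = n_kc, weight_family = family,
                             pn_kc_delay = if (delay_diversity)
                               c(7.5, 3) else NULL)
  if (is.null(pn)) pn <- pn_config(scheme = pn_scheme)
  pn$scheme <- pn_scheme
  rates <- if (pn_scheme == "fixed") rates_fixed(pn) else
    rates_shifting(pn, seed = seed)
  trains <- sample_poisson(rates, seed = seed + 1,
                           duration = pn$odor_window[2] +
                             pn$off_epoch + 0.2)
  network <- build_network(config, model, n_pn = pn$n_pn,
                           seed = seed + 2)
  res <- run_network(network, trains)
  list(result = res, network = network, trains = trains,
       metrics = network_metrics(res))
}

#' Summary metrics of a network simulation
#'
#' @param res `simulation_result` from [run_network()].
#' @return list with `sustainedness`, `synchrony`, `spiking_fraction`,
#'   `spike_counts` (per KC, odor + off windows), `total_spikes`.
#' @export
network_metrics <- function(res) {
  pcfg <- res$config$pn
  odor_ms <- pcfg$odor_window * 1000
  resp_ms <- c(odor_ms[1], odor_ms[2] + pcfg$off_epoch * 1000)
  vf <- lowpass_trace(res$ggn$Vm, res$t[2] - res$t[1])
  sus <- sustainedness_index(res$t, vf, odor_ms)
  sp <- res$kc$spikes
  in_resp <- sp$t >= resp_ms[1] & sp$t < resp_ms[2]
  counts <- tabulate(sp$kc[in_resp], nbins = res$kc$n_kc)
  in_odor <- sp$t >= odor_ms[1] & sp$t < odor_ms[2]
  syn_idx <- if (any(in_odor)) {
    ps <- population_psth(data.frame(t = sp$t[in_odor]), bin = 50,
                          t_range = odor_ms)
    max(ps$counts) / sum(ps$counts)
  } else NA_real_
  list(sustainedness = sus, synchrony = syn_idx,
       spiking_fraction = mean(counts > 0), spike_counts = counts,
       total_spikes = sum(counts))
}

#' Iterative ablation of high-spike-rate KCs
#'
#' Repeatedly disconnects KCs whose odor-elicited spike count (odor +
#' off windows) exceeds the current limit, re-runs the otherwise
#' identical simulation, and iterates until no KC exceeds the limit;
#' the limit then tightens through the given stages (more than five
#' spikes; three or more; any spikes). Replacement high-rate KCs emerge
#' each round but in smaller numbers; total KC spiking decreases
#' monotonically until neither KC spikes nor a GGN response remains.
#'
#' @param network [build_network()] result.
#' @param pn_trains PN spike trains (held fixed across iterations).
#' @param stages list of predicates on spike counts defining removal,
#'   in order of application.
#' @param max_iter safety cap on total iterations.
#' @return list of per-iteration records (`stage`, `removed`,
#'   `total_spikes`, `hist`, `psth`, `ggn_vm`, `t`) plus the final
#'   network.
#' @export
exp_ablation_loop <- function(network, pn_trains,
                              stages = list(
                                function(n) n > 5,
                                function(n) n >= 3,
                                function(n) n >= 1),
                              max_iter = 60) {
  pcfg <- pn_trains$config
  resp_ms <- c(pcfg$odor_window[1],
               pcfg$odor_window[2] + pcfg$off_epoch) * 1000
  removed_ever <- logical(network$config$n_kc)
  iterations <- list()
  it <- 0L
  for (si in seq_along(stages)) {
    pred <- stages[[si]]
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("ablation loop exceeded max_iter")
      res <- run_network(network, pn_trains)
      sp <- res$kc$spikes
      in_resp <- sp$t >= resp_ms[1] & sp$t < resp_ms[2]
      counts <- tabulate(sp$kc[in_resp], nbins = network$config$n_kc)
      over <- which(pred(counts) & !removed_ever)
      psth <- population_psth(data.frame(t = sp$t), bin = 100,
                              t_range = c(0, max(res$t)))
      iterations[[it]] <- list(stage = si, removed = over,
                               n_removed = length(over),
                               total_spikes = sum(counts),
                               hist = counts, psth = psth,
                               ggn_vm = res$ggn$Vm, t = res$t)
      if (!length(over)) break
      removed_ever[over] <- TRUE
      network$pn_w[, over] <- 0
      network$kc_ggn_w[over] <- 0
      network$ggn_kc_gbar[over] <- 0
    }
  }
  list(iterations = iterations, network = network,
       removed = which(removed_ever))
}

# Odor-elicited hyperpolarization: the 100 ms-smoothed, low-passed
# trace must stay at least `depth` mV below the pre-odor mean for
# `min_ms`, AND dip below anything seen during the pre-odor period
# (so a tonic barrage of spontaneous IPSPs does not count).
has_hyperpolarization <- function(t, v, window, depth = 1,
                                  min_ms = 100) {
  dt <- t[2] - t[1]
  vf <- lowpass_trace(v, dt)
  k <- max(1L, round(100 / dt))
  ma <- as.numeric(stats::filter(vf, rep(1 / k, k), sides = 2))
  ma[is.na(ma)] <- vf[is.na(ma)]
  pre <- t < window[1]
  base <- mean(ma[pre])
  floor_pre <- min(ma[pre])
  thr <- min(base - depth, floor_pre - 0.25)
  sel <- t >= window[1] & t < window[2]
  below <- ma[sel] < thr
  if (!any(below)) return(FALSE)
  r <- rle(below)
  any(r$values & r$lengths * dt >= min_ms)
}

#' IG wiring-variant experiment
#'
#' Tests which IG wiring can generate odor-elicited hyperpolarization in
#' GGN: a sweep over reciprocal-only configurations (GGN<->IG strengths,
#' IPSP time constants, IG baseline rates), the variant adding direct
#' KC->IG excitation with a 200 ms delay and lognormal weights, and the
#' variant adding PN->IG excitation. For each run the GGN trace at the
#' recording site is scanned for hyperpolarization (>= 1 mV below
#' baseline for >= 100 ms, after 49 Hz low-pass) during the odor + off
#' window, and IPSPs are detected to infer IG activity.
#'
#' @param model `compartmental_model`.
#' @param seed integer seed.
#' @param n_kc KCs for these runs.
#' @param variants subset of `c("reciprocal", "reciprocal+KC_drive",
#'   "reciprocal+PN_drive")`.
#' @param sweep reciprocal-only grid: `strength` (multipliers on both
#'   graded GGN->IG and IG->GGN conductances), `tau` (IG->GGN decay,
#'   ms), `baseline` (IG spontaneous rates, spikes/s).
#' @param pn optional [pn_config()].
#' @param ig_overrides named list merged into the IG wiring parameters.
#' @return list with `runs` (per-run metrics) and `summary`.
#' @export
exp_ig_variants <- function(model, seed = 1, n_kc = 1000,
                            variants = c("reciprocal",
                                         "reciprocal+KC_drive",
                                         "reciprocal+PN_drive"),
                            sweep = list(strength = c(0.5, 1, 4),
                                         tau = c(10, 100),
                                         baseline = c(3, 7, 15)),
                            pn = NULL, ig_overrides = list()) {
  if (is.null(pn)) pn <- pn_config(scheme = "shifting")
  duration_ms <- (pn$odor_window[2] + pn$off_epoch) * 1000 + 500
  rates <- rates_shifting(pn, seed = seed)
  trains <- sample_poisson(rates, seed = seed + 1,
                           duration = duration_ms / 1000)
  odor_ms <- pn$odor_window * 1000
  # hyperpolarization is scanned from odor onset to the end of the run:
  # with the 200 ms KC->IG delay it typically follows stimulus offset
  window <- c(odor_ms[1], duration_ms)
  ip <- ig_params()
  runs <- list()
  run_one <- function(variant, ig_par) {
    cfg <- network_config(n_kc = n_kc, ig_variant = variant,
                          ig = utils::modifyList(ig_par, ig_overrides))
    network <- build_network(cfg, model, n_pn = pn$n_pn,
                             seed = seed + 2)
    res <- run_network(network, trains, duration = duration_ms)
    dt <- res$t[2] - res$t[1]
    vf <- lowpass_trace(res$ggn$Vm, dt)
    baseline <- mean(vf[res$t < odor_ms[1]])
    ipsps <- detect_ipsps(res$t, res$ggn$Vm)
    pre_rate <- sum(ipsps < odor_ms[1]) / (odor_ms[1] / 1000)
    odor_rate <- sum(ipsps >= window[1] & ipsps < window[2]) /
      (diff(window) / 1000)
    list(variant = variant, ig = ig_par,
         hyperpolarized = has_hyperpolarization(res$t, res$ggn$Vm,
                                                window),
         ipsp_pre_rate = pre_rate, ipsp_odor_rate = odor_rate,
         ig_spikes = res$ig$spikes, t = res$t, ggn_vm = res$ggn$Vm,
         baseline = baseline)
  }
  if ("reciprocal" %in% variants) {
    base_cur <- vapply(sweep$baseline, function(r)
      calibrate_ig_current(ip, target_rate = r, tol = 0.5),
      numeric(1))
    for (s in sweep$strength) for (tau in sweep$tau)
      for (bi in seq_along(sweep$baseline)) {
        ig_par <- list(ggn_ig_gbar = 5e-3 * s, ig_ggn_w = 0.03 * s,
                       ig_ggn_tau = tau, i_base = base_cur[bi])
        runs[[length(runs) + 1L]] <- run_one("reciprocal", ig_par)
      }
  }
  ibase7 <- calibrate_ig_current(ip, target_rate = 7, tol = 0.5)
  for (v in setdiff(variants, "reciprocal"))
    runs[[length(runs) + 1L]] <- run_one(v, list(i_base = ibase7))
  hyp <- vapply(runs, `[[`, logical(1), "hyperpolarized")
  var_of <- vapply(runs, `[[`, character(1), "variant")
  list(runs = runs,
       summary = list(
         any_reciprocal_hyperpolarized = any(hyp[var_of == "reciprocal"]),
         kc_drive_hyperpolarized =
           if ("reciprocal+KC_drive" %in% var_of)
             any(hyp[var_of == "reciprocal+KC_drive"]) else NA,
         pn_drive_hyperpolarized =
           if ("reciprocal+PN_drive" %in% var_of)
             any(hyp[var_of == "reciprocal+PN_drive"]) else NA))
}
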