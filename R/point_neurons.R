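# Point-neuron models: the Hodgkin-Huxley-type Kenyon cell and the
# Izhikevich regular-spiking neuron used for IG, plus calibration
# utilities.

#' Kenyon-cell model parameters
#'
#' Single-compartment Hodgkin-Huxley-type model with five voltage-gated
#' currents: fast Na, slow Na, delayed-rectifier K, transient A-type K,
#' and a slow transient outward K current, alongside a passive leak with
#' -70 mV reversal. All constants live in this one function so an
#' alternative channel set can be substituted wholesale. Kinetics use
#' Boltzmann steady states and bell-shaped voltage-dependent time
#' constants; the constants below were tuned for the qualitative KC
#' phenotype: rest near -70 mV, no spontaneous spiking, spiking only to
#' strong synchronized input, and a non-monotone f-I curve that collapses
#' into depolarization block at high drive.
#'
#' @param C_nF membrane capacitance, nF.
#' @param g_leak_uS leak conductance, uS.
#' @param E_leak leak reversal, mV.
#' @param E_Na,E_K ionic reversals, mV.
#' @param g_naf,g_nas,g_kdr,g_ka,g_kst maximal conductances, uS.
#' @param kinetics 9x6 matrix of gate constants (rows: naf_m, naf_h,
#'   nas_m, nas_h, kdr_n, ka_m, ka_h, kst_m, kst_h; columns: vh, slope,
#'   tau_base, tau_amp, tau_vh, tau_sig).
#' @return numeric parameter vector of class `kc_params` in the layout
#'   expected by the compiled model.
#' @export
kc_params <- function(C_nF = 0.01, g_leak_uS = 0.00125, E_leak = -70,
                      E_Na = 58, E_K = -81,
                      g_naf = 1.2, g_nas = 0.15, g_kdr = 0.5,
                      g_ka = 0.08, g_kst = 0.04,
                      kinetics = NULL) {
  if (is.null(kinetics)) {
    kinetics <- rbind(
      naf_m = c(-33.0,  4.5, 0.08, 0.30, -35, 15),
      naf_h = c(-50.0, -4.0, 0.40, 3.00, -45, 12),
      nas_m = c(-35.0,  6.0, 0.30, 1.00, -35, 15),
      nas_h = c(-52.0, -7.0, 2.00, 30.0, -45, 12),
      kdr_n = c(-30.0,  8.0, 0.50, 2.50, -30, 20),
      ka_m  = c(-48.0, 10.0, 0.20, 1.00, -40, 20),
      ka_h  = c(-58.0, -4.0, 30.0, 10.0, -50, 15),
      kst_m = c(-45.0, 10.0, 1.50, 4.00, -40, 20),
      kst_h = c(-62.0, -8.0, 50.0, 200., -50, 20))
  }
  stopifnot(nrow(kinetics) == 9L, ncol(kinetics) == 6L)
  g <- c(g_naf, g_nas, g_kdr, g_ka, g_kst)
  if (any(g < 0)) stop("maximal conductances must be >= 0")
  if (!(E_K < E_leak && E_leak < E_Na))
    stop("reversals must satisfy E_K < E_leak < E_Na")
  p <- c(C_nF, g_leak_uS, E_leak, E_Na, E_K, g, as.numeric(t(kinetics)))
  structure(p, class = "kc_params")
}

as_wave <- function(w, dt, n_steps) {
  if (is.null(w)) return(numeric(0))
  if (is.function(w)) return(w((seq_len(n_steps) - 1) * dt))
  if (length(w) == 1L) return(rep(as.numeric(w), n_steps))
  if (length(w) < n_steps)
    stop("waveform shorter than the simulation")
  as.numeric(w[seq_len(n_steps)])
}

#' Simulate a single Kenyon cell
#'
#' Exponential-Euler gating with implicit-Euler voltage update. Spikes
#' are upward 0 mV crossings with a 2 ms detection refractory. The
#' simulation is deterministic.
#'
#' @param params [kc_params()].
#' @param dt time step, ms (must be <= 0.025 for accuracy).
#' @param duration simulated time, ms.
#' @param current injected current: constant (nA), vector, or function
#'   of time (ms).
#' @param g_exc,g_inh synaptic conductance waveforms (uS), same forms.
#' @param E_exc,E_inh synaptic reversals, mV.
#' @param v0 initial voltage (default leak reversal).
#' @return list with `t`, `v` (mV) and `spikes` (ms).
#' @export
simulate_kc <- function(params, dt = 0.025, duration = 1000,
                        current = NULL, g_exc = NULL, g_inh = NULL,
                        E_exc = 0, E_inh = -80, v0 = NULL) {
  if (dt > 0.025 + 1e-12)
    stop("dt must be <= 0.025 ms for the HH Kenyon-cell model")
  n_steps <- ceiling(duration / dt)
  res <- simulate_kc_cpp(unclass(params), dt, n_steps,
                         as_wave(current, dt, n_steps),
                         as_wave(g_exc, dt, n_steps), E_exc,
                         as_wave(g_inh, dt, n_steps), E_inh,
                         if (is.null(v0)) params[3] else v0)
  list(t = seq(0, by = dt, length.out = n_steps + 1L), v = res$v,
       spikes = res$spikes)
}

#' IG (Izhikevich regular-spiking) parameters
#'
#' Canonical regular-spiking constants (a = 0.02, b = 0.2, c = -65,
#' d = 8) plus a baseline injected current that sets the spontaneous
#' firing rate (about 7 spikes/s after [calibrate_ig_current()]).
#'
#' @param a,b,c,d Izhikevich parameters.
#' @param i_base baseline injected current (model units).
#' @return list of class `ig_params`.
#' @export
ig_params <- function(a = 0.02, b = 0.2, c = -65, d = 8, i_base = 0) {
  stopifnot(is.finite(c(a, b, c, d, i_base)))
  structure(list(a = a, b = b, c = c, d = d, i_base = i_base),
            class = "ig_params")
}

#' Simulate the IG neuron
#'
#' Standard two-variable Izhikevich update with conductance-based
#' synaptic currents added; a spike resets `v` to `c` and increments `u`
#' by `d`.
#'
#' @param params [ig_params()].
#' @param dt time step, ms (<= 0.1).
#' @param duration simulated time, ms.
#' @param current extra injected current (constant, vector or function).
#' @param g_exc,g_inh synaptic conductance waveforms (uS-scale model
#'   units).
#' @param E_exc,E_inh reversals, mV.
#' @param v0 initial voltage.
#' @return list with `t`, `v` and `spikes` (ms).
#' @export
simulate_ig <- function(params, dt = 0.1, duration = 1000, current = NULL,
                        g_exc = NULL, g_inh = NULL, E_exc = 0,
                        E_inh = -80, v0 = -65) {
  if (dt > 0.1 + 1e-12) stop("dt must be <= 0.1 ms for the IG model")
  n_steps <- ceiling(duration / dt)
  res <- simulate_ig_cpp(params$a, params$b, params$c, params$d,
                         params$i_base, dt, n_steps,
                         as_wave(current, dt, n_steps),
                         as_wave(g_exc, dt, n_steps), E_exc,
                         as_wave(g_inh, dt, n_steps), E_inh, v0)
  list(t = seq(0, by = dt, length.out = n_steps + 1L), v = res$v,
       spikes = res$spikes)
}

ig_rate <- function(params, current, sim_s = 10, dt = 0.1) {
  p <- params
  p$i_base <- current
  length(simulate_ig(p, dt = dt, duration = sim_s * 1000)$spikes) / sim_s
}

#' Calibrate IG baseline current for a target spontaneous rate
#'
#' Bisection on the injected current until the firing rate measured over
#' a 10 s simulation is within `tol` of `target_rate`. The firing rate
#' of the regular-spiking model is monotone in the injected current, so
#' bisection converges whenever the bracket spans the target.
#'
#' @param params [ig_params()].
#' @param target_rate desired spontaneous rate, spikes/s.
#' @param tol tolerance, spikes/s.
#' @param bracket current search interval.
#' @param sim_s simulation length per evaluation, s.
#' @return calibrated baseline current.
#' @export
calibrate_ig_current <- function(params, target_rate = 7, tol = 0.5,
                                 bracket = c(0, 30), sim_s = 10) {
  lo <- bracket[1]; hi <- bracket[2]
  r_lo <- ig_rate(params, lo, sim_s)
  r_hi <- ig_rate(params, hi, sim_s)
  if (r_lo > target_rate + tol || r_hi < target_rate - tol)
    stop("calibration bracket does not span the target rate")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    r <- ig_rate(params, mid, sim_s)
    if (abs(r - target_rate) <= tol) return(mid)
    if (r < target_rate) lo <- mid else hi <- mid
  }
  stop("IG calibration did not converge")
}
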