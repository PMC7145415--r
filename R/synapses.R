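# Synapse models: graded (voltage-dependent, spike-free) release as used
# by GGN's output synapses, spike-triggered double-exponential
# conductances, lognormal weight sampling, and aggregation of many
# delayed synapses into a single equivalent kernel.

#' Graded synapse parameters
#'
#' Defaults place half-activation at -40 mV with a 2 mV slope and a
#' -80 mV (GABAergic) reversal, so release engages steeply over the
#' -50...-40 mV span that graded transmission covers in non-spiking
#' interneurons. At the GGN resting potential of -51 mV the synapse
#' releases a small tonic conductance (a few percent of maximum),
#' implementing baseline inhibition from spontaneous activity in GGN
#' while leaving a large dynamic range for odor-evoked depolarization.
#'
#' @param gbar maximal conductance, uS.
#' @param E_rev reversal potential, mV.
#' @param V_half half-activation presynaptic voltage, mV.
#' @param slope activation slope, mV.
#' @param tau activation time constant, ms.
#' @return list of class `graded_synapse`.
#' @export
graded_synapse <- function(gbar = 1e-3, E_rev = -80, V_half = -40,
                           slope = 2, tau = 4) {
  if (gbar < 0 || slope <= 0 || tau <= 0)
    stop("gbar must be >= 0 and slope, tau > 0")
  structure(list(gbar = gbar, E_rev = E_rev, V_half = V_half,
                 slope = slope, tau = tau), class = "graded_synapse")
}

#' Steady-state activation of a graded synapse
#' @param V presynaptic voltage, mV.
#' @param params [graded_synapse].
#' @return activation in `[0, 1]`.
#' @export
graded_sinf <- function(V, params) {
  1 / (1 + exp((params$V_half - V) / params$slope))
}

#' Graded conductance released by a presynaptic voltage trace
#'
#' First-order activation `ds/dt = (s_inf(V_pre) - s) / tau` with
#' sigmoidal `s_inf`, integrated by exponential Euler; the released
#' conductance is `gbar * s`.
#'
#' @param V_pre presynaptic voltage trace, mV (uniform grid).
#' @param params [graded_synapse].
#' @param dt sample interval, ms.
#' @param s0 initial activation (default steady state at the first
#'   sample).
#' @return conductance trace (uS), same length as `V_pre`.
#' @export
graded_release <- function(V_pre, params, dt, s0 = NULL) {
  if (any(!is.finite(V_pre))) stop("V_pre must be finite")
  sinf <- graded_sinf(V_pre, params)
  a <- exp(-dt / params$tau)
  s <- numeric(length(V_pre))
  s[1] <- if (is.null(s0)) sinf[1] else s0
  for (i in seq_along(V_pre)[-1])
    s[i] <- sinf[i] + (s[i - 1] - sinf[i]) * a
  params$gbar * s
}

#' Spike-triggered synapse parameters
#'
#' @param weight peak conductance per spike, uS.
#' @param E_rev reversal potential, mV.
#' @param tau_rise,tau_decay kernel time constants, ms
#'   (`tau_decay > tau_rise > 0`).
#' @param delay axonal/synaptic delay, ms.
#' @return list of class `spike_synapse`.
#' @export
spike_synapse <- function(weight = 1e-3, E_rev = 0, tau_rise = 1,
                          tau_decay = 5, delay = 0) {
  if (!(tau_decay > tau_rise && tau_rise > 0))
    stop("need tau_decay > tau_rise > 0")
  if (delay < 0) stop("delay must be >= 0")
  structure(list(weight = weight, E_rev = E_rev, tau_rise = tau_rise,
                 tau_decay = tau_decay, delay = delay),
            class = "spike_synapse")
}

# peak-normalized double-exponential kernel evaluated at times t >= 0
dblexp_kernel <- function(t, tau_rise, tau_decay) {
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  norm <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  out <- (exp(-t / tau_decay) - exp(-t / tau_rise)) / norm
  out[t < 0] <- 0
  out
}

#' Conductance trace from a spike train
#'
#' Linear superposition of peak-normalized double-exponential kernels,
#' one per spike, each delayed by the synaptic delay and peaking at the
#' synaptic weight.
#'
#' @param spikes spike times, ms, within `[0, duration]`.
#' @param params [spike_synapse].
#' @param dt sample interval, ms.
#' @param duration trace duration, ms.
#' @return conductance trace (uS) on `seq(0, duration, by = dt)`.
#' @export
spike_conductance <- function(spikes, params, dt, duration) {
  t <- seq(0, duration, by = dt)
  g <- numeric(length(t))
  for (ts in spikes)
    g <- g + params$weight *
      dblexp_kernel(t - ts - params$delay, params$tau_rise,
                    params$tau_decay)
  g
}

#' Weight distribution specification
#'
#' @param family `"uniform-constant"` (all weights equal to `mean`) or
#'   `"lognormal"`. For the lognormal family the default standard
#'   deviation equals the mean, the heterogeneity used throughout the
#'   network model.
#' @param mean mean conductance, uS.
#' @param sd standard deviation on the natural scale, uS (lognormal
#'   only).
#' @return list of class `weight_spec`.
#' @export
weight_spec <- function(family = c("lognormal", "uniform-constant"),
                        mean, sd = mean) {
  family <- match.arg(family)
  if (mean <= 0) stop("mean must be positive")
  if (family == "lognormal" && sd <= 0) stop("sd must be positive")
  structure(list(family = family, mean = mean, sd = sd),
            class = "weight_spec")
}

#' Sample synaptic weights
#'
#' For the lognormal family the underlying normal parameters are solved
#' from the requested natural-scale mean and standard deviation:
#' `sigma^2 = log(1 + (sd/mean)^2)`, `mu = log(mean) - sigma^2 / 2`.
#'
#' @param spec [weight_spec].
#' @param n number of weights.
#' @param seed integer seed (sampling is deterministic given the seed).
#' @return numeric vector of `n` positive weights.
#' @export
sample_weights <- function(spec, n, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (spec$family == "uniform-constant") return(rep(spec$mean, n))
  sig2 <- log(1 + (spec$sd / spec$mean)^2)
  mu <- log(spec$mean) - sig2 / 2
  with_seed(seed, rlnorm(n, meanlog = mu, sdlog = sqrt(sig2)))
}

#' Collapse many delayed synapses into one equivalent kernel
#'
#' The expected summed conductance of `n_syn` identical unit synapses
#' whose delays are uniform on `delay_range` is the unit kernel convolved
#' with a boxcar over the delay range, scaled by `n_syn`. The returned
#' object produces that smeared aggregate conductance for a single
#' presynaptic spike, e.g. the 50,000 synapses with 0-60 ms delays that
#' couple one KC to the GGN alpha-lobe branch.
#'
#' @param n_syn number of collapsed synapses.
#' @param delay_range `c(min, max)` delay, ms.
#' @param unit_params [spike_synapse] describing one synapse.
#' @return list of class `aggregate_kernel` with fields `n_syn`,
#'   `delay_range`, `unit` and `E_rev`.
#' @export
equivalent_synapse <- function(n_syn, delay_range, unit_params) {
  if (n_syn < 1) stop("n_syn must be >= 1")
  if (length(delay_range) != 2 || diff(delay_range) < 0 ||
      any(delay_range < 0))
    stop("delay_range must be an increasing non-negative pair")
  structure(list(n_syn = n_syn, delay_range = delay_range,
                 unit = unit_params, E_rev = unit_params$E_rev),
            class = "aggregate_kernel")
}

#' Sample an aggregate kernel on a time grid
#'
#' @param agg [equivalent_synapse()] result.
#' @param dt sample interval, ms.
#' @param duration kernel support to evaluate, ms (default covers the
#'   delay window plus eight decay constants).
#' @return conductance trace (uS) for a single presynaptic spike at t=0.
#' @export
aggregate_kernel_trace <- function(agg, dt,
                                   duration = diff(range(
                                     c(0, agg$delay_range))) +
                                     agg$unit$delay +
                                     8 * agg$unit$tau_decay) {
  t <- seq(0, duration, by = dt)
  u <- agg$unit
  base <- u$weight * dblexp_kernel(t - u$delay, u$tau_rise, u$tau_decay)
  width <- diff(agg$delay_range)
  if (width == 0) return(agg$n_syn * shift_trace(base, agg$delay_range[1], dt))
  # convolve with a boxcar of the delay spread (area 1), then scale
  nbox <- max(1L, round(width / dt))
  box <- rep(1 / nbox, nbox)
  sm <- stats::convolve(base, rev(box), type = "open")[seq_along(t)]
  agg$n_syn * shift_trace(sm, agg$delay_range[1], dt)
}

shift_trace <- function(x, shift_ms, dt) {
  k <- round(shift_ms / dt)
  if (k == 0) return(x)
  c(numeric(k), x)[seq_along(x)]
}
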