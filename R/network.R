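# Assembly and co-simulation of the full mushroom-body circuit:
# PN spike drive -> KC population -> GGN cable -> graded feedback to the
# KCs, with the inhibitory neuron IG wired in optional variants.

#' Conduction-delay ceiling for a neurite path
#'
#' Upper bound on the synaptic delay implied by signal propagation along
#' a neurite of the given length at a conservative dendritic conduction
#' speed: 1,500 um of PN axon at 0.2 m/s (= 200 um/ms) bounds the
#' PN->KC delay at 7.5 ms, the mean of the delay-diversity option.
#'
#' @param distance_um path length, um.
#' @param speed_m_per_s conduction speed, m/s.
#' @return delay, ms.
#' @export
conduction_delay <- function(distance_um = 1500, speed_m_per_s = 0.2) {
  if (distance_um < 0 || speed_m_per_s <= 0)
    stop("need non-negative distance and positive speed")
  distance_um / (speed_m_per_s * 1000)
}

#' Network configuration
#'
#' Defaults define the desk-scale network: 5,000 KCs standing in for the
#' biological 50,000 with the KC->GGN conductances scaled by
#' `50,000 / n_kc` so the total excitatory drive onto GGN is preserved.
#' Each KC samples half of the PN population independently; synaptic
#' weights onto KCs (PN->KC and GGN->KC) are drawn from a lognormal
#' distribution with sd = mean in the heterogeneous configuration, or
#' held uniform in the homogeneous one.
#'
#' @param n_kc number of Kenyon cells.
#' @param n_kc_full population size the conductance scaling refers to.
#' @param pn_per_kc_fraction fraction of the PN population presynaptic
#'   to each KC.
#' @param weight_family `"lognormal"` or `"uniform-constant"`, applied
#'   to the PN->KC and GGN->KC weights.
#' @param pn_kc_weight mean PN->KC peak conductance, uS.
#' @param ggn_kc_gbar mean maximal graded GGN->KC conductance, uS.
#' @param kc_ggn_weight KC->GGN peak conductance per biological synapse,
#'   uS (multiplied by the population scaling).
#' @param pn_kc_delay `NULL` for no delay diversity, or `c(mean, sd)` in
#'   ms for normally distributed PN->KC delays (negatives truncated).
#' @param tau_rise,tau_decay excitatory kernel time constants, ms.
#' @param graded graded-synapse kinetics for GGN output
#'   ([graded_synapse()]; its `gbar` is ignored, `ggn_kc_gbar` rules).
#' @param kc Kenyon-cell parameters ([kc_params()]).
#' @param ig_variant `"absent"`, `"reciprocal"`,
#'   `"reciprocal+KC_drive"` or `"reciprocal+PN_drive"`.
#' @param ig IG wiring parameters: `ggn_ig_gbar` (graded GGN->IG, uS),
#'   `ig_ggn_w` / `ig_ggn_tau` (IG->GGN IPSP conductance and decay),
#'   `kc_ig_weight` (mean lognormal KC->IG weight), `kc_ig_delay` (ms),
#'   `pn_ig_weight`, `i_base` (baseline current; `NULL` to calibrate to
#'   `spont_rate`), `spont_rate` (spikes/s).
#' @return list of class `network_config`.
#' @export
network_config <- function(n_kc = 5000,
                           n_kc_full = 50000,
                           pn_per_kc_fraction = 0.5,
                           weight_family = "lognormal",
                           pn_kc_weight = 1.4e-4,
                           ggn_kc_gbar = 0.2,
                           kc_ggn_weight = 3e-4,
                           pn_kc_delay = NULL,
                           tau_rise = 1, tau_decay = 5,
                           graded = graded_synapse(),
                           kc = kc_params(),
                           ig_variant = "absent",
                           ig = list()) {
  if (n_kc < 1) stop("n_kc must be >= 1")
  if (pn_per_kc_fraction <= 0 || pn_per_kc_fraction > 1)
    stop("pn_per_kc_fraction must be in (0, 1]")
  ig_defaults <- list(ggn_ig_gbar = 5e-3, ig_ggn_w = 0.03,
                      ig_ggn_tau = 10, kc_ig_weight = 2e-4,
                      kc_ig_delay = 200, pn_ig_weight = 1.5e-3,
                      i_base = NULL, spont_rate = 7)
  ig <- utils::modifyList(ig_defaults, ig)
  variants <- c("absent", "reciprocal", "reciprocal+KC_drive",
                "reciprocal+PN_drive")
  if (!ig_variant %in% variants)
    stop("unknown ig_variant: ", ig_variant)
  structure(list(n_kc = as.integer(n_kc), n_kc_full = n_kc_full,
                 pn_per_kc_fraction = pn_per_kc_fraction,
                 weight_family = weight_family,
                 pn_kc_weight = pn_kc_weight,
                 ggn_kc_gbar = ggn_kc_gbar,
                 kc_ggn_weight = kc_ggn_weight,
                 pn_kc_delay = pn_kc_delay,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 graded = graded, kc = kc,
                 kc_scaling = n_kc_full / n_kc,
                 ig_variant = ig_variant, ig = ig),
            class = "network_config")
}

#' Build the mushroom-body network
#'
#' Wires the circuit onto a compartmentalized GGN model: each KC receives
#' an independent uniform sample of `round(fraction * n_pn)` PNs, sends
#' one excitatory synapse to a random alpha-lobe terminal compartment,
#' and receives one graded inhibitory synapse from a random calyceal
#' compartment. When IG is present it inhibits GGN at a basal
#' compartment (-80 mV reversal) and receives graded drive from the same
#' compartment, plus KC or PN excitation per variant.
#'
#' @param config [network_config()].
#' @param model `compartmental_model` of the GGN with non-empty
#'   `ALPHA_LOBE` and calyceal regions.
#' @param n_pn PN population size the wiring refers to.
#' @param seed integer seed.
#' @return object of class `mb_network`.
#' @export
build_network <- function(config, model, n_pn = 830, seed = 1) {
  alpha_term <- which(model$region == "ALPHA_LOBE" & model$terminal)
  calyx <- which(model$region %in% c("CALYX_LATERAL", "CALYX_MEDIAL"))
  basal <- which(model$region == "BASAL")
  if (!length(alpha_term) || !length(calyx))
    stop("GGN model must contain alpha-lobe terminals and calyceal ",
         "compartments")
  n_kc <- config$n_kc
  n_per <- round(config$pn_per_kc_fraction * n_pn)
  with_seed(seed, {
    pn_sets <- vapply(seq_len(n_kc),
                      function(k) sample.int(n_pn, n_per),
                      integer(n_per))
    w_spec <- weight_spec(config$weight_family, mean = config$pn_kc_weight)
    pn_w <- matrix(sample_weights(w_spec, n_per * n_kc,
                                  seed = sample.int(2^30, 1)),
                   n_per, n_kc)
    pn_delay <- if (is.null(config$pn_kc_delay)) NULL else
      matrix(pmax(0, rnorm(n_per * n_kc, config$pn_kc_delay[1],
                           config$pn_kc_delay[2])), n_per, n_kc)
    g_spec <- weight_spec(config$weight_family, mean = config$ggn_kc_gbar)
    ggn_kc_gbar <- sample_weights(g_spec, n_kc,
                                  seed = sample.int(2^30, 1))
    kc_ggn_target <- sample(alpha_term, n_kc, replace = TRUE)
    ggn_kc_assign <- sample(calyx, n_kc, replace = TRUE)
    ig_wiring <- NULL
    if (config$ig_variant != "absent") {
      comp <- if (length(basal)) basal[ceiling(length(basal) / 2)] else 1L
      # conductances scaled like KC->GGN so total drive onto IG matches
      # the full-size population
      kc_ig_w <- if (config$ig_variant == "reciprocal+KC_drive")
        sample_weights(weight_spec("lognormal",
                                   mean = config$ig$kc_ig_weight),
                       n_kc, seed = sample.int(2^30, 1)) *
          config$kc_scaling else numeric(0)
      ig_wiring <- list(comp = comp, kc_ig_w = kc_ig_w)
    }
    structure(list(config = config, model = model, n_pn = n_pn,
                   pn_sets = pn_sets, pn_w = pn_w, pn_delay = pn_delay,
                   ggn_kc_gbar = ggn_kc_gbar,
                   kc_ggn_target = kc_ggn_target,
                   kc_ggn_w = rep(config$kc_ggn_weight * config$kc_scaling,
                                  n_kc),
                   ggn_kc_assign = ggn_kc_assign,
                   ig_wiring = ig_wiring,
                   record_site = region_entry_comp(model, "ALPHA_LOBE"),
                   seed = seed),
              class = "mb_network")
  })
}

#' @export
print.mb_network <- function(x, ...) {
  cat(sprintf(paste0("mushroom-body network: %d KCs x %d PNs, %d GGN ",
                     "compartments, IG: %s\n"),
              x$config$n_kc, x$n_pn, length(x$model$parent),
              x$config$ig_variant))
  invisible(x)
}

# PN->KC arrival events for the engine: step-sorted (step, kc, weight)
pn_arrival_events <- function(network, pn_trains, dt, n_steps) {
  n_per <- nrow(network$pn_sets)
  n_kc <- ncol(network$pn_sets)
  edge_pn <- as.vector(network$pn_sets)
  edge_kc <- rep(seq_len(n_kc), each = n_per)
  edge_w <- as.vector(network$pn_w)
  edge_d <- if (is.null(network$pn_delay)) NULL else
    as.integer(round(as.vector(network$pn_delay) / dt))
  ord <- order(edge_pn)
  edge_pn <- edge_pn[ord]; edge_kc <- edge_kc[ord]; edge_w <- edge_w[ord]
  if (!is.null(edge_d)) edge_d <- edge_d[ord]
  # CSR offsets per PN
  counts <- tabulate(edge_pn, nbins = network$n_pn)
  offs <- c(0L, cumsum(counts))
  steps_list <- list(); kc_list <- list(); w_list <- list()
  j <- 0L
  for (p in seq_len(network$n_pn)) {
    spikes <- pn_trains$trains[[p]]
    if (!length(spikes) || counts[p] == 0L) next
    st <- as.integer(round(spikes * 1000 / dt))
    st <- st[st < n_steps]
    if (!length(st)) next
    r <- (offs[p] + 1L):offs[p + 1L]
    j <- j + 1L
    base <- rep(st, each = length(r))
    steps_list[[j]] <- if (is.null(edge_d)) base else
      base + rep(edge_d[r], times = length(st))
    kc_list[[j]] <- rep(edge_kc[r], times = length(st))
    w_list[[j]] <- rep(edge_w[r], times = length(st))
  }
  if (j == 0L)
    return(list(ev_step = integer(0), ev_kc = integer(0),
                ev_w = numeric(0)))
  step <- unlist(steps_list, use.names = FALSE)
  kc <- unlist(kc_list, use.names = FALSE)
  w <- unlist(w_list, use.names = FALSE)
  keep <- step < n_steps
  step <- step[keep]; kc <- kc[keep]; w <- w[keep]
  ord2 <- order(step)
  list(ev_step = step[ord2], ev_kc = kc[ord2] - 1L, ev_w = w[ord2])
}

empty_ext <- function() list(ev_step = integer(0), ev_comp = integer(0),
                             ev_w = numeric(0), tau_r = 1, tau_d = 5,
                             e_rev = 0)

ig_engine_args <- function(network, pn_trains, dt, n_steps) {
  cfg <- network$config
  if (cfg$ig_variant == "absent" || is.null(network$ig_wiring))
    return(list(has = FALSE, a = 0, b = 0, c = 0, d = 0, i_base = 0,
                comp = 1L, ggn_ig_gbar = 0, e_ggn_ig = -80, ig_ggn_w = 0,
                ig_ggn_tau = 10, e_ig_ggn = -80, kc_ig_w = numeric(0),
                kc_ig_delay_steps = 0L, pn_ig_steps = integer(0),
                pn_ig_w = 0, syn_tau_r = 1, syn_tau_d = 5))
  ig <- cfg$ig
  ip <- ig_params()
  i_base <- ig$i_base
  if (is.null(i_base))
    i_base <- calibrate_ig_current(ip, target_rate = ig$spont_rate,
                                   tol = 0.5)
  pn_ig_steps <- integer(0)
  pn_ig_w <- 0
  if (cfg$ig_variant == "reciprocal+PN_drive") {
    all_sp <- sort(unlist(pn_trains$trains, use.names = FALSE))
    st <- as.integer(round(all_sp * 1000 / dt))
    pn_ig_steps <- st[st < n_steps]
    pn_ig_w <- ig$pn_ig_weight
  }
  list(has = TRUE, a = ip$a, b = ip$b, c = ip$c, d = ip$d,
       i_base = i_base, comp = network$ig_wiring$comp,
       ggn_ig_gbar = ig$ggn_ig_gbar, e_ggn_ig = -80,
       ig_ggn_w = ig$ig_ggn_w, ig_ggn_tau = ig$ig_ggn_tau,
       e_ig_ggn = -80, kc_ig_w = network$ig_wiring$kc_ig_w,
       kc_ig_delay_steps = as.integer(round(ig$kc_ig_delay / dt)),
       pn_ig_steps = pn_ig_steps, pn_ig_w = pn_ig_w,
       syn_tau_r = 1, syn_tau_d = 5)
}

#' Co-simulate the assembled network
#'
#' Per-step coupling: PN spikes drive KC excitatory conductances; KC
#' spikes (after their synaptic delay plus the one-step stagger of the
#' cross-population coupling) drive GGN alpha-lobe synapses; each KC's
#' graded inhibitory conductance follows its assigned calyceal
#' compartment's voltage of the previous step; IG exchanges graded and
#' spiking input with GGN per wiring variant. The GGN membrane potential
#' is recorded at the base of the alpha-lobe branch (matching the in
#' vivo recording site) and at sampled compartments in every region.
#'
#' @param network [build_network()] result.
#' @param pn_trains [sample_poisson()] result.
#' @param duration simulated time, ms (default: odor offset + off epoch
#'   + 200 ms margin).
#' @param dt time step, ms (<= 0.025, the HH constraint).
#' @param record_every_ms trace sampling interval, ms.
#' @param kc_record indices of KCs whose voltages are recorded.
#' @param frozen_ggn hold GGN at rest (used for calibration and for the
#'   open-loop "spontaneous inhibition" configuration).
#' @return `simulation_result` (see [simulation_result()]).
#' @export
run_network <- function(network, pn_trains, duration = NULL, dt = 0.025,
                        record_every_ms = 1, kc_record = integer(0),
                        frozen_ggn = FALSE) {
  if (dt > 0.025 + 1e-12) stop("dt must be <= 0.025 ms (HH constraint)")
  cfg <- network$config
  model <- network$model
  pcfg <- pn_trains$config
  if (is.null(duration))
    duration <- (pcfg$odor_window[2] + pcfg$off_epoch) * 1000 + 200
  n_steps <- as.integer(ceiling(duration / dt))
  rec_every <- max(1L, as.integer(round(record_every_ms / dt)))
  ev <- pn_arrival_events(network, pn_trains, dt, n_steps)
  # record site plus a few compartments per region
  rec_comps <- unique(c(network$record_site,
                        unlist(lapply(split(seq_along(model$region),
                                            model$region),
                                      function(ix) head(ix, 2)))))
  odor_steps <- as.integer(round(pcfg$odor_window * 1000 / dt))
  n_kc <- cfg$n_kc
  res <- engine_run_cpp(
    cable = list(parent = model$parent, g_ax = model$g_ax,
                 g_leak = model$g_leak, C = model$C,
                 E_rest = model$bio$E_rest, frozen = frozen_ggn),
    kcs = list(n_kc = n_kc, params = unclass(cfg$kc), v0 = -70,
               exc_tau_r = cfg$tau_rise, exc_tau_d = cfg$tau_decay,
               e_exc = 0,
               graded_gbar = network$ggn_kc_gbar,
               graded_assign = network$ggn_kc_assign,
               graded_vhalf = cfg$graded$V_half,
               graded_slope = cfg$graded$slope,
               graded_tau = cfg$graded$tau,
               graded_erev = cfg$graded$E_rev,
               i_amp = numeric(0), i_on_step = 0L, i_off_step = 0L),
    pn = ev,
    kc_ggn = list(mode = 0L, target = network$kc_ggn_target,
                  w = network$kc_ggn_w,
                  delay_steps = rep(0L, n_kc),
                  tau_r = cfg$tau_rise, tau_d = cfg$tau_decay,
                  e_rev = 0, kernel = numeric(0)),
    ext = empty_ext(),
    ig = ig_engine_args(network, pn_trains, dt, n_steps),
    control = list(dt = dt, n_steps = n_steps, record_every = rec_every,
                   record_comps = rec_comps,
                   odor_on_step = odor_steps[1],
                   odor_off_step = odor_steps[2],
                   kc_record = as.integer(kc_record)))
  simulation_result(
    t = res$t,
    ggn = list(Vm = res$ggn_v[, 1], comps = rec_comps,
               v = res$ggn_v, comp_v_mean = res$comp_v_mean),
    kc = list(spikes = data.frame(kc = res$kc_spike_id,
                                  t = res$kc_spike_t),
              n_kc = n_kc, v = res$kc_v, recorded = kc_record),
    ig = list(v = res$ig_v, spikes = res$ig_spikes),
    config = list(network = cfg, pn = pcfg, dt = dt,
                  duration = duration, frozen_ggn = frozen_ggn),
    seed = list(network = network$seed, pn = pn_trains$seed))
}

#' Calibrate the mean graded GGN->KC conductance
#'
#' Bisection on a multiplier of the graded conductances until the median
#' KC membrane potential under spontaneous PN bombardment lies in
#' `band`. The run holds GGN at its resting potential: under spontaneous
#' drive GGN stays within a fraction of a millivolt of rest and KCs are
#' nearly silent, so the open-loop median is the calibration-relevant
#' quantity at a fraction of the closed-loop cost. A KC subsample keeps
#' each bisection probe cheap.
#'
#' @param network [build_network()] result.
#' @param pn_trains spontaneous-only PN spike trains (generate with an
#'   odor window outside the simulated duration).
#' @param band target band for the median KC potential, mV.
#' @param n_sample number of KCs to simulate per probe.
#' @param duration_ms probe duration, ms.
#' @param max_iter bisection iterations.
#' @return the network with scaled `ggn_kc_gbar`; the applied multiplier
#'   is in attribute `"gbar_multiplier"`, the achieved median in
#'   `"median_kc_mV"`.
#' @export
calibrate_kc_inhibition <- function(network, pn_trains,
                                    band = c(-61, -59), n_sample = 200,
                                    duration_ms = 2000, max_iter = 20) {
  probe <- function(mult) {
    median(kc_mean_potentials(network, pn_trains, mult, n_sample,
                              duration_ms))
  }
  lo <- 0; hi <- 1
  m_hi <- probe(hi)
  while (m_hi > band[2] && hi < 256) {
    lo <- hi; hi <- hi * 2
    m_hi <- probe(hi)
  }
  if (m_hi > band[2])
    stop("calibration target unattainable within bracket")
  m <- NA_real_; mult <- hi
  for (i in seq_len(max_iter)) {
    mult <- (lo + hi) / 2
    m <- probe(mult)
    if (m >= band[1] && m <= band[2]) break
    if (m > band[2]) lo <- mult else hi <- mult
  }
  if (!(m >= band[1] && m <= band[2]))
    stop("calibration did not converge to the target band")
  network$ggn_kc_gbar <- network$ggn_kc_gbar * mult
  attr(network, "gbar_multiplier") <- mult
  attr(network, "median_kc_mV") <- m
  network
}

# time-averaged membrane potential of a KC subsample under the given
# PN drive with GGN frozen at rest; gbar scaled by `mult`
kc_mean_potentials <- function(network, pn_trains, mult = 1,
                               n_sample = 200, duration_ms = 2000,
                               dt = 0.025) {
  n_kc <- network$config$n_kc
  idx <- if (n_kc <= n_sample) seq_len(n_kc) else
    round(seq(1, n_kc, length.out = n_sample))
  sub <- network
  sub$config$n_kc <- length(idx)
  sub$pn_sets <- network$pn_sets[, idx, drop = FALSE]
  sub$pn_w <- network$pn_w[, idx, drop = FALSE]
  sub$pn_delay <- if (is.null(network$pn_delay)) NULL else
    network$pn_delay[, idx, drop = FALSE]
  sub$ggn_kc_gbar <- network$ggn_kc_gbar[idx] * mult
  sub$kc_ggn_target <- network$kc_ggn_target[idx]
  sub$kc_ggn_w <- network$kc_ggn_w[idx]
  sub$ggn_kc_assign <- network$ggn_kc_assign[idx]
  if (!is.null(sub$ig_wiring) && length(sub$ig_wiring$kc_ig_w))
    sub$ig_wiring$kc_ig_w <- sub$ig_wiring$kc_ig_w[idx]
  res <- run_network(sub, pn_trains, duration = duration_ms, dt = dt,
                     record_every_ms = 2,
                     kc_record = seq_along(idx), frozen_ggn = TRUE)
  # drop the first quarter (settling) before averaging
  nt <- nrow(res$kc$v)
  colMeans(res$kc$v[seq(ceiling(nt / 4), nt), , drop = FALSE])
}
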