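# Synthetic projection-neuron (PN) population activity: the only input
# to the mushroom-body model.  Spike trains follow the population
# statistics measured in vivo: 77% of PNs spontaneously active at 2.6
# spikes/s; during a 1 s odor window 20% of PNs switch to 20 spikes/s
# modulated by the 20 Hz LFP oscillation (modulation amplitude 0.4 x
# rate) and 10% of the spontaneously active PNs are inhibited; an
# alternative "shifting" scheme divides the responsive PNs into four
# groups with epoch-wise excitation/inhibition sequences and per-cycle
# recruitment.  All times in this module are in seconds.

#' PN population configuration
#'
#' @param n_pn number of PNs.
#' @param frac_spontaneous fraction spontaneously active.
#' @param spont_rate spontaneous firing rate, spikes/s.
#' @param frac_excited fraction of PNs excited during odor.
#' @param odor_rate mean odor-evoked rate of excited PNs, spikes/s.
#' @param frac_inhibited fraction of spontaneously active PNs inhibited
#'   during odor.
#' @param lfp_freq LFP oscillation frequency, Hz.
#' @param lfp_mod sinusoidal modulation amplitude as a fraction of
#'   `odor_rate`.
#' @param odor_window `c(onset, offset)`, s.
#' @param off_epoch duration of the off-response epoch after odor offset,
#'   s (third epoch of the shifting scheme).
#' @param scheme `"fixed"` (one static responsive set) or `"shifting"`
#'   (four groups with E/I epoch sequences).
#' @return list of class `pn_config`.
#' @export
pn_config <- function(n_pn = 830, frac_spontaneous = 0.77,
                      spont_rate = 2.6, frac_excited = 0.20,
                      odor_rate = 20, frac_inhibited = 0.10,
                      lfp_freq = 20, lfp_mod = 0.4,
                      odor_window = c(0.5, 1.5), off_epoch = 0.5,
                      scheme = c("fixed", "shifting")) {
  scheme <- match.arg(scheme)
  fr <- c(frac_spontaneous, frac_excited, frac_inhibited)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (spont_rate < 0 || odor_rate < 0) stop("rates must be >= 0")
  if (diff(odor_window) <= 0) stop("odor_window must be increasing")
  structure(list(n_pn = as.integer(n_pn),
                 frac_spontaneous = frac_spontaneous,
                 spont_rate = spont_rate, frac_excited = frac_excited,
                 odor_rate = odor_rate, frac_inhibited = frac_inhibited,
                 lfp_freq = lfp_freq, lfp_mod = lfp_mod,
                 odor_window = odor_window, off_epoch = off_epoch,
                 scheme = scheme), class = "pn_config")
}

# odor-evoked modulated rate; LFP phase is 0 at odor onset
odor_rate_t <- function(config, t) {
  config$odor_rate *
    (1 + config$lfp_mod *
       sin(2 * pi * config$lfp_freq * (t - config$odor_window[1])))
}

#' Per-PN rate functions for the fixed-population scheme
#'
#' Population bookkeeping uses `round()` so counts are reproducible: with
#' 830 PNs, 639 are spontaneously active, 166 odor-excited and 64
#' odor-inhibited. Excited PNs follow the 20 Hz-modulated odor rate
#' inside the odor window and the spontaneous rate outside; inhibited
#' PNs fall silent for the odor window.
#'
#' @param config [pn_config()] with `scheme = "fixed"`.
#' @return object of class `pn_rates`.
#' @export
rates_fixed <- function(config) {
  stopifnot(config$scheme == "fixed")
  n <- config$n_pn
  n_spont <- round(config$frac_spontaneous * n)
  n_exc <- round(config$frac_excited * n)
  n_inh <- round(config$frac_inhibited * n_spont)
  if (n_exc + n_inh > n_spont)
    stop("excited + inhibited PNs exceed the spontaneously active pool")
  class <- rep("silent", n)
  class[seq_len(n_spont)] <- "spontaneous"
  class[seq_len(n_exc)] <- "excited"
  class[n_exc + seq_len(n_inh)] <- "inhibited"
  structure(list(config = config, class = class,
                 group = rep(NA_character_, n)),
            class = "pn_rates")
}

#' Per-PN rate functions for the shifting-population scheme
#'
#' About 30% of PNs are unresponsive; the rest form four equal groups
#' with odor-elicited epoch sequences EEI, EIE, IEI and IIE over two
#' odor half-epochs and the off epoch. Within an excitatory epoch a
#' group starts with 70% of members active and recruits a further 10%
#' at each of the next three LFP cycles; recruitment is cumulative
#' within the epoch and the active subsets are redrawn per epoch, so the
#' responding composition shifts through the response.
#'
#' @param config [pn_config()] with `scheme = "shifting"`.
#' @param seed integer seed for group assignment and recruitment draws.
#' @return object of class `pn_rates` with group metadata.
#' @export
rates_shifting <- function(config, seed = 1) {
  stopifnot(config$scheme == "shifting")
  n <- config$n_pn
  gsz <- floor(0.7 * n / 4)
  patterns <- c("EEI", "EIE", "IEI", "IIE")
  with_seed(seed, {
    perm <- sample.int(n)
    group <- rep(NA_character_, n)
    members <- vector("list", 4)
    for (g in 1:4) {
      members[[g]] <- sort(perm[(g - 1) * gsz + seq_len(gsz)])
      group[members[[g]]] <- patterns[g]
    }
    group[is.na(group)] <- "unresponsive"
    spont <- logical(n)
    spont[sample.int(n, round(config$frac_spontaneous * n))] <- TRUE
    # per group x epoch recruitment order (a fresh permutation each
    # excitatory epoch shifts the active composition)
    rec_order <- lapply(1:4, function(g)
      lapply(1:3, function(e) sample(members[[g]])))
    structure(list(config = config,
                   class = ifelse(group == "unresponsive",
                                  ifelse(spont, "spontaneous", "silent"),
                                  "responsive"),
                   group = group, members = members, spont = spont,
                   patterns = patterns, rec_order = rec_order),
              class = "pn_rates")
  })
}

# epoch boundaries of the shifting scheme (s): two half-odor epochs and
# the off epoch
epoch_bounds <- function(config) {
  on <- config$odor_window[1]; off <- config$odor_window[2]
  c(on, (on + off) / 2, off, off + config$off_epoch)
}

#' Evaluate the firing rate of one PN at given times
#'
#' @param rates `pn_rates` from [rates_fixed()] or [rates_shifting()].
#' @param i PN index.
#' @param t times, s.
#' @return rate values, spikes/s (never negative).
#' @export
pn_rate <- function(rates, i, t) {
  config <- rates$config
  on <- config$odor_window[1]; off <- config$odor_window[2]
  in_odor <- t >= on & t < off
  if (is.null(rates$members)) {           # fixed scheme
    cls <- rates$class[i]
    r <- rep(switch(cls, silent = 0, config$spont_rate), length(t))
    if (cls == "excited")
      r[in_odor] <- pmax(0, odor_rate_t(config, t[in_odor]))
    if (cls == "inhibited") r[in_odor] <- 0
    return(r)
  }
  # shifting scheme
  spont_r <- if (rates$spont[i]) config$spont_rate else 0
  grp <- rates$group[i]
  if (grp == "unresponsive") return(rep(spont_r, length(t)))
  g <- match(grp, rates$patterns)
  eb <- epoch_bounds(config)
  r <- rep(spont_r, length(t))
  # responsive PNs are driven by their epoch pattern between odor onset
  # and the end of the off epoch
  pat <- strsplit(grp, "")[[1]]
  for (e in 1:3) {
    sel <- t >= eb[e] & t < eb[e + 1]
    if (!any(sel)) next
    if (pat[e] == "I") { r[sel] <- 0; next }
    # excitatory epoch: active iff recruited by the current LFP cycle
    cyc <- floor((t[sel] - eb[e]) * config$lfp_freq)
    frac <- pmin(1, 0.7 + 0.1 * pmin(cyc, 3))
    ord <- rates$rec_order[[g]][[e]]
    pos <- match(i, ord)
    active <- pos <= floor(frac * length(ord))
    rr <- pmax(0, odor_rate_t(config, t[sel]))
    rr[!active] <- 0
    r[sel] <- rr
  }
  r
}

max_rate <- function(rates, i) {
  config <- rates$config
  base <- config$odor_rate * (1 + config$lfp_mod)
  cls <- if (is.null(rates$members)) rates$class[i]
  else if (rates$group[i] == "unresponsive") "spontaneous" else "excited"
  switch(cls,
         silent = 0,
         spontaneous = config$spont_rate,
         inhibited = config$spont_rate,
         excited = max(base, config$spont_rate),
         max(base, config$spont_rate))
}

#' Sample PN spike trains by Poisson thinning
#'
#' Independent nonhomogeneous Poisson trains: homogeneous candidates at
#' each PN's rate ceiling are thinned by the ratio of the instantaneous
#' rate to the ceiling. Deterministic for a fixed seed.
#'
#' @param rates `pn_rates`.
#' @param seed integer seed.
#' @param duration simulated time, s.
#' @return object of class `spike_train_set`: `trains` (list of sorted
#'   spike-time vectors, s), `meta` (per-PN class/group), `config`,
#'   `seed`, `duration`.
#' @export
sample_poisson <- function(rates, seed = 1, duration = 2.5) {
  config <- rates$config
  n <- config$n_pn
  trains <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      rmax <- max_rate(rates, i)
      if (rmax <= 0) return(numeric(0))
      n_cand <- rpois(1, rmax * duration)
      if (n_cand == 0) return(numeric(0))
      cand <- sort(runif(n_cand, 0, duration))
      keep <- runif(n_cand) < pn_rate(rates, i, cand) / rmax
      cand[keep]
    })
  })
  structure(list(trains = trains,
                 meta = data.frame(pn = seq_len(n),
                                   class = rates$class,
                                   group = rates$group),
                 config = config, seed = seed, duration = duration),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  ns <- lengths(x$trains)
  cat(sprintf("spike train set: %d PNs over %.2f s, %d spikes total\n",
              length(x$trains), x$duration, sum(ns)))
  invisible(x)
}
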