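# Passive branched-cable electrical model of a labeled morphology:
# electrical discretization, steady-state solves under clamps/injections,
# and implicit transient integration.
#
# Units throughout: mV, ms, nA, uS, nF (so g[uS] * V[mV] = I[nA] and
# C[nF] * dV/dt[mV/ms] = I[nA]).  Specific parameters keep their
# conventional units: RM kOhm cm^2, RA Ohm cm, Cm uF/cm^2.

#' Passive membrane and cytoplasm parameters
#'
#' Defaults are the values used for the GGN model: membrane resistivity
#' 33 kOhm cm^2, cytoplasmic (axial) resistivity 100 Ohm cm, specific
#' capacitance 1 uF/cm^2, and a resting potential of -51 mV.
#'
#' @param RM membrane resistivity, kOhm cm^2.
#' @param RA axial resistivity, Ohm cm.
#' @param Cm specific capacitance, uF/cm^2.
#' @param E_rest leak reversal / resting potential, mV.
#' @return list of class `biophysics`.
#' @export
biophysics <- function(RM = 33, RA = 100, Cm = 1, E_rest = -51) {
  if (RM <= 0 || RA <= 0 || Cm <= 0)
    stop("RM, RA and Cm must all be positive")
  structure(list(RM = RM, RA = RA, Cm = Cm, E_rest = E_rest),
            class = "biophysics")
}

# length constant (um) of a cable of diameter d_um under bio
lambda_um <- function(d_um, bio) {
  # lambda = sqrt(RM * d / (4 RA)); convert RM to Ohm cm^2, d to cm
  lam_cm <- sqrt(bio$RM * 1000 * (d_um * 1e-4) / (4 * bio$RA))
  lam_cm * 1e4
}

#' Discretize a labeled morphology into isopotential compartments
#'
#' Every parent-child neurite segment is split so that no compartment is
#' electrically longer than `max_elec_len` times the local DC length
#' constant lambda(d) = sqrt(RM d / (4 RA)). Compartment membrane areas
#' are cylinder lateral areas with the radius linearly interpolated along
#' the tapering segment; axial conductances connect adjacent compartment
#' centers through the two half-segment resistances. Region labels are
#' inherited from the child node of each segment. Zero-length segments
#' are merged into their parent.
#'
#' @param m labeled [morphology].
#' @param bio [biophysics] parameters.
#' @param max_elec_len maximum compartment length as a fraction of lambda
#'   (default 0.1, common passive-model practice).
#' @return object of class `compartmental_model`: parallel vectors
#'   `parent` (0 for the root compartment), `g_ax` (uS, to parent),
#'   `g_leak` (uS), `C` (nF), `area_cm2`, `region`, `terminal`,
#'   `length_um`, `diam_um`, `pos` (n x 3 matrix of centers) plus the
#'   `biophysics` used.
#' @export
compartmentalize <- function(m, bio = biophysics(), max_elec_len = 0.1) {
  validate_morphology(m)
  if (anyNA(m$nodes$region)) stop("morphology must be labeled first")
  if (max_elec_len <= 0) stop("max_elec_len must be positive")
  nodes <- m$nodes
  pidx <- parent_index(m)
  ord <- topo_order(m)
  root_row <- which(nodes$parent == -1L)

  # accumulators
  cap <- 4096L
  parent <- integer(0); g_ax <- numeric(0); area <- numeric(0)
  region <- character(0); len_um <- numeric(0); diam_um <- numeric(0)
  pos <- NULL
  half_res <- numeric(0)           # axial half-resistance of each comp, Ohm
  pos_list <- list()
  n_comp <- 0L
  add_comp <- function(par, l_um, d_um, reg, center) {
    n_comp <<- n_comp + 1L
    parent[n_comp] <<- par
    len_um[n_comp] <<- l_um
    diam_um[n_comp] <<- d_um
    region[n_comp] <<- reg
    area[n_comp] <<- pi * (d_um * 1e-4) * (l_um * 1e-4)     # cm^2
    half_res[n_comp] <<- 4 * bio$RA * (l_um * 1e-4 / 2) /
      (pi * (d_um * 1e-4)^2)                                 # Ohm
    pos_list[[n_comp]] <<- center
    n_comp
  }

  # soma/root compartment: cylinder with length = diameter
  r0 <- nodes$r[root_row]
  node_comp <- integer(nrow(nodes))
  node_comp[root_row] <- add_comp(0L, 2 * r0, 2 * r0,
                                  nodes$region[root_row],
                                  c(nodes$x[root_row], nodes$y[root_row],
                                    nodes$z[root_row]))
  n_merged <- 0L
  for (i in ord) {
    p <- pidx[i]
    if (is.na(p)) next
    p0 <- c(nodes$x[p], nodes$y[p], nodes$z[p])
    p1 <- c(nodes$x[i], nodes$y[i], nodes$z[i])
    L <- sqrt(sum((p1 - p0)^2))
    if (L == 0) {                         # degenerate: merge with parent
      node_comp[i] <- node_comp[p]
      n_merged <- n_merged + 1L
      next
    }
    d_mean <- nodes$r[p] + nodes$r[i]     # mean diameter of the frustum
    n_sub <- max(1L, ceiling(L / (max_elec_len * lambda_um(d_mean, bio))))
    prev <- node_comp[p]
    for (s in seq_len(n_sub)) {
      f0 <- (s - 1) / n_sub; f1 <- s / n_sub; fm <- (f0 + f1) / 2
      d_sub <- 2 * (nodes$r[p] * (1 - fm) + nodes$r[i] * fm)
      center <- p0 + (p1 - p0) * fm
      prev <- add_comp(prev, L / n_sub, d_sub, nodes$region[i], center)
    }
    node_comp[i] <- prev
  }
  if (n_merged > 0)
    message("compartmentalize: merged ", n_merged,
            " zero-length segments into their parents")

  parent <- parent[seq_len(n_comp)]
  g_ax <- numeric(n_comp)
  has_p <- parent > 0L
  g_ax[has_p] <- 1e6 / (half_res[seq_len(n_comp)][has_p] +
                          half_res[parent[has_p]])          # uS
  area <- area[seq_len(n_comp)]
  terminal <- tabulate(parent[has_p], nbins = n_comp) == 0L
  structure(list(
    parent = parent,
    g_ax = g_ax,
    g_leak = area / bio$RM * 1000,      # uS
    C = bio$Cm * area * 1000,           # nF
    area_cm2 = area,
    region = region[seq_len(n_comp)],
    terminal = terminal,
    length_um = len_um[seq_len(n_comp)],
    diam_um = diam_um[seq_len(n_comp)],
    pos = do.call(rbind, pos_list),
    node_comp = node_comp,
    bio = bio,
    max_elec_len = max_elec_len), class = "compartmental_model")
}

#' @export
print.compartmental_model <- function(x, ...) {
  cat(sprintf("compartmental model: %d compartments, %.2f cm^2 membrane\n",
              length(x$parent), sum(x$area_cm2)))
  print(table(x$region))
  invisible(x)
}

#' Stimulus set for cable simulations
#'
#' @param clamps list of `list(comp =, command =)` voltage clamps (mV);
#'   `command` may be a constant or a function of time (ms).
#' @param injections list of `list(comp =, current =)` current injections
#'   (nA); constant or function of time.
#' @param conductances list of `list(comp =, g =, erev =)` conductance
#'   inputs (uS, mV); `g` constant or function of time.
#' @return object of class `stimulus_set`.
#' @export
stimulus_set <- function(clamps = list(), injections = list(),
                         conductances = list()) {
  cl <- vapply(clamps, function(s) s$comp, numeric(1))
  if (anyDuplicated(cl)) stop("a compartment may carry at most one clamp")
  structure(list(clamps = clamps, injections = injections,
                 conductances = conductances), class = "stimulus_set")
}

eval_wave <- function(w, t) if (is.function(w)) w(t) else w

# assemble diag additions / rhs additions (beyond leak) at time t
stim_terms <- function(model, stim, t) {
  n <- length(model$parent)
  g_add <- numeric(n); rhs_add <- numeric(n)
  for (s in stim$injections)
    rhs_add[s$comp] <- rhs_add[s$comp] + eval_wave(s$current, t)
  for (s in stim$conductances) {
    g <- eval_wave(s$g, t)
    g_add[s$comp] <- g_add[s$comp] + g
    rhs_add[s$comp] <- rhs_add[s$comp] + g * s$erev
  }
  list(g = g_add, rhs = rhs_add)
}

#' Steady-state voltage of a passive compartmental model
#'
#' Solves the linear leak/axial balance with clamped compartments held
#' exactly at their commands (ideal clamp, Dirichlet substitution) using
#' Hines-ordered elimination on the tree. With no stimulus every
#' compartment sits at the resting potential.
#'
#' @param model `compartmental_model`.
#' @param stim [stimulus_set] with time-constant waveforms.
#' @return numeric vector of compartment voltages, mV.
#' @export
steady_state <- function(model, stim = stimulus_set()) {
  n <- length(model$parent)
  E <- model$bio$E_rest
  st <- stim_terms(model, stim, 0)
  diag_add <- model$g_leak + st$g
  rhs <- model$g_leak * E + st$rhs
  clamp_comp <- vapply(stim$clamps, function(s) as.integer(s$comp),
                       integer(1))
  clamp_v <- vapply(stim$clamps, function(s) eval_wave(s$command, 0),
                    numeric(1))
  hines_solve_cpp(model$parent, model$g_ax, diag_add, rhs,
                  clamp_comp, clamp_v)
}

#' Transient simulation of a passive compartmental model
#'
#' Backward-Euler (fully implicit in voltage) integration of
#' `C dV/dt = -g_leak (V - E) - axial flux - g_syn(t) (V - E_syn) + I(t)`;
#' unconditionally stable and convergent to [steady_state()] for constant
#' stimuli. Conductances and currents are evaluated at the end of each
#' step.
#'
#' @param model `compartmental_model`.
#' @param stim [stimulus_set].
#' @param dt time step, ms.
#' @param duration total simulated time, ms.
#' @param record integer compartment indices to record.
#' @param v0 initial voltage (default resting potential everywhere).
#' @return list of class `voltage_trace`: `t` (ms), `v` (matrix, time x
#'   compartment), `comps`.
#' @export
cable_transient <- function(model, stim = stimulus_set(), dt = 0.1,
                            duration = 100, record = NULL, v0 = NULL) {
  if (dt <= 0) stop("dt must be positive")
  n <- length(model$parent)
  if (is.null(record)) record <- seq_len(min(n, 8L))
  if (any(record < 1L | record > n)) stop("recorded compartment not in model")
  E <- model$bio$E_rest
  v <- if (is.null(v0)) rep(E, n) else rep_len(v0, n)
  n_steps <- ceiling(duration / dt)
  out <- matrix(NA_real_, n_steps + 1L, length(record))
  out[1L, ] <- v[record]
  cap_dt <- model$C / dt
  clamp_comp <- vapply(stim$clamps, function(s) as.integer(s$comp),
                       integer(1))
  for (k in seq_len(n_steps)) {
    t1 <- k * dt
    st <- stim_terms(model, stim, t1)
    diag_add <- cap_dt + model$g_leak + st$g
    rhs <- cap_dt * v + model$g_leak * E + st$rhs
    clamp_v <- vapply(stim$clamps, function(s) eval_wave(s$command, t1),
                      numeric(1))
    v <- hines_solve_cpp(model$parent, model$g_ax, diag_add, rhs,
                         clamp_comp, clamp_v)
    if (!all(is.finite(v)))
      stop("cable_transient diverged at t = ", t1, " ms")
    out[k + 1L, ] <- v[record]
  }
  structure(list(t = seq(0, by = dt, length.out = n_steps + 1L),
                 v = out, comps = record), class = "voltage_trace")
}

#' Regional steady-state depolarization under a single voltage clamp
#'
#' Clamps one compartment and returns the steady-state depolarization
#' (V - E_rest) of every *terminal* compartment, grouped by region label;
#' the standard readout for signal-attenuation maps across the GGN arbor.
#'
#' @param model `compartmental_model`.
#' @param clamp_site compartment index to clamp.
#' @param command clamp command, mV.
#' @return named list (one numeric vector of mV depolarizations per
#'   region present among terminal compartments).
#' @export
attenuation_map <- function(model, clamp_site, command) {
  v <- steady_state(model, stimulus_set(clamps = list(
    list(comp = clamp_site, command = command))))
  dv <- v - model$bio$E_rest
  keep <- model$terminal
  split(dv[keep], model$region[keep])
}

#' First compartment of a region along the path from the root
#'
#' Used to locate e.g. the "base of the alpha-lobe branch" recording or
#' clamp site.
#'
#' @param model `compartmental_model`.
#' @param region region label.
#' @return compartment index.
#' @export
region_entry_comp <- function(model, region) {
  cand <- which(model$region == region)
  if (!length(cand)) stop("model has no compartments in region ", region)
  cand[1L]   # compartments are stored in parent-before-child order
}
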