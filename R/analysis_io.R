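# Spike/voltage analysis metrics, IPSP detection, and the hierarchical
# result container shared by all experiments.

#' Hierarchical simulation result container
#'
#' Simulation outputs are stored as a hierarchical group layout
#' (`/ggn/Vm`, `/kc/spikes`, `/ig/Vm`, `/provenance`, ...), mirroring the
#' layout conventions of hierarchical simulation-data formats. The
#' container is a nested R list; [save_result()] / [load_result()]
#' serialize it losslessly.
#'
#' @param t shared time grid, ms.
#' @param ggn,kc,ig,config,seed groups (lists) of payloads.
#' @param ... further groups.
#' @return object of class `simulation_result`.
#' @export
simulation_result <- function(t, ggn = list(), kc = list(), ig = list(),
                              config = list(), seed = list(), ...) {
  res <- list(t = t, ggn = ggn, kc = kc, ig = ig, config = config,
              seed = seed, ...)
  res$provenance <- list(
    config_hash = object_hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("mbggn")),
    r_version = R.version.string)
  structure(res, class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation result: %.0f ms at %d samples",
              max(x$t), length(x$t)))
  if (!is.null(x$kc$spikes))
    cat(sprintf(", %d KC spikes", nrow(x$kc$spikes)))
  cat("\n")
  invisible(x)
}

#' Save / load a simulation result
#'
#' @param res `simulation_result`.
#' @param path file path.
#' @return `path` (save) or the restored object (load).
#' @export
save_result <- function(res, path) {
  saveRDS(res, path)
  invisible(path)
}

#' @rdname save_result
#' @export
load_result <- function(path) readRDS(path)

#' Population spike-time histogram
#'
#' @param raster list of spike-time vectors or a data.frame with a `t`
#'   column (one row per spike), ms.
#' @param bin bin width, ms.
#' @param t_range `c(min, max)` histogram range, ms (default spans the
#'   data).
#' @return list with `breaks` (ms) and `counts`; `sum(counts)` equals
#'   the number of spikes inside the range.
#' @export
population_psth <- function(raster, bin = 100, t_range = NULL) {
  if (bin <= 0) stop("bin must be positive")
  times <- if (is.data.frame(raster)) raster$t else
    unlist(raster, use.names = FALSE)
  if (is.null(t_range))
    t_range <- if (length(times)) range(times) else c(0, bin)
  breaks <- seq(t_range[1], t_range[2] + bin, by = bin)
  counts <- if (length(times))
    tabulate(findInterval(times[times >= t_range[1] &
                                  times < max(breaks)], breaks),
             nbins = length(breaks) - 1L)
  else integer(length(breaks) - 1L)
  list(breaks = breaks, counts = counts)
}

#' Gaussian-smoothed firing rate
#'
#' Each spike contributes a unit-integral Gaussian kernel, so the
#' integral of the rate function equals the spike count.
#'
#' @param spikes spike times, ms.
#' @param sigma kernel SD, ms (the conventional smoothing is 100 ms).
#' @param t_grid evaluation grid, ms.
#' @return rate values (spikes per ms) on `t_grid`.
#' @export
gaussian_rate <- function(spikes, sigma = 100, t_grid) {
  if (sigma <= 0) stop("sigma must be positive")
  if (!length(spikes)) return(numeric(length(t_grid)))
  out <- numeric(length(t_grid))
  for (s in spikes)
    out <- out + exp(-(t_grid - s)^2 / (2 * sigma^2))
  out / (sigma * sqrt(2 * pi))
}

#' Sustainedness index of a GGN response
#'
#' Fraction of 100 ms bins inside the odor window whose mean
#' depolarization from baseline is at least `threshold` (default 2 mV,
#' the lower edge of the depolarization range able to support graded
#' synaptic transmission). A sustained in-vivo-like response scores near
#' 1; isolated synchronized peaks score near 0.
#'
#' @param t time grid, ms.
#' @param v GGN voltage trace, mV.
#' @param odor_window `c(on, off)`, ms.
#' @param threshold depolarization threshold, mV.
#' @param baseline baseline voltage (default: mean before odor onset).
#' @param bin bin width, ms.
#' @return fraction in `[0, 1]`.
#' @export
sustainedness_index <- function(t, v, odor_window, threshold = 2,
                                baseline = NULL, bin = 100) {
  if (odor_window[1] < min(t) || odor_window[2] > max(t))
    stop("odor window outside the trace")
  if (is.null(baseline)) {
    pre <- t < odor_window[1]
    baseline <- if (any(pre)) mean(v[pre]) else v[1]
  }
  edges <- seq(odor_window[1], odor_window[2], by = bin)
  if (tail(edges, 1) < odor_window[2]) edges <- c(edges, odor_window[2])
  means <- vapply(seq_len(length(edges) - 1L), function(i) {
    sel <- t >= edges[i] & t < edges[i + 1]
    mean(v[sel]) - baseline
  }, numeric(1))
  mean(means >= threshold)
}

#' Detect IPSPs in a voltage trace
#'
#' The trace is detrended with a running-median baseline (median filter),
#' and negative deflections whose depth exceeds `min_amplitude` are
#' timestamped at their local minima, enforcing a refractory interval
#' between accepted events. Used to infer IG spiking from the GGN
#' membrane potential, where IG spikes appear one-to-one as IPSPs.
#'
#' @param t time grid, ms.
#' @param v voltage trace, mV.
#' @param min_amplitude minimal deflection depth, mV.
#' @param refractory minimal separation of accepted IPSPs, ms.
#' @param baseline_ms running-median window, ms.
#' @return IPSP trough times, ms.
#' @export
detect_ipsps <- function(t, v, min_amplitude = 0.5, refractory = 20,
                         baseline_ms = 200) {
  dt <- t[2] - t[1]
  if (max(t) - min(t) <= refractory) stop("trace shorter than refractory")
  k <- max(3L, round(baseline_ms / dt))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(v) %% 2L == 0L) length(v) - 1L else length(v))
  base <- stats::runmed(v, k)
  resid <- v - base
  # local minima below threshold
  n <- length(resid)
  is_min <- c(FALSE, resid[2:(n - 1)] < resid[1:(n - 2)] &
                resid[2:(n - 1)] <= resid[3:n], FALSE)
  cand <- which(is_min & resid < -min_amplitude)
  if (!length(cand)) return(numeric(0))
  # deepest-first refractory enforcement
  cand <- cand[order(resid[cand])]
  accepted <- numeric(0)
  for (i in cand) {
    if (!length(accepted) || all(abs(t[i] - accepted) > refractory))
      accepted <- c(accepted, t[i])
  }
  sort(accepted)
}

#' Normalized slope of the rising branch of an input-response curve
#'
#' Least-squares slope of the spike-count curve over its contiguous
#' rising branch (from the first nonzero count to the maximum-count
#' amplitude), divided by a reference slope (typically the isolated-KC
#' slope, making the isolated cell 1 by construction). A ratio below 1
#' means a shallower input-response curve, i.e. an expanded dynamic
#' range.
#'
#' @param amplitudes stimulus amplitudes (increasing).
#' @param counts spike counts per amplitude.
#' @param ref_slope reference slope to normalize by (default: own
#'   slope, giving 1).
#' @return list with `slope`, `normalized`, `branch` (indices used).
#' @export
dynamic_range_slope <- function(amplitudes, counts, ref_slope = NULL) {
  stopifnot(length(amplitudes) == length(counts))
  i0 <- which(counts > 0)[1]
  if (is.na(i0)) stop("no nonzero spike counts: slope undefined")
  imax <- which.max(counts)
  branch <- seq(max(1L, i0 - 1L), imax)
  if (length(branch) < 3L)
    stop("fewer than 3 points on the rising branch: slope undefined")
  fit <- lm(counts[branch] ~ amplitudes[branch])
  slope <- unname(coef(fit)[2])
  if (is.null(ref_slope)) ref_slope <- slope
  list(slope = slope, normalized = slope / ref_slope, branch = branch)
}

#' Correlation between KC output and local GGN depolarization
#'
#' Pearson correlation between per-KC odor-window spike counts and the
#' mean depolarization of each KC's assigned GGN compartment. In a
#' uniform-input network this is clearly negative (KCs under branches
#' receiving weaker feedback spike more); with heterogeneous weights the
#' correlation is expected to be small.
#'
#' @param spike_counts per-KC spike counts.
#' @param local_dv per-KC mean depolarization of the assigned
#'   compartment, mV.
#' @return Pearson correlation coefficient.
#' @export
kc_ggn_local_correlation <- function(spike_counts, local_dv) {
  if (length(spike_counts) < 10) stop("need at least 10 KCs")
  if (sd(spike_counts) == 0 || sd(local_dv) == 0)
    stop("zero-variance input: correlation undefined")
  cor(spike_counts, local_dv)
}

#' Power spectrum of a population rate
#'
#' Periodogram of a binned population spike count (mean removed),
#' returning frequencies in Hz; used to verify the 20 Hz LFP-locked
#' modulation of the odor-evoked PN population rate.
#'
#' @param counts binned spike counts.
#' @param bin_s bin width, s.
#' @return data.frame with `freq` (Hz) and `power`.
#' @export
rate_spectrum <- function(counts, bin_s) {
  x <- counts - mean(counts)
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  k <- seq_len(floor(n / 2))
  data.frame(freq = (k - 1) / (n * bin_s), power = p[k])
}
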