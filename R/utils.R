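# Shared internal helpers.

#' Evaluate an expression with a temporarily fixed RNG state
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state so seeded package functions never disturb the
#' session RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Polynomial rolling hash of an R object's serialization; used only to
# fingerprint configurations in run provenance (not cryptographic).
object_hash <- function(x) {
  v <- as.integer(serialize(x, connection = NULL, version = 2))
  h <- 0
  m <- 2^31 - 1
  for (byte in v) h <- (h * 131 + byte) %% m
  sprintf("%08x", h)
}

#' Zero-phase low-pass filter for membrane-potential traces
#'
#' 4th-order Butterworth applied forward and backward
#' (`signal::filtfilt`), matching the 49 Hz low-pass conventionally used
#' before computing summary metrics on GGN voltage recordings.
#'
#' @param v numeric trace (mV).
#' @param dt sample interval, ms.
#' @param cutoff_hz cutoff frequency, Hz.
#' @return filtered trace, same length.
#' @export
lowpass_trace <- function(v, dt, cutoff_hz = 49) {
  fs <- 1000 / dt                       # Hz
  wn <- cutoff_hz / (fs / 2)
  if (wn >= 1) return(v)
  bf <- signal::butter(4, wn, type = "low")
  # pad with edge values to suppress start/end filter transients
  n_pad <- min(length(v), ceiling(200 / dt))
  padded <- c(rep(v[1], n_pad), v, rep(v[length(v)], n_pad))
  out <- as.numeric(signal::filtfilt(bf, padded))
  out[n_pad + seq_along(v)]
}
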