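# Shared fixtures, built once per test run.

# unbranched cylinder morphology along x
make_cylinder <- function(n = 51, L_um = 1000, d_um = 2,
                          region = "BASAL") {
  nodes <- data.frame(id = seq_len(n), parent = c(-1L, seq_len(n - 1)),
                      type = 5L,
                      x = seq(0, L_um, length.out = n), y = 0, z = 0,
                      r = d_um / 2, region = region)
  morphology(nodes)
}

# Y-shaped tree: stem plus two branches of given lengths
make_y_tree <- function(stem = 100, arm = 100, step = 10) {
  ns <- stem / step; na <- arm / step
  id <- 1L; rows <- list()
  add <- function(parent, x, y) {
    rows[[length(rows) + 1L]] <<- data.frame(id = id, parent = parent,
                                             type = 5L, x = x, y = y,
                                             z = 0, r = 1,
                                             region = "BASAL")
    old <- id; id <<- id + 1L; old
  }
  p <- add(-1L, 0, 0)
  for (i in seq_len(ns)) p <- add(p, i * step, 0)
  fork <- p
  p <- fork
  for (i in seq_len(na)) p <- add(p, stem + i * step, i * step)
  p <- fork
  for (i in seq_len(na)) p <- add(p, stem + i * step, -i * step)
  morphology(do.call(rbind, rows))
}

# small synthetic GGN-like tree + compartmental model, cached
fixture_env <- new.env()
small_ggn <- function() {
  if (is.null(fixture_env$small_ggn))
    fixture_env$small_ggn <- generate_synthetic_ggn(
      seed = 11, total_length_um = 6500, max_path_um = 1200,
      segment_um = 40)
  fixture_env$small_ggn
}
small_model <- function() {
  if (is.null(fixture_env$small_model))
    fixture_env$small_model <- compartmentalize(small_ggn())
  fixture_env$small_model
}
full_ggn <- function() {
  if (is.null(fixture_env$full_ggn))
    fixture_env$full_ggn <- generate_synthetic_ggn(seed = 1)
  fixture_env$full_ggn
}
full_model <- function() {
  if (is.null(fixture_env$full_model))
    fixture_env$full_model <- compartmentalize(full_ggn())
  fixture_env$full_model
}
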