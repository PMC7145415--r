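test_that("a minimal SWC file parses into a one-branch-point tree", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# toy neuron",
               "1 1 0 0 0 5 -1",
               "2 5 10 0 0 1 1",
               "3 5 -10 0 0 1 1"), path)
  m <- load_swc(path)
  expect_s3_class(m, "morphology")
  st <- morphometry(m)
  expect_equal(st$n_branch_points, 1L)
  expect_equal(st$total_length, 20)
  expect_equal(st$max_diameter, 10)
})

test_that("SWC round trip preserves the tree and remaps ids to 1..N", {
  m <- small_ggn()
  # scramble ids to prove remapping
  sc <- m
  sc$nodes$id <- sc$nodes$id * 10L
  sc$nodes$parent <- ifelse(sc$nodes$parent == -1L, -1L,
                            sc$nodes$parent * 10L)
  sc <- morphology(sc$nodes)
  path <- withr::local_tempfile(fileext = ".swc")
  save_swc(sc, path)
  m2 <- load_swc(path)
  expect_equal(sort(m2$nodes$id), seq_len(nrow(m$nodes)))
  s1 <- morphometry(m); s2 <- morphometry(m2)
  expect_equal(s2$total_length, s1$total_length, tolerance = 1e-6)
  expect_equal(s2$n_branch_points, s1$n_branch_points)
  # isomorphism surrogate: identical sorted segment-length multiset
  expect_equal(sort(mbggn:::segment_lengths(m2)),
               sort(mbggn:::segment_lengths(m)), tolerance = 1e-6)
  expect_equal(sort(table(m2$nodes$region)), sort(table(m$nodes$region)))
})

test_that("structural defects are rejected", {
  good <- data.frame(id = 1:3, parent = c(-1L, 1L, 2L), type = 5L,
                     x = 0:2, y = 0, z = 0, r = 1)
  expect_s3_class(morphology(good), "morphology")
  bad_r <- good; bad_r$r[2] <- 0
  expect_error(morphology(bad_r), "radii")
  orphan <- good; orphan$parent[3] <- 99L
  expect_error(morphology(orphan), "orphan")
  two_roots <- good; two_roots$parent[3] <- -1L
  expect_error(morphology(two_roots), "exactly one root")
  cyc <- data.frame(id = 1:3, parent = c(-1L, 3L, 2L), type = 5L,
                    x = 0:2, y = 0, z = 0, r = 1)
  expect_error(morphology(cyc), "cycle|connected")
  expect_error(save_swc(structure(list(nodes = good[0, ]),
                                  class = "morphology"),
                        tempfile()), "no nodes")
})

test_that("morphometry matches forced geometries and ignores node order", {
  chain <- make_cylinder(n = 11, L_um = 100)
  st <- morphometry(chain)
  expect_equal(st$total_length, 100 + 0, tolerance = 1e-9)
  expect_equal(st$n_branch_points, 0L)
  y <- make_y_tree(stem = 100, arm = 100)
  sty <- morphometry(y)
  # tip-to-tip path runs through both arms
  expect_equal(sty$max_path_length, 2 * 100 * sqrt(2), tolerance = 1e-9)
  expect_lte(sty$max_euclidean, sty$max_path_length)
  # permutation invariance
  perm <- sample(nrow(y$nodes))
  shuffled <- morphology(y$nodes[perm, ])
  stp <- morphometry(shuffled)
  expect_equal(stp$total_length, sty$total_length)
  expect_equal(stp$max_path_length, sty$max_path_length)
})

test_that("synthetic GGN hits its morphometric targets deterministically", {
  m <- full_ggn()
  st <- morphometry(m)
  expect_gt(st$total_length, 58500)   # within 10% of 65 mm
  expect_lt(st$total_length, 71500)
  expect_lt(st$max_path_length, 3000) # order 2 mm
  expect_gt(st$max_path_length, 1200)
  expect_equal(st$max_diameter, 20, tolerance = 0.5)  # trunk diameter
  expect_lte(st$max_euclidean, st$max_path_length)
  expect_false(anyNA(m$nodes$region))
  # determinism: identical SWC output for the same seed
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  save_swc(generate_synthetic_ggn(seed = 42, total_length_um = 5000,
                                  max_path_um = 1000), p1)
  save_swc(generate_synthetic_ggn(seed = 42, total_length_um = 5000,
                                  max_path_um = 1000), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(generate_synthetic_ggn(seed = 1, total_length_um = -5),
               "positive")
})

test_that("calyces dominate terminals and avoid the alpha lobe", {
  m <- full_ggn()
  term <- terminal_nodes(m)
  reg <- m$nodes$region[term]
  expect_gte(mean(reg %in% c("CALYX_LATERAL", "CALYX_MEDIAL")), 0.5)
  # every calyceal terminal reachable from the root without passing
  # through alpha-lobe nodes
  pidx <- mbggn:::parent_index(m)
  crosses_alpha <- vapply(term[reg %in% c("CALYX_LATERAL",
                                          "CALYX_MEDIAL")],
                          function(i) {
    j <- i
    while (!is.na(pidx[j])) {
      if (m$nodes$region[j] == "ALPHA_LOBE") return(TRUE)
      j <- pidx[j]
    }
    FALSE
  }, logical(1))
  expect_false(any(crosses_alpha))
})

test_that("region labeling schemes assign every node or fail loudly", {
  m <- small_ggn()
  relabeled <- label_regions(m, "swc_type")
  expect_identical(relabeled$nodes$region, m$nodes$region)
  unl <- m
  unl$nodes$region[5] <- NA
  expect_error(label_regions(unl, "passthrough"), "unlabeled")
  fn <- function(nodes) rep("BASAL", nrow(nodes))
  expect_identical(unique(label_regions(m, fn)$nodes$region), "BASAL")
})

test_that("compartmentalization respects the electrotonic length rule", {
  bio <- biophysics()
  # one short cylinder: well under 0.1 lambda -> one compartment per
  # segment (single-segment morphology -> root comp + 1)
  short <- make_cylinder(n = 2, L_um = 50, d_um = 2)
  cm1 <- compartmentalize(short, bio)
  expect_equal(length(cm1$parent), 2L)
  # long thin cylinder gets split
  long <- make_cylinder(n = 2, L_um = 2000, d_um = 1)
  lam <- mbggn:::lambda_um(1, bio)   # frustum mean diameter r_p + r_i
  cml <- compartmentalize(long, bio)
  expect_equal(length(cml$parent) - 1L, ceiling(2000 / (0.1 * lam)))
  expect_true(all(cml$length_um[-1] <= 0.1 * lam + 1e-9))
  # halving the rule at least doubles counts (+/- 1 per section)
  m <- small_ggn()
  n1 <- length(compartmentalize(m, bio, 0.1)$parent)
  n2 <- length(compartmentalize(m, bio, 0.05)$parent)
  n_sections <- nrow(m$nodes) - 1L
  expect_gte(n2, 2L * n1 - n_sections - 1L)
})

test_that("compartmentalization conserves membrane area and labels", {
  m <- small_ggn()
  bio <- biophysics()
  cm <- compartmentalize(m, bio, 0.1)
  # analytic frustum-sum area of the source morphology
  pidx <- mbggn:::parent_index(m)
  len <- mbggn:::segment_lengths(m)
  has_p <- !is.na(pidx)
  d_mean <- (m$nodes$r[has_p] + m$nodes$r[pidx[has_p]])
  area_src <- sum(pi * d_mean * 1e-4 * len[has_p] * 1e-4)
  root <- which(m$nodes$parent == -1L)
  area_src <- area_src + pi * (2 * m$nodes$r[root] * 1e-4) *
    (2 * m$nodes$r[root] * 1e-4)
  expect_equal(sum(cm$area_cm2), area_src, tolerance = 0.01)
  expect_true(all(cm$region %in% REGION_LABELS))
  expect_true(all(cm$parent[-1] < seq_along(cm$parent)[-1]))
})
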