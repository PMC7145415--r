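# Neuronal tree morphologies: SWC I/O, validation, morphometry, region
# labeling, and a seeded synthetic GGN-like generator.
#
# A morphology is a rooted tree of 3-D points with radii (SWC semantics,
# all distances in micrometers).  Region labels partition the tree into the
# anatomical domains that matter for the mushroom-body circuit: the alpha
# lobe (where KCs excite GGN), the two calyces (where GGN inhibits KCs),
# the basal/soma region (IG contact), and the lateral horn.

#' Region labels used for GGN-like morphologies
#'
#' Closed enumeration of anatomical regions. The calyceal arbor is the
#' union of `CALYX_LATERAL` and `CALYX_MEDIAL`.
#' @export
REGION_LABELS <- c("SOMA", "BASAL", "ALPHA_LOBE", "CALYX_LATERAL",
                   "CALYX_MEDIAL", "LATERAL_HORN")

# SWC struct_type codes carrying region identity for files written by this
# package: 1 = soma plus custom codes 5-9 for the GGN regions.
SWC_REGION_CODES <- c(SOMA = 1L, BASAL = 5L, ALPHA_LOBE = 6L,
                      CALYX_LATERAL = 7L, CALYX_MEDIAL = 8L,
                      LATERAL_HORN = 9L)

#' Construct a morphology from a node table
#'
#' @param nodes data.frame with columns `id`, `parent` (`-1` for the root),
#'   `type` (integer SWC structure code), `x`, `y`, `z` (um), `r` (radius,
#'   um). An optional `region` column carries region labels.
#' @return object of class `morphology`.
#' @export
morphology <- function(nodes) {
  required <- c("id", "parent", "type", "x", "y", "z", "r")
  if (!all(required %in% names(nodes)))
    stop("node table must have columns ", paste(required, collapse = ", "))
  if (!("region" %in% names(nodes))) nodes$region <- NA_character_
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  m <- structure(list(nodes = nodes), class = "morphology")
  validate_morphology(m)
  m
}

#' Validate tree structure of a morphology
#'
#' Checks positive radii, a single root, that every parent reference
#' resolves, and that the graph is a connected tree (N nodes, N-1 edges,
#' no cycles).
#'
#' @param m morphology.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_morphology <- function(m) {
  nodes <- m$nodes
  if (nrow(nodes) == 0L) stop("morphology has no nodes")
  if (any(!is.finite(nodes$r)) || any(nodes$r <= 0))
    stop("all radii must be positive")
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  root <- which(nodes$parent == -1L)
  if (length(root) != 1L)
    stop("morphology must have exactly one root, found ", length(root))
  idx <- match(nodes$parent, nodes$id)
  orphan <- is.na(idx) & nodes$parent != -1L
  if (any(orphan))
    stop("orphan nodes (parent id not present): ",
         paste(nodes$id[orphan], collapse = ", "))
  # connectivity / acyclicity: walk each node to the root, marking visits
  parent_idx <- idx
  n <- nrow(nodes)
  reached <- logical(n)
  reached[root] <- TRUE
  for (i in seq_len(n)) {
    path <- integer(0)
    j <- i
    while (!reached[j]) {
      path <- c(path, j)
      j <- parent_idx[j]
      if (is.na(j)) stop("broken parent chain at node ", nodes$id[i])
      if (j %in% path) stop("cycle detected involving node ", nodes$id[j])
    }
    reached[path] <- TRUE
  }
  if (!all(reached)) stop("morphology is not connected")
  invisible(m)
}

# index of each node's parent in row order (NA for root)
parent_index <- function(m) {
  idx <- match(m$nodes$parent, m$nodes$id)
  idx[m$nodes$parent == -1L] <- NA_integer_
  idx
}

# parent-child Euclidean segment lengths (um); 0 for the root row
segment_lengths <- function(m) {
  nodes <- m$nodes
  pidx <- parent_index(m)
  len <- numeric(nrow(nodes))
  has_p <- !is.na(pidx)
  dx <- nodes$x[has_p] - nodes$x[pidx[has_p]]
  dy <- nodes$y[has_p] - nodes$y[pidx[has_p]]
  dz <- nodes$z[has_p] - nodes$z[pidx[has_p]]
  len[has_p] <- sqrt(dx^2 + dy^2 + dz^2)
  len
}

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`), `#` comments,
#' coordinates and radii in micrometers. If the structure-type column uses
#' this package's region codes (1, 5-9) every node is also assigned its
#' region label.
#'
#' @param path file path.
#' @return a validated [morphology].
#' @export
load_swc <- function(path) {
  tab <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z", "r",
                                  "parent"),
                    colClasses = c("integer", "integer", "numeric",
                                   "numeric", "numeric", "numeric",
                                   "integer"))
  if (nrow(tab) == 0L) stop("SWC file contains no nodes: ", path)
  nodes <- tab[, c("id", "parent", "type", "x", "y", "z", "r")]
  code_match <- match(nodes$type, SWC_REGION_CODES)
  if (!anyNA(code_match))
    nodes$region <- names(SWC_REGION_CODES)[code_match]
  morphology(nodes)
}

#' Write a morphology to an SWC file
#'
#' Node ids are remapped to contiguous `1..N` in parent-before-child order
#' so the emitted file is a canonical SWC that re-loads to an isomorphic
#' tree. Region labels (when present) are encoded in the structure-type
#' column using codes 1 and 5-9; the mapping is documented in the header.
#'
#' @param m morphology.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_swc <- function(m, path) {
  validate_morphology(m)
  ord <- topo_order(m)
  nodes <- m$nodes[ord, , drop = FALSE]
  new_id <- seq_len(nrow(nodes))
  old_to_new <- setNames(new_id, nodes$id)
  parent <- ifelse(nodes$parent == -1L, -1L,
                   unname(old_to_new[as.character(nodes$parent)]))
  type <- nodes$type
  if (!anyNA(nodes$region))
    type <- unname(SWC_REGION_CODES[nodes$region])
  header <- c(
    "# SWC morphology written by mbggn",
    "# columns: id type x y z radius parent (um)",
    "# struct type codes: 1=SOMA 5=BASAL 6=ALPHA_LOBE 7=CALYX_LATERAL",
    "#                    8=CALYX_MEDIAL 9=LATERAL_HORN")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(data.frame(new_id, type,
                         signif(nodes$x, 8), signif(nodes$y, 8),
                         signif(nodes$z, 8), signif(nodes$r, 8), parent),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# row order with every parent before its children
topo_order <- function(m) {
  pidx <- parent_index(m)
  n <- nrow(m$nodes)
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; j <- i
    while (!is.na(pidx[j])) { d <- d + 1L; j <- pidx[j] }
    depth[i] <- d
  }
  order(depth)
}

# children adjacency list by row index
children_list <- function(m) {
  pidx <- parent_index(m)
  kids <- vector("list", nrow(m$nodes))
  for (i in which(!is.na(pidx)))
    kids[[pidx[i]]] <- c(kids[[pidx[i]]], i)
  kids
}

#' Morphometric summary of a morphology
#'
#' Lengths are sums of parent-child Euclidean segment lengths. The maximum
#' path length (greatest along-neurite distance between any two points) is
#' found with the standard two-pass tree-diameter search; the maximum
#' Euclidean extent is the largest straight-line distance between nodes.
#'
#' @param m morphology.
#' @return list of class `morphometry_stats` with `total_length`,
#'   `max_path_length`, `max_euclidean` (um), `n_branch_points`,
#'   `max_diameter` (um).
#' @export
morphometry <- function(m) {
  validate_morphology(m)
  nodes <- m$nodes
  len <- segment_lengths(m)
  pidx <- parent_index(m)
  n <- nrow(nodes)
  n_children <- tabulate(pidx[!is.na(pidx)], nbins = n)
  # two-pass diameter on the weighted tree
  far <- function(start) {
    dist <- rep(NA_real_, n)
    dist[start] <- 0
    kids <- children_list(m)
    stack <- start
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      nbr <- c(kids[[i]], pidx[i])
      nbr <- nbr[!is.na(nbr)]
      for (j in nbr) {
        if (is.na(dist[j])) {
          w <- if (!is.na(pidx[j]) && pidx[j] == i) len[j] else len[i]
          dist[j] <- dist[i] + w
          stack <- c(stack, j)
        }
      }
    }
    dist
  }
  d1 <- far(which(nodes$parent == -1L))
  a <- which.max(d1)
  d2 <- far(a)
  max_path <- max(d2)
  # max pairwise Euclidean distance, chunked to bound memory
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  max_eu <- 0
  step <- 512L
  for (i0 in seq(1L, n, by = step)) {
    i1 <- min(i0 + step - 1L, n)
    block <- xyz[i0:i1, , drop = FALSE]
    d2m <- outer(rowSums(block^2), rowSums(xyz^2), "+") -
      2 * tcrossprod(block, xyz)
    max_eu <- max(max_eu, sqrt(max(0, max(d2m))))
  }
  structure(list(total_length = sum(len),
                 max_path_length = max_path,
                 max_euclidean = max_eu,
                 n_branch_points = sum(n_children >= 2L),
                 max_diameter = 2 * max(nodes$r)),
            class = "morphometry_stats")
}

#' @export
print.morphometry_stats <- function(x, ...) {
  cat(sprintf(paste0("morphometry: total length %.1f mm, max path %.1f um, ",
                     "max euclidean %.1f um,\n  %d branch points, ",
                     "max diameter %.1f um\n"),
              x$total_length / 1000, x$max_path_length, x$max_euclidean,
              x$n_branch_points, x$max_diameter))
  invisible(x)
}

#' Assign region labels to every node
#'
#' Supported schemes: `"passthrough"` keeps existing labels (errors if any
#' node is unlabeled); `"swc_type"` maps structure-type codes to regions
#' via `type_map`; a function `f(nodes)` returning one label per node may
#' also be given. Labels must be subtree-coherent downstream users rely on
#' whole-subtree regions.
#'
#' @param m morphology.
#' @param scheme `"passthrough"`, `"swc_type"`, or a function.
#' @param type_map named integer vector mapping region label -> type code
#'   (default the package codes).
#' @return morphology with a complete `region` column.
#' @export
label_regions <- function(m, scheme = "passthrough",
                          type_map = SWC_REGION_CODES) {
  validate_morphology(m)
  nodes <- m$nodes
  labels <-
    if (is.function(scheme)) {
      scheme(nodes)
    } else if (identical(scheme, "passthrough")) {
      nodes$region
    } else if (identical(scheme, "swc_type")) {
      names(type_map)[match(nodes$type, type_map)]
    } else stop("unknown labeling scheme")
  if (anyNA(labels) || !all(labels %in% REGION_LABELS))
    stop("labeling left unlabeled or unknown-region nodes")
  m$nodes$region <- labels
  m
}

#' Terminal (leaf) node row indices
#' @param m morphology.
#' @return integer vector of row indices with no children.
#' @export
terminal_nodes <- function(m) {
  pidx <- parent_index(m)
  n <- nrow(m$nodes)
  which(tabulate(pidx[!is.na(pidx)], nbins = n) == 0L)
}

#' Generate a synthetic GGN-like morphology
#'
#' Deterministic (seeded) stochastic binary-branching generator emulating
#' the gross anatomy of the giant GABAergic neuron: a soma with a short
#' basal neurite from which an alpha-lobe subtree, lateral and medial
#' calyceal subtrees rich in short terminal twigs, and a lateral-horn
#' subtree arise. Total neurite length is driven to `total_length_um`
#' (default 65 mm as measured for the traced neuron), neurite diameters
#' taper from about 20 um at the trunk toward 0.5 um at the tips, and path
#' depth is capped so the maximum along-tree path length lands near 2 mm.
#'
#' @param seed integer seed; the same seed always yields the same tree.
#' @param total_length_um target total neurite length, um.
#' @param max_path_um approximate cap on root-to-tip path length, um.
#' @param max_diameter_um trunk diameter, um.
#' @param tip_diameter_um terminal twig diameter, um.
#' @param segment_um mean node-to-node step length, um.
#' @return labeled [morphology].
#' @export
generate_synthetic_ggn <- function(seed = 1,
                                   total_length_um = 65000,
                                   max_path_um = 2000,
                                   max_diameter_um = 20,
                                   tip_diameter_um = 0.5,
                                   segment_um = 40) {
  if (total_length_um <= 0 || max_path_um <= 0 || max_diameter_um <= 0 ||
      tip_diameter_um <= 0 || tip_diameter_um > max_diameter_um)
    stop("morphometry targets must be positive and consistent")
  with_seed(seed, {
    # region length budgets as fractions of the total; calyces dominate,
    # as in the traced neuron where most terminal arbor is calyceal
    budgets <- c(BASAL = 0.02, ALPHA_LOBE = 0.20, CALYX_LATERAL = 0.32,
                 CALYX_MEDIAL = 0.30, LATERAL_HORN = 0.16)
    budgets <- budgets * total_length_um
    depth_cap <- max_path_um / 2 - 150   # per-subtree depth allowance

    rows <- list()
    nid <- 0L
    add_node <- function(parent, type, pos, r) {
      nid <<- nid + 1L
      rows[[nid]] <<- c(nid, parent, type, pos[1], pos[2], pos[3], r)
      nid
    }
    soma_r <- max_diameter_um / 2
    root <- add_node(-1L, SWC_REGION_CODES[["SOMA"]], c(0, 0, 0), soma_r)

    rand_dir <- function(base) {
      d <- base + rnorm(3, sd = 0.35)
      d / sqrt(sum(d^2))
    }

    # grow one subtree: queue of active tips, each tip extends by one
    # segment per draw and branches with probability branch_p until the
    # region budget is spent or the tip hits the depth cap
    grow_region <- function(attach_id, attach_pos, region, budget,
                            start_r, base_dir, seg, branch_p, depth0 = 0) {
      code <- SWC_REGION_CODES[[region]]
      tips <- list(list(id = attach_id, pos = attach_pos, r = start_r,
                        dir = rand_dir(base_dir), depth = depth0))
      used <- 0
      while (used < budget && length(tips) > 0) {
        k <- sample.int(length(tips), 1L)
        tip <- tips[[k]]
        tips[[k]] <- NULL
        L <- seg * runif(1, 0.7, 1.3)
        dir <- rand_dir(tip$dir * 3)
        npos <- tip$pos + dir * L
        # radius shrinks with consumed depth toward the tip diameter
        frac <- min(1, (tip$depth + L) / depth_cap)
        nr <- max(tip_diameter_um / 2,
                  tip$r * (1 - frac * 0.35) *
                    ifelse(runif(1) < branch_p, 0.85, 0.98))
        node <- add_node(tip$id, code, npos, nr)
        used <- used + L
        depth <- tip$depth + L
        if (depth < depth_cap) {
          n_out <- if (runif(1) < branch_p) 2L else 1L
          for (b in seq_len(n_out))
            tips[[length(tips) + 1L]] <-
              list(id = node, pos = npos, r = nr * ifelse(n_out == 2, 0.8, 1),
                   dir = dir, depth = depth)
        }
        # if every tip hit the depth cap but budget remains, restart tips
        if (length(tips) == 0 && used < budget)
          tips[[1L]] <- list(id = attach_id, pos = attach_pos,
                             r = start_r * 0.7, dir = rand_dir(base_dir),
                             depth = depth0)
      }
      node
    }

    # basal trunk: a short thick neurite from the soma
    bcode <- SWC_REGION_CODES[["BASAL"]]
    trunk <- root
    tpos <- c(0, 0, 0)
    n_basal <- max(3L, round(budgets[["BASAL"]] / segment_um))
    for (i in seq_len(n_basal)) {
      tpos <- tpos + c(segment_um, 0, 0) + rnorm(3, sd = 2)
      trunk <- add_node(trunk, bcode, tpos, soma_r * (1 - 0.02 * i))
    }
    trunk_r <- soma_r * 0.9

    # major subtrees leave the end of the basal trunk
    grow_region(trunk, tpos, "ALPHA_LOBE", budgets[["ALPHA_LOBE"]],
                trunk_r * 0.8, c(0, 1, 0), segment_um, branch_p = 0.35)
    grow_region(trunk, tpos, "LATERAL_HORN", budgets[["LATERAL_HORN"]],
                trunk_r * 0.6, c(0, -1, 0), segment_um, branch_p = 0.35)
    # calyces: shorter segments, heavier branching -> many terminal twigs
    grow_region(trunk, tpos, "CALYX_LATERAL", budgets[["CALYX_LATERAL"]],
                trunk_r * 0.7, c(0.2, 0, 1), segment_um * 0.7,
                branch_p = 0.45)
    grow_region(trunk, tpos, "CALYX_MEDIAL", budgets[["CALYX_MEDIAL"]],
                trunk_r * 0.7, c(-0.2, 0, 1), segment_um * 0.7,
                branch_p = 0.45)

    mat <- do.call(rbind, rows)
    nodes <- data.frame(id = as.integer(mat[, 1]),
                        parent = as.integer(mat[, 2]),
                        type = as.integer(mat[, 3]),
                        x = mat[, 4], y = mat[, 5], z = mat[, 6],
                        r = mat[, 7])
    m <- morphology(nodes)
    label_regions(m, "swc_type")
  })
}
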