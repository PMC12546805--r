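# Quantifier stage: detect cilium objects in a segmented stack, filter them,
# and compute per-cilium morphometric and intensity measurements including
# skeleton-based length.

#' Label connected objects in a mask
#'
#' 26-connected component labeling in 3D. With `increase_range` enabled,
#' objects whose voxel sets come within a one-voxel background gap are merged
#' into one label: labeling is performed on the one-voxel-dilated mask and
#' the labels are then restricted to the original foreground.
#'
#' @param mask logical 3D array (or numeric; nonzero = foreground).
#' @param increase_range bridge small background gaps between objects.
#' @param range_voxels dilation radius (voxels) used for gap bridging when
#'   `increase_range` is on; the default 1 merges objects separated by a
#'   one-voxel gap.
#' @return an object of class `labeled_mask`: list with integer array
#'   `labels` (consecutive labels, 0 = background), `n_objects`,
#'   `connectivity_used`, `increase_range`.
#' @export
label_objects <- function(mask, increase_range = FALSE, range_voxels = 1L) {
  m <- array(mask != 0, dim(mask))
  if (increase_range) {
    md <- m
    for (r in seq_len(range_voxels)) md <- dilate1(md)
    lab_d <- cpp_label3d(md, dim(m), 26L)
    lab <- array(0L, dim(m))
    lab[m] <- lab_d[m]
    lab <- relabel_consecutive(lab)
  } else {
    lab <- cpp_label3d(m, dim(m), 26L)
  }
  structure(list(labels = lab, n_objects = max(lab),
                 connectivity_used = 26L, increase_range = increase_range),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> %d object(s), %d-connectivity%s\n",
              x$n_objects, x$connectivity_used,
              if (x$increase_range) ", increase-range" else ""))
  invisible(x)
}

# one-voxel 26-neighbourhood (box) dilation by shifting along all offsets
dilate1 <- function(m) {
  d <- dim(m)
  out <- m
  for (dz in -1:1) for (dx in -1:1) for (dy in -1:1) {
    if (dy == 0 && dx == 0 && dz == 0) next
    ys <- pmin(pmax(seq_len(d[1]) + dy, 1L), d[1])
    xs <- pmin(pmax(seq_len(d[2]) + dx, 1L), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    out <- out | m[ys, xs, zs, drop = FALSE]
  }
  out
}

relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

#' Filter labeled objects by size and border contact
#'
#' Removes objects with fewer than `min_size_voxels` voxels (reason
#' `too-small`) and objects with any voxel in the first or last plane of a
#' flagged axis (reason `border`). Survivors are relabeled consecutively and
#' every removal is listed in the exclusion report.
#'
#' @param labeled a [label_objects()] result.
#' @param min_size_voxels minimum object size in voxels (>= 1; default 10,
#'   appropriate for ~0.1 um lateral pixels — see [suggest_min_size()]).
#' @param exclude_borders logical length-3 `(x, y, z)`: drop objects touching
#'   the first/last plane of that axis.
#' @return a `labeled_mask` with an `exclusion_report` data.frame attached
#'   (`label`, `reason`, `size`).
#' @export
filter_objects <- function(labeled, min_size_voxels = 10L,
                           exclude_borders = c(x = FALSE, y = FALSE,
                                               z = FALSE)) {
  stopifnot(inherits(labeled, "labeled_mask"))
  if (min_size_voxels < 1L) stop("min_size_voxels must be >= 1")
  lab <- labeled$labels
  d <- dim(lab)
  n <- labeled$n_objects
  report <- data.frame(label = integer(0), reason = character(0),
                       size = integer(0))
  if (n > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = n)
    tb <- touches_border_per_label(lab, n)
    border_hit <- (exclude_borders[1] & tb[, "x"]) |
                  (exclude_borders[2] & tb[, "y"]) |
                  (exclude_borders[3] & tb[, "z"])
    too_small <- sizes < min_size_voxels
    drop <- too_small | border_hit
    if (any(drop)) {
      report <- data.frame(
        label = which(drop),
        reason = ifelse(too_small[drop], "too-small", "border"),
        size = sizes[drop])
      lab[lab %in% which(drop)] <- 0L
      lab <- relabel_consecutive(lab)
    }
  }
  out <- structure(list(labels = lab, n_objects = max(lab),
                        connectivity_used = labeled$connectivity_used,
                        increase_range = labeled$increase_range),
                   class = "labeled_mask")
  attr(out, "exclusion_report") <- report
  out
}

# per-label border contact flags; array dims are (y, x, z)
touches_border_per_label <- function(lab, n) {
  d <- dim(lab)
  fl <- function(planes) {
    u <- unique(planes[planes > 0])
    seq_len(n) %in% u
  }
  cbind(x = fl(c(lab[, 1, ], lab[, d[2], ])),
        y = fl(c(lab[1, , ], lab[d[1], , ])),
        z = fl(c(lab[, , 1], lab[, , d[3]])))
}

#' Suggested minimum cilium size for a pixel size
#'
#' The minimum object size threshold scales with the inverse square of the
#' lateral pixel size (pixel size is a length, object size an area in a
#' projection): halving the pixel size requires at least a 4-fold larger
#' voxel threshold. Reference: 10 voxels at 0.1 um/px. The value is a lower
#' bound ("at least") and is rounded up.
#'
#' @param pixel_size_um lateral pixel size in um (> 0).
#' @param reference named vector `c(px = 0.1, voxels = 10)`.
#' @return suggested minimum size in voxels (integer, ceiling).
#' @export
suggest_min_size <- function(pixel_size_um,
                             reference = c(px = 0.1, voxels = 10)) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  as.integer(ceiling(reference[["voxels"]] *
                     (reference[["px"]] / pixel_size_um)^2))
}

# physical voxel-center coordinates for 1-based (y, x, z) indices
voxel_centers_um <- function(coords, vs) {
  cbind(x = (coords[, 2] - 0.5) * vs["dx"],
        y = (coords[, 1] - 0.5) * vs["dy"],
        z = (coords[, 3] - 0.5) * vs["dz"])
}

#' Morphometry of one object
#'
#' Volume (voxel count and um^3), surface as the summed area of exposed
#' voxel faces (um^2), maximum span as the largest pairwise distance between
#' voxel centers in physical units (exact; computed on boundary voxels for
#' large objects, which preserves the maximum), and the centroid (um).
#'
#' @param coords integer matrix (n x 3) of 1-based `(y, x, z)` voxel indices.
#' @param voxel_size_um named `(dx, dy, dz)` vector.
#' @return list: `volume_voxels`, `volume_um3`, `surface_um2`, `max_span_um`,
#'   `centroid_um`.
#' @export
measure_morphology <- function(coords, voxel_size_um) {
  coords <- matrix(as.integer(coords), ncol = 3L)
  if (!nrow(coords)) stop("empty voxel set")
  vs <- voxel_size_um
  n <- nrow(coords)
  # exposed faces via a cropped occupancy array
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  dd <- hi - lo + 3L
  occ <- array(FALSE, dd)
  local <- sweep(coords, 2, lo - 2L, `-`)
  occ[local] <- TRUE
  face_area <- c(y = vs[["dx"]] * vs[["dz"]],   # faces normal to y
                 x = vs[["dy"]] * vs[["dz"]],
                 z = vs[["dx"]] * vs[["dy"]])
  shift <- function(dyy, dxx, dzz) {
    occ[cbind(local[, 1] + dyy, local[, 2] + dxx, local[, 3] + dzz)]
  }
  exposed <- sum(!shift(1, 0, 0)) + sum(!shift(-1, 0, 0))
  surface <- exposed * face_area[["y"]]
  exposed <- sum(!shift(0, 1, 0)) + sum(!shift(0, -1, 0))
  surface <- surface + exposed * face_area[["x"]]
  exposed <- sum(!shift(0, 0, 1)) + sum(!shift(0, 0, -1))
  surface <- surface + exposed * face_area[["z"]]
  pts <- voxel_centers_um(coords, vs)
  if (n > 6000L) {
    boundary <- !(shift(1, 0, 0) & shift(-1, 0, 0) & shift(0, 1, 0) &
                  shift(0, -1, 0) & shift(0, 0, 1) & shift(0, 0, -1))
    pts_span <- pts[boundary, , drop = FALSE]
  } else pts_span <- pts
  list(volume_voxels = n,
       volume_um3 = n * vs[["dx"]] * vs[["dy"]] * vs[["dz"]],
       surface_um2 = as.numeric(surface),
       max_span_um = if (n == 1L) 0 else cpp_max_pairwise(pts_span),
       centroid_um = colMeans(pts))
}

#' Skeletonize an object and measure skeleton-based parameters
#'
#' The object mask is optionally blurred in XY (`gauss_xy_sigma`, pixels) and
#' re-binarized at half maximum (smoother skeletons, fewer noise-driven side
#' branches), then thinned to a one-voxel-wide skeleton by 3D
#' topology-preserving thinning. The skeleton is converted to a graph whose
#' nodes are skeleton voxels and whose edges (between 26-neighbors) are
#' weighted by the anisotropic physical step length. Branches are the graph
#' edges between junction/end nodes (a clean cilium has exactly one);
#' `tree_length_um` is the total physical skeleton length; `cilia_length_um`
#' the largest shortest path between any two end nodes; `bending_ratio` the
#' end-to-end straight-line distance over that path length. A single-voxel
#' skeleton (spherical object) yields length 0, reported rather than erred.
#'
#' @param obj_mask logical 3D array containing only the object.
#' @param voxel_size_um named `(dx, dy, dz)` vector.
#' @param gauss_xy_sigma XY blur sigma in pixels applied to the mask before
#'   thinning (0 = off).
#' @param z_refine z-resampling factor for anisotropic grids (default:
#'   refine to near-isotropic voxels); 1 disables.
#' @param rebinarize_level level at which the blurred mask is re-binarized
#'   (0.5 is the symmetric choice; slightly lower values counteract tip
#'   erosion of thin objects).
#' @return list: `n_branches`, `tree_length_um`, `cilia_length_um`,
#'   `bending_ratio`, `orientation`, plus the `skeleton` array.
#' @export
skeletonize_and_measure <- function(obj_mask, voxel_size_um,
                                    gauss_xy_sigma = 0, z_refine = NULL,
                                    rebinarize_level = 0.5) {
  d <- dim(obj_mask)
  m <- array(obj_mask != 0, d)
  if (!any(m)) stop("empty object")
  vs <- voxel_size_um
  # z-resampling: on strongly anisotropic grids a thin object spans 1-2
  # z-planes and the thinned curve hops between planes, each hop costing a
  # full (large) z-step it never physically made. Replicating slices to a
  # finer z-grid and smoothing in z localizes the skeleton at sub-slice
  # precision; all physical edge weights then use the refined z-spacing.
  # The default refines to (near-)isotropic voxels.
  zf <- if (!is.null(z_refine)) as.integer(z_refine) else
    max(1L, round(vs[["dz"]] / min(vs[["dx"]], vs[["dy"]])))
  if (zf > 1L) {
    m <- m[, , rep(seq_len(d[3]), each = zf), drop = FALSE]
    dim(m) <- c(d[1], d[2], d[3] * zf)
    vs[["dz"]] <- vs[["dz"]] / zf
    d <- dim(m)
  }
  sig_z <- if (zf > 1L) zf / 2 else 0
  if (gauss_xy_sigma > 0 || sig_z > 0) {
    f <- cpp_gauss3d(array(as.numeric(m), d), d,
                     gauss_xy_sigma, gauss_xy_sigma, sig_z)
    m2 <- array(f >= rebinarize_level, d)
    if (any(m2)) m <- m2      # keep original if blur annihilates the object
  }
  skel <- cpp_thin3d(m, d)
  skel <- regularize_skeleton(skel, m, vs)
  g <- skeleton_graph(skel, vs)
  g <- stitch_skeleton(g)
  # a skeleton spanning at most one voxel step is point-like at grid scale
  # (spherical object): reported as zero length, not an error
  point_tol <- sqrt(sum(unlist(vs)^2)) + 1e-12
  measures <- skeleton_measures(g, point_tol = point_tol)
  c(measures, list(skeleton = skel, skeleton_voxel_size_um = vs))
}

# Digital skeletons overestimate physical length: thinning produces staircase
# corners and, on anisotropic grids, spurious hops between z-planes, each
# costing a full (large) z step. This pass shortens chain interiors without
# changing topology: a degree-2 voxel whose two neighbours are themselves
# adjacent is removed (corner cut), and a degree-2 voxel is moved to another
# in-mask position adjacent to both neighbours when that strictly shortens
# the chain. Iterated to a fixed point.
regularize_skeleton <- function(skel, mask, vs) {
  d <- dim(skel)
  w <- c(vs[["dy"]], vs[["dx"]], vs[["dz"]])   # (y, x, z) index order
  step_len <- function(a, b) sqrt(sum(((a - b) * w)^2))
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  neighbors <- function(p) {
    nb <- sweep(offs, 2, p, `+`)
    nb[nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
       nb[, 3] >= 1 & nb[, 3] <= d[3], , drop = FALSE]
  }
  repeat {
    changed <- FALSE
    coords <- which(skel, arr.ind = TRUE)
    for (k in seq_len(nrow(coords))) {
      p <- coords[k, ]
      if (!skel[p[1], p[2], p[3]]) next
      nb <- neighbors(p)
      on <- nb[skel[nb], , drop = FALSE]
      if (nrow(on) != 2L) next
      u <- on[1, ]; v <- on[2, ]
      if (all(abs(u - v) <= 1L)) {           # corner: neighbours adjacent
        skel[p[1], p[2], p[3]] <- FALSE
        changed <- TRUE
        next
      }
      cur <- step_len(u, p) + step_len(p, v)
      cand <- neighbors(u)
      cand <- cand[mask[cand] & !skel[cand], , drop = FALSE]
      if (!nrow(cand)) next
      adj_v <- abs(cand[, 1] - v[1]) <= 1L & abs(cand[, 2] - v[2]) <= 1L &
               abs(cand[, 3] - v[3]) <= 1L
      cand <- cand[adj_v, , drop = FALSE]
      if (!nrow(cand)) next
      costs <- apply(cand, 1L, function(q) step_len(u, q) + step_len(q, v))
      j <- which.min(costs)
      if (costs[j] < cur - 1e-9) {
        skel[p[1], p[2], p[3]] <- FALSE
        q <- cand[j, ]
        skel[q[1], q[2], q[3]] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  skel
}

# An object merged by the connect-range rule can contain small physical gaps
# (e.g. partial-volume dimming between z-planes); its skeleton then falls
# into several components. Since the object is by definition one cilium, the
# skeleton components are joined by their shortest physical link so path
# lengths span the whole cilium.
stitch_skeleton <- function(g) {
  repeat {
    comp <- igraph::components(g)
    if (comp$no <= 1L) return(g)
    px <- igraph::vertex_attr(g, "px")
    py <- igraph::vertex_attr(g, "py")
    pz <- igraph::vertex_attr(g, "pz")
    best <- c(Inf, NA, NA)
    main <- which(comp$membership == which.max(comp$csize))
    rest <- which(comp$membership != comp$membership[main[1]])
    for (a in main) {
      dd <- sqrt((px[rest] - px[a])^2 + (py[rest] - py[a])^2 +
                 (pz[rest] - pz[a])^2)
      j <- which.min(dd)
      if (dd[j] < best[1]) best <- c(dd[j], a, rest[j])
    }
    g <- igraph::add_edges(g, c(best[2], best[3]), weight = best[1])
  }
}

# skeleton voxels -> weighted igraph; vertex attributes px/py/pz are the
# physical coordinates (um)
skeleton_graph <- function(skel, vs) {
  d <- dim(skel)
  idx <- which(skel)
  if (!length(idx)) stop("empty skeleton")
  coords <- arrayInd(idx, d)
  node_of <- integer(prod(d))
  node_of[idx] <- seq_along(idx)
  edges <- NULL
  weights <- NULL
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[with(offs, dz > 0 | (dz == 0 & dx > 0) |
                          (dz == 0 & dx == 0 & dy > 0)), ]  # half-space
  for (k in seq_len(nrow(offs))) {
    o <- unlist(offs[k, ])
    nb <- cbind(coords[, 1] + o[1], coords[, 2] + o[2], coords[, 3] + o[3])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) + d[1] * d[2] * (nb[ok, 3] - 1L)
    hit <- node_of[lin] > 0
    if (!any(hit)) next
    from <- which(ok)[hit]
    to <- node_of[lin[hit]]
    w <- sqrt((o[2] * vs[["dx"]])^2 + (o[1] * vs[["dy"]])^2 +
              (o[3] * vs[["dz"]])^2)
    edges <- rbind(edges, cbind(from, to))
    weights <- c(weights, rep(w, length(from)))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges), weight = weights)
  pts <- voxel_centers_um(coords, vs)
  igraph::vertex_attr(g, "px") <- pts[, "x"]
  igraph::vertex_attr(g, "py") <- pts[, "y"]
  igraph::vertex_attr(g, "pz") <- pts[, "z"]
  g
}

skeleton_measures <- function(g, point_tol = 0) {
  nv <- igraph::vcount(g)
  deg <- igraph::degree(g)
  tree_length <- if (igraph::ecount(g))
    sum(igraph::edge_attr(g, "weight")) else 0
  # branches per connected component: single voxel or pure cycle -> 1,
  # otherwise edges minus internal (degree-2) nodes
  comp <- igraph::components(g)
  n_branches <- 0L
  for (ci in seq_len(comp$no)) {
    vc <- which(comp$membership == ci)
    sub_deg <- deg[vc]
    ec <- sum(igraph::ends(g, igraph::E(g))[, 1] %in% vc) # edges inside comp
    if (length(vc) == 1L || all(sub_deg == 2)) n_branches <- n_branches + 1L
    else n_branches <- n_branches + (ec - sum(sub_deg == 2))
  }
  ends <- which(deg <= 1L)
  cilia_length <- 0
  bending <- NA_real_
  orientation <- c(NA_real_, NA_real_, NA_real_)
  if (length(ends) >= 2L) {
    dm <- igraph::distances(g, v = ends, to = ends)
    dm[!is.finite(dm)] <- -Inf
    best <- which(dm == max(dm), arr.ind = TRUE)[1, ]
    cilia_length <- max(dm)
    if (cilia_length > 0) {
      a <- ends[best[1]]; b <- ends[best[2]]
      pa <- c(igraph::vertex_attr(g, "px")[a], igraph::vertex_attr(g, "py")[a],
              igraph::vertex_attr(g, "pz")[a])
      pb <- c(igraph::vertex_attr(g, "px")[b], igraph::vertex_attr(g, "py")[b],
              igraph::vertex_attr(g, "pz")[b])
      chord <- sqrt(sum((pa - pb)^2))
      bending <- min(chord / cilia_length, 1)
      orientation <- (pb - pa) / max(chord, .Machine$double.eps)
    } else cilia_length <- 0
  }
  if (cilia_length <= point_tol) {
    cilia_length <- 0
    bending <- NA_real_
    orientation <- c(NA_real_, NA_real_, NA_real_)
  }
  list(n_branches = as.integer(max(n_branches, 1L)),
       tree_length_um = tree_length,
       cilia_length_um = max(cilia_length, 0),
       bending_ratio = bending,
       orientation = orientation)
}

#' Intensity statistics within an object mask
#'
#' Mean, population standard deviation, minimum and maximum of the original
#' (unsegmented) intensities at the object voxels.
#'
#' @param coords integer matrix (n x 3) of 1-based `(y, x, z)` indices.
#' @param stack an [image_stack()].
#' @param channel channel index.
#' @return named numeric: `mean`, `sd`, `min`, `max`.
#' @export
measure_intensity <- function(coords, stack, channel) {
  d <- dim(stack$voxels)
  if (channel < 1L || channel > d[4])
    stop("invalid channel index ", channel)
  coords <- matrix(as.integer(coords), ncol = 3L)
  vals <- stack$voxels[cbind(coords, channel)]
  m <- mean(vals)
  c(mean = m, sd = sqrt(mean((vals - m)^2)), min = min(vals),
    max = max(vals))
}

#' Quantify all cilia in a prepared stack
#'
#' Runs the full per-object pipeline (label, filter, measure) on a segmented
#' stack and returns one record per surviving object. Intensity statistics
#' for the reconstruction channel are taken from the unsegmented copy when
#' the prepared stack carries one; optional channels A/B are quantified
#' within the same masks.
#'
#' @param stack prepared [image_stack()] whose `reconstruction_channel` holds
#'   the segmented marker.
#' @param reconstruction_channel index of the segmented channel (default 1).
#' @param intensity_channel channel for marker intensity statistics (default:
#'   a channel labeled "unsegmented" when present, else the reconstruction
#'   channel).
#' @param channel_a,channel_b optional additional channels quantified within
#'   the ciliary masks.
#' @param min_size_voxels minimum object size (voxels).
#' @param exclude_borders logical `(x, y, z)` border-exclusion flags.
#' @param increase_range bridge small gaps when labeling.
#' @param range_voxels gap-bridging dilation radius in voxels (see
#'   [label_objects()]).
#' @param gauss_xy_sigma mask blur sigma before skeletonization (px).
#' @param z_refine,rebinarize_level skeletonization controls, see
#'   [skeletonize_and_measure()].
#' @param tool_version version string embedded in the table metadata.
#' @param verbose log progress per object.
#' @return a [cilia_table()]; the exclusion report is attached as
#'   `attr(, "exclusion_report")`.
#' @export
quantify_stack <- function(stack, reconstruction_channel = 1L,
                           intensity_channel = NULL,
                           channel_a = NULL, channel_b = NULL,
                           min_size_voxels = 10L,
                           exclude_borders = c(x = TRUE, y = TRUE, z = TRUE),
                           increase_range = TRUE, range_voxels = 1L,
                           gauss_xy_sigma = 0.5, z_refine = NULL,
                           rebinarize_level = 0.5,
                           tool_version = "v0.1.7", verbose = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (reconstruction_channel < 1L || reconstruction_channel > d[4])
    stop("reconstruction channel ", reconstruction_channel,
         " not present in the stack")
  vol <- stack$voxels[, , , reconstruction_channel, drop = TRUE]
  dim(vol) <- d[1:3]
  if (mean(vol > 0) > 0.5)
    warning("reconstruction channel does not look segmented (more than half ",
            "of the voxels are nonzero); verify that the segmentation is ",
            "good and does not contain too many background objects")
  if (is.null(intensity_channel)) {
    intensity_channel <- reconstruction_channel
    if (!is.null(stack$channel_labels)) {
      u <- which(stack$channel_labels == "unsegmented")
      if (length(u)) intensity_channel <- u[1]
    }
  }
  mask <- vol > 0
  labeled <- label_objects(mask, increase_range = increase_range,
                           range_voxels = range_voxels)
  filtered <- filter_objects(labeled, min_size_voxels = min_size_voxels,
                             exclude_borders = exclude_borders)
  lab <- filtered$labels
  n <- filtered$n_objects
  vs <- stack$voxel_size_um
  tb_all <- if (n > 0) touches_border_per_label(lab, n) else NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    coords <- arrayInd(which(lab == i), d[1:3])
    morph <- measure_morphology(coords, vs)
    # crop to bounding box with a 1-voxel pad for thinning
    lo <- pmax(apply(coords, 2, min) - 1L, 1L)
    hi <- pmin(apply(coords, 2, max) + 1L, d[1:3])
    sub <- array(FALSE, hi - lo + 1L)
    sub[sweep(coords, 2, lo - 1L, `-`)] <- TRUE
    sk <- skeletonize_and_measure(sub, vs, gauss_xy_sigma = gauss_xy_sigma,
                                  z_refine = z_refine,
                                  rebinarize_level = rebinarize_level)
    ints <- measure_intensity(coords, stack, intensity_channel)
    row <- data.frame(
      id = i,
      centroid_x_um = morph$centroid_um[["x"]],
      centroid_y_um = morph$centroid_um[["y"]],
      centroid_z_um = morph$centroid_um[["z"]],
      volume_voxels = morph$volume_voxels,
      volume_um3 = morph$volume_um3,
      surface_um2 = morph$surface_um2,
      max_span_um = morph$max_span_um,
      n_branches = sk$n_branches,
      tree_length_um = sk$tree_length_um,
      cilia_length_um = sk$cilia_length_um,
      bending_ratio = sk$bending_ratio,
      orientation_x = sk$orientation[1],
      orientation_y = sk$orientation[2],
      orientation_z = sk$orientation[3],
      intensity_mean = ints[["mean"]], intensity_sd = ints[["sd"]],
      intensity_min = ints[["min"]], intensity_max = ints[["max"]])
    if (!is.null(channel_a)) {
      ia <- measure_intensity(coords, stack, channel_a)
      row$intensity_mean_a <- ia[["mean"]]; row$intensity_sd_a <- ia[["sd"]]
      row$intensity_min_a <- ia[["min"]]; row$intensity_max_a <- ia[["max"]]
    }
    if (!is.null(channel_b)) {
      ib <- measure_intensity(coords, stack, channel_b)
      row$intensity_mean_b <- ib[["mean"]]; row$intensity_sd_b <- ib[["sd"]]
      row$intensity_min_b <- ib[["min"]]; row$intensity_max_b <- ib[["max"]]
    }
    row$touches_border_x <- as.integer(tb_all[i, "x"])
    row$touches_border_y <- as.integer(tb_all[i, "y"])
    row$touches_border_z <- as.integer(tb_all[i, "z"])
    row$excluded_reason <- "none"
    rows[[i]] <- row
    if (verbose) message("object ", i, "/", n, ": length ",
                         sprintf("%.3f", sk$cilia_length_um), " um")
  }
  rec <- if (n > 0) do.call(rbind, rows) else
    empty_record_frame(channel_a, channel_b)
  # volume_um3 stays exact (volume identity); the others are reported at the
  # table dialect's 3-decimal precision
  umcols <- intersect(c("centroid_x_um", "centroid_y_um", "centroid_z_um",
                        "surface_um2", "max_span_um",
                        "tree_length_um", "cilia_length_um", "bending_ratio",
                        "orientation_x", "orientation_y", "orientation_z"),
                      names(rec))
  rec[umcols] <- lapply(rec[umcols], function(v) round(v, 3))
  in_meta <- attr(stack, "metadata")
  settings <- list(reconstruction_channel = reconstruction_channel,
                   min_size_voxels = min_size_voxels,
                   exclude_border_x = as.integer(exclude_borders[[1]]),
                   exclude_border_y = as.integer(exclude_borders[[2]]),
                   exclude_border_z = as.integer(exclude_borders[[3]]),
                   increase_range = as.integer(increase_range),
                   gauss_xy_sigma = gauss_xy_sigma)
  if (!is.null(in_meta)) settings <- c(settings, in_meta$settings)
  tab <- cilia_table(rec, metadata = run_metadata(tool_version, settings))
  attr(tab, "exclusion_report") <- attr(filtered, "exclusion_report")
  tab
}

empty_record_frame <- function(channel_a, channel_b) {
  cols <- c("id", "centroid_x_um", "centroid_y_um", "centroid_z_um",
            "volume_voxels", "volume_um3", "surface_um2", "max_span_um",
            "n_branches", "tree_length_um", "cilia_length_um",
            "bending_ratio", "orientation_x", "orientation_y",
            "orientation_z", "intensity_mean", "intensity_sd",
            "intensity_min", "intensity_max")
  if (!is.null(channel_a))
    cols <- c(cols, "intensity_mean_a", "intensity_sd_a", "intensity_min_a",
              "intensity_max_a")
  if (!is.null(channel_b))
    cols <- c(cols, "intensity_mean_b", "intensity_sd_b", "intensity_min_b",
              "intensity_max_b")
  cols <- c(cols, "touches_border_x", "touches_border_y", "touches_border_z",
            "excluded_reason")
  df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  df$excluded_reason <- character(0)
  df
}
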