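# Synthetic phantoms: tubes of analytically known centerline arc length
# rendered into anisotropic voxel grids, plus grouped measurement tables with
# planted statistical structure. Every downstream stage is testable against
# these without any external data.

# evaluate code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Centerline specification for a synthetic cilium
#'
#' An ordered set of 3D control points (micrometers) interpolated by a natural
#' cubic spline (parameterized by cumulative chord length); the tube phantom
#' is the set of points within `radius_um` of that curve. Arc length is
#' analytic (adaptive quadrature over the spline), giving the ground-truth
#' counterpart of the pipeline's measured cilium length.
#'
#' @param control_points numeric matrix (n x 3), columns x, y, z in um; at
#'   least two points.
#' @param radius_um tube radius in um (> 0).
#' @param intensity foreground amplitude in native intensity units.
#' @return an object of class `centerline_spec` with the analytic
#'   `arc_length_um` attached.
#' @export
centerline_spec <- function(control_points, radius_um, intensity = 1000) {
  control_points <- as.matrix(control_points)
  if (nrow(control_points) < 2L || ncol(control_points) != 3L)
    stop("control_points must be an n x 3 matrix with n >= 2")
  if (radius_um <= 0) stop("radius_um must be > 0")
  obj <- structure(list(control_points = control_points,
                        radius_um = radius_um, intensity = intensity),
                   class = "centerline_spec")
  obj$arc_length_um <- arc_length(obj)
  if (obj$arc_length_um <= 0) stop("degenerate centerline: zero arc length")
  obj
}

centerline_splines <- function(spec) {
  cp <- spec$control_points
  d <- sqrt(rowSums((cp[-1, , drop = FALSE] -
                     cp[-nrow(cp), , drop = FALSE])^2))
  t <- c(0, cumsum(d))
  if (any(d == 0)) stop("coincident consecutive control points")
  list(t = t,
       fx = splinefun(t, cp[, 1], method = "natural"),
       fy = splinefun(t, cp[, 2], method = "natural"),
       fz = splinefun(t, cp[, 3], method = "natural"))
}

#' Analytic arc length of a centerline
#'
#' Adaptive quadrature of the spline speed \eqn{\lVert r'(t) \rVert} over the
#' chord-length parameterization.
#'
#' @param spec a [centerline_spec()].
#' @return arc length in um.
#' @export
arc_length <- function(spec) {
  s <- centerline_splines(spec)
  speed <- function(t)
    sqrt(s$fx(t, deriv = 1)^2 + s$fy(t, deriv = 1)^2 + s$fz(t, deriv = 1)^2)
  tot <- 0
  knots <- s$t
  for (i in seq_len(length(knots) - 1L)) {
    tot <- tot + integrate(speed, knots[i], knots[i + 1L],
                           rel.tol = 1e-10, subdivisions = 200L)$value
  }
  tot
}

#' Densely resample a centerline to a polyline
#'
#' @param spec a [centerline_spec()].
#' @param n number of points (default chosen so segment length is well below
#'   a voxel).
#' @return n x 3 matrix of points in um.
#' @export
resample_centerline <- function(spec, n = 2048L) {
  s <- centerline_splines(spec)
  tt <- seq(0, max(s$t), length.out = n)
  cbind(s$fx(tt), s$fy(tt), s$fz(tt))
}

#' Generate a random centerline inside a bounding box
#'
#' Draws a gently curved spline whose analytic arc length falls in
#' `length_range_um`: a canonical curve along x with sinusoidal lateral and
#' axial deviations of relative amplitude `curvature` is scaled exactly to a
#' target arc length (arc length is linear under uniform scaling), rotated
#' randomly in the xy-plane and translated to a random feasible position that
#' keeps the whole tube (centerline plus radius) strictly inside `bounds_um`.
#'
#' @param seed integer seed (deterministic output).
#' @param bounds_um length-3 box extents (x, y, z) in um, all > 0.
#' @param length_range_um interval for the target arc length.
#' @param curvature relative lateral deviation amplitude (0 = straight).
#' @param radius_um tube radius (um).
#' @param intensity foreground amplitude.
#' @return a [centerline_spec()].
#' @export
generate_centerline <- function(seed, bounds_um, length_range_um,
                                curvature = 0.05, radius_um = 0.25,
                                intensity = 1000) {
  bounds_um <- as.numeric(bounds_um)
  if (length(bounds_um) != 3L || any(bounds_um <= 0))
    stop("bounds_um must be three positive extents")
  if (length_range_um[1] <= 0 || length_range_um[2] < length_range_um[1])
    stop("invalid length_range_um")
  if (length_range_um[1] > sqrt(sum(bounds_um^2)))
    stop("infeasible length_range_um: minimum length ",
         length_range_um[1], " um exceeds the bounds diagonal")
  with_seed(seed, {
    for (attempt in 1:200) {
      target <- runif(1, length_range_um[1], length_range_um[2])
      tt <- seq(0, 1, length.out = 5L)
      phase <- runif(1, 0, 2 * pi)
      cp <- cbind(target * tt,
                  curvature * target * sin(pi * tt) * runif(1, 0.5, 1),
                  0.3 * curvature * target * sin(2 * pi * tt + phase))
      spec0 <- centerline_spec(cp, radius_um, intensity)
      cp <- cp * (target / spec0$arc_length_um)   # exact: arc is scale-linear
      ang <- runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
                    3, 3)
      cp <- cp %*% rot
      margin <- radius_um * 1.5 + 1e-6
      lo <- apply(cp, 2, min)
      hi <- apply(cp, 2, max)
      room <- bounds_um - (hi - lo) - 2 * margin
      if (any(room < 0)) next
      shift <- margin - lo + runif(3, 0, 1) * room
      cp <- sweep(cp, 2, shift, `+`)
      spec <- centerline_spec(cp, radius_um, intensity)
      if (spec$arc_length_um >= length_range_um[1] - 1e-9 &&
          spec$arc_length_um <= length_range_um[2] + 1e-9)
        return(spec)
    }
    stop("could not place a centerline of the requested length inside ",
         "bounds after 200 attempts (infeasible length_range for bounds)")
  })
}

#' Ground truth for a synthetic scene
#'
#' Bundles centerlines, their analytic arc lengths, the voxel grid geometry
#' and the corruption model (PSF blur widths, background offset, Gaussian
#' noise at a stated signal-to-noise ratio) with the seed that renders the
#' scene deterministic.
#'
#' @param centerlines list of [centerline_spec()].
#' @param voxel_size_um `(dx, dy, dz)` in um.
#' @param snr ratio of foreground amplitude to background-noise standard
#'   deviation (`Inf` = noise-free).
#' @param background_level additive offset in native intensity units.
#' @param psf_sigma_um per-axis Gaussian blur sigmas `(x, y, z)` in um.
#' @param seed integer seed used by [rasterize_scene()].
#' @return an object of class `phantom_truth`.
#' @export
phantom_truth <- function(centerlines, voxel_size_um = c(0.08, 0.08, 0.5),
                          snr = Inf, background_level = 0,
                          psf_sigma_um = c(0, 0, 0), seed = 1L) {
  stopifnot(is.list(centerlines),
            all(vapply(centerlines, inherits, TRUE, "centerline_spec")))
  voxel_size_um <- as.numeric(voxel_size_um)
  if (any(voxel_size_um <= 0)) stop("voxel sizes must be positive")
  if (!(snr > 0)) stop("snr must be > 0")
  structure(list(centerlines = centerlines,
                 arc_lengths_um = vapply(centerlines,
                                         function(s) s$arc_length_um, 0),
                 voxel_size_um = setNames(voxel_size_um, c("dx", "dy", "dz")),
                 snr = snr, background_level = background_level,
                 psf_sigma_um = psf_sigma_um, seed = as.integer(seed)),
            class = "phantom_truth")
}

#' Rasterize a phantom scene into an image stack
#'
#' Voxels whose centers lie within `radius_um` of a centerline (anisotropic
#' physical distance) receive that tube's foreground amplitude; the scene is
#' then blurred per axis with the PSF sigmas (physical units), offset by the
#' background level, and corrupted with additive Gaussian noise of standard
#' deviation `amplitude / snr`. Deterministic given the truth's seed.
#'
#' @param truth a [phantom_truth()].
#' @param shape voxel grid dimensions `(nx, ny, nz)`.
#' @param bit_depth output bit depth (intensities are rounded and clamped).
#' @param antialias emulate partial-volume integration by sub-voxel
#'   supersampling (what an integrating detector records; default). With
#'   `FALSE`, a voxel is foreground exactly when its center lies within the
#'   tube radius (the idealized binary contract used by exact-count
#'   oracles).
#' @return an [image_stack()] with one channel.
#' @export
rasterize_scene <- function(truth, shape, bit_depth = 16L,
                            antialias = TRUE) {
  stopifnot(inherits(truth, "phantom_truth"))
  shape <- as.integer(shape)
  vs <- truth$voxel_size_um
  extent <- shape * vs                      # physical extents (x, y, z)
  dims <- c(shape[2], shape[1], shape[3])   # array dims (ny, nx, nz)
  img <- array(0, dims)
  for (i in seq_along(truth$centerlines)) {
    cl <- truth$centerlines[[i]]
    poly <- resample_centerline(cl, n = max(64L, ceiling(
      cl$arc_length_um / (min(vs) / 4)) + 1L))
    lo <- apply(poly, 2, min) - cl$radius_um
    hi <- apply(poly, 2, max) + cl$radius_um
    if (any(lo < 0) || any(hi > extent))
      stop("centerline ", i, " exits the voxel grid (tube extent [",
           paste(sprintf("%.3f", lo), collapse = ", "), "] - [",
           paste(sprintf("%.3f", hi), collapse = ", "),
           "] um vs grid [0,0,0] - [",
           paste(sprintf("%.3f", extent), collapse = ", "), "] um)")
    nsub <- if (antialias) c(3L, 3L, 5L) else c(1L, 1L, 1L)
    fg <- cpp_tube_fill(dims, as.numeric(vs), poly, cl$radius_um, nsub)
    img <- pmax(img, cl$intensity * array(as.numeric(fg), dims))
  }
  sig_px <- c(truth$psf_sigma_um[2] / vs[2],   # y
              truth$psf_sigma_um[1] / vs[1],   # x
              truth$psf_sigma_um[3] / vs[3])   # z
  if (any(sig_px > 0))
    img <- cpp_gauss3d(img, dims, sig_px[1], sig_px[2], sig_px[3])
  img <- img + truth$background_level
  if (is.finite(truth$snr)) {
    # snr describes the image as acquired: the realized (post-PSF) foreground
    # amplitude over the background-noise standard deviation
    amp <- max(max(img) - truth$background_level, 1)
    img <- with_seed(truth$seed,
                     img + array(rnorm(length(img), 0, amp / truth$snr), dims))
  }
  img <- pmin(pmax(round(img), 0), 2^bit_depth - 1)
  image_stack(array(img, c(dims, 1L)), vs, bit_depth = bit_depth,
              channel_labels = "marker")
}

#' Group specification for synthetic measurement tables
#'
#' Defines one experimental condition: how many replicates, how many cilia
#' per replicate, the sampling distribution per measurement and a planted
#' effect (shift relative to a reference group).
#'
#' @param group_label condition name (becomes the folder name).
#' @param n_replicates number of replicate tables (>= 1).
#' @param cilia_per_replicate records per table (>= 1).
#' @param distribution `"normal"` or `"lognormal"` (lognormal interprets
#'   location/scale as meanlog/sdlog).
#' @param location,scale per-measurement parameters: scalars or named vectors
#'   over measurement names.
#' @param effect per-measurement shift added to `location`.
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(group_label, n_replicates, cilia_per_replicate,
                       distribution = c("normal", "lognormal"),
                       location = 0, scale = 1, effect = 0) {
  distribution <- match.arg(distribution)
  if (n_replicates < 1L || cilia_per_replicate < 1L)
    stop("n_replicates and cilia_per_replicate must be >= 1")
  if (any(scale <= 0)) stop("scale must be > 0")
  structure(list(group_label = group_label,
                 n_replicates = as.integer(n_replicates),
                 cilia_per_replicate = as.integer(cilia_per_replicate),
                 distribution = distribution, location = location,
                 scale = scale, effect = effect),
            class = "group_spec")
}

param_for <- function(p, measurement, default) {
  if (is.null(names(p))) {
    if (length(p) == 1L) return(as.numeric(p))
    stop("unnamed multi-valued parameter")
  }
  if (measurement %in% names(p)) as.numeric(p[[measurement]]) else default
}

#' Generate grouped measurement tables on disk
#'
#' Writes one folder per group under `dir`, one TSV table per replicate, each
#' carrying an identical synthetic tool-version tag by default; sample moments
#' converge to the specified parameters as counts grow.
#'
#' @param specs list of [group_spec()]; group labels must be unique.
#' @param measurements character vector of unique measurement names.
#' @param seed integer seed (deterministic output).
#' @param dir parent directory to write group folders into.
#' @param tool_version version tag embedded in every table's metadata.
#' @return a [grouped_dataset()] pooled from the written folders.
#' @export
generate_grouped_tables <- function(specs, measurements, seed, dir,
                                    tool_version = "v0.1.7") {
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, TRUE, "group_spec")))
  labels <- vapply(specs, function(s) s$group_label, "")
  if (anyDuplicated(labels))
    stop("duplicate group labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (anyDuplicated(measurements)) stop("measurement names must be unique")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    for (sp in specs) {
      gdir <- file.path(dir, sp$group_label)
      dir.create(gdir, showWarnings = FALSE)
      for (r in seq_len(sp$n_replicates)) {
        n <- sp$cilia_per_replicate
        rec <- data.frame(id = seq_len(n))
        for (m in measurements) {
          loc <- param_for(sp$location, m, 0) + param_for(sp$effect, m, 0)
          sc <- param_for(sp$scale, m, 1)
          rec[[m]] <- if (sp$distribution == "normal")
            rnorm(n, loc, sc) else rlnorm(n, loc, sc)
        }
        tab <- cilia_table(rec,
                           metadata = run_metadata(tool_version),
                           source_image = sprintf("replicate_%02d", r),
                           group_label = sp$group_label,
                           replicate_id = sprintf("replicate_%02d", r))
        write_cilia_table(tab, file.path(gdir,
                                         sprintf("replicate_%02d.tsv", r)))
      }
    }
  })
  pool_groups(file.path(dir, labels))
}
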