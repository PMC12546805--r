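#' Multi-channel 3D image stack
#'
#' The in-memory container for confocal z-stacks. Voxels are stored as a
#' 4-dimensional array in the canonical axis order `(y, x, z, channel)`
#' (column-major friendly in R); physical voxel sizes are carried alongside in
#' micrometers so every downstream measurement can be reported in physical
#' units. Intensities are kept numeric but must lie within the declared bit
#' depth range.
#'
#' @param voxels numeric array, either 3D `(y, x, z)` for a single channel or
#'   4D `(y, x, z, channel)`.
#' @param voxel_size_um numeric length-3 vector `(dx, dy, dz)` in micrometers;
#'   `dx`/`dy` are the lateral pixel sizes, `dz` the z-step interval.
#' @param bit_depth integer, one of 8, 12, 16.
#' @param channel_labels optional character vector naming the channels.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size_um, bit_depth = 16L,
                        channel_labels = NULL) {
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L)
    stop("voxels must be a 3D (y,x,z) or 4D (y,x,z,channel) array")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("voxel_size_um must be three positive numbers (dx, dy, dz)")
  if (!bit_depth %in% c(8L, 12L, 16L)) stop("bit_depth must be 8, 12 or 16")
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
    stop("intensities outside the representable range for bit depth ",
         bit_depth)
  if (dim(voxels)[3] < 1L || dim(voxels)[4] < 1L)
    stop("stack needs at least one z-slice and one channel")
  if (!is.null(channel_labels) && length(channel_labels) != dim(voxels)[4])
    stop("channel_labels length must match the number of channels")
  structure(list(voxels = voxels,
                 voxel_size_um = setNames(voxel_size_um, c("dx", "dy", "dz")),
                 bit_depth = as.integer(bit_depth),
                 channel_labels = channel_labels),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d px, %d slices, %d channel(s), %d-bit\n",
              d[2], d[1], d[3], d[4], x$bit_depth))
  cat(sprintf("  voxel size: %.4g x %.4g x %.4g um\n",
              x$voxel_size_um["dx"], x$voxel_size_um["dy"],
              x$voxel_size_um["dz"]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Write an image stack to a multi-page TIFF with a metadata sidecar
#'
#' Pages are written z-major, channel-fastest (page = (z-1)*C + c). Because
#' baseline TIFF has no portable slot for the z-step, the voxel sizes, bit
#' depth and channel count are written to a plain-text sidecar file
#' (`<stem>_meta.txt`) next to the image, which [read_image_stack()] reads
#' back.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  scale <- 2^stack$bit_depth - 1
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (z in seq_len(d[3])) for (ch in seq_len(d[4])) {
    pages[[k]] <- stack$voxels[, , z, ch] / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- c(
    sprintf("voxel_size_x_um\t%.10g", stack$voxel_size_um["dx"]),
    sprintf("voxel_size_y_um\t%.10g", stack$voxel_size_um["dy"]),
    sprintf("voxel_size_z_um\t%.10g", stack$voxel_size_um["dz"]),
    sprintf("bit_depth\t%d", stack$bit_depth),
    sprintf("n_channels\t%d", d[4]),
    sprintf("n_slices\t%d", d[3]))
  if (!is.null(stack$channel_labels))
    meta <- c(meta, sprintf("channel_labels\t%s",
                            paste(stack$channel_labels, collapse = ",")))
  writeLines(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_meta.txt")
}

#' Read a multi-page TIFF into an image stack
#'
#' Axes are normalized to the package's canonical `(y, x, z, channel)` order.
#' Voxel sizes are taken from the metadata sidecar written by
#' [write_image_stack()]; without a sidecar they must be supplied via
#' `voxel_size_um` because all morphometric outputs are in micrometers and
#' cannot be computed otherwise.
#'
#' @param path TIFF path.
#' @param voxel_size_um optional override `(dx, dy, dz)` in micrometers.
#' @param n_channels number of channels if no sidecar is present (default 1).
#' @param bit_depth bit depth if no sidecar is present (default 16).
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, voxel_size_um = NULL, n_channels = NULL,
                             bit_depth = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    kv <- strsplit(readLines(sp), "\t", fixed = TRUE)
    meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  }
  if (is.null(voxel_size_um)) {
    if (is.null(meta))
      stop("voxel size metadata not found for ", path,
           " and no voxel_size_um override given; physical measurements ",
           "in um cannot be computed")
    voxel_size_um <- as.numeric(meta[c("voxel_size_x_um", "voxel_size_y_um",
                                       "voxel_size_z_um")])
  }
  if (is.null(n_channels))
    n_channels <- if (!is.null(meta)) as.integer(meta[["n_channels"]]) else 1L
  if (is.null(bit_depth))
    bit_depth <- if (!is.null(meta)) as.integer(meta[["bit_depth"]]) else 16L
  labels <- if (!is.null(meta) && "channel_labels" %in% names(meta))
    strsplit(meta[["channel_labels"]], ",", fixed = TRUE)[[1]] else NULL
  n_pages <- length(pages)
  if (n_pages %% n_channels != 0L)
    stop("page count ", n_pages, " not divisible by channel count ",
         n_channels)
  nz <- n_pages %/% n_channels
  d2 <- dim(pages[[1]])[1:2]
  voxels <- array(0, c(d2[1], d2[2], nz, n_channels))
  scale <- 2^bit_depth - 1
  k <- 1L
  for (z in seq_len(nz)) for (ch in seq_len(n_channels)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # grayscale written as planar
    voxels[, , z, ch] <- round(pg * scale)
    k <- k + 1L
  }
  image_stack(voxels, voxel_size_um, bit_depth, labels)
}
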