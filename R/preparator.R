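# Preparator stage: preprocessing (background subtraction, Gaussian blur),
# threshold selection, hysteresis segmentation, segmentation styles, and
# programmatic mask edits. Turns a raw multi-channel stack into a
# segmentation-ready stack.

#' Segmentation settings
#'
#' The parameter record of a segmentation run. `method` is either the name of
#' an auto-threshold algorithm (see [auto_threshold()]), a manual numeric
#' value, or `hysteresis(low, high)` given as `list(low = ..., high = ...)`
#' where each element is again a method name or value.
#'
#' @param channel_index which channel holds the ciliary marker (1-based).
#' @param include_unsegmented_copy append the original channel to the output.
#' @param bg_radius_px optional rolling-ball background-subtraction radius.
#' @param blur_sigma_px optional Gaussian blur sigma (pixels, applied
#'   slice-wise).
#' @param method threshold method name, numeric manual value, or
#'   `list(low=, high=)` for hysteresis.
#' @param style `"keep-intensities"` (zero sub-threshold voxels, keep the
#'   rest) or `"binary"` (supra-threshold voxels set to the maximum
#'   representable intensity).
#' @param histogram_source `"max-projection"` (default: threshold computed on
#'   the maximum-intensity projection, mirroring manual threshold testing) or
#'   `"full-stack"`.
#' @return an object of class `segmentation_settings`.
#' @export
segmentation_settings <- function(channel_index = 1L,
                                  include_unsegmented_copy = FALSE,
                                  bg_radius_px = NULL, blur_sigma_px = NULL,
                                  method = "Otsu",
                                  style = c("keep-intensities", "binary"),
                                  histogram_source = c("max-projection",
                                                       "full-stack")) {
  style <- match.arg(style)
  histogram_source <- match.arg(histogram_source)
  structure(list(channel_index = as.integer(channel_index),
                 include_unsegmented_copy = isTRUE(include_unsegmented_copy),
                 bg_radius_px = bg_radius_px, blur_sigma_px = blur_sigma_px,
                 method = method, style = style,
                 histogram_source = histogram_source),
            class = "segmentation_settings")
}

#' Rolling-ball background subtraction (slice-wise)
#'
#' Estimates the background of every z-slice by grayscale morphological
#' opening with a disc of the given radius and subtracts it, clamping at
#' zero. A constant image maps to the zero image; isolated bright spots
#' narrower than the disc are preserved.
#'
#' @param stack an [image_stack()].
#' @param radius_px disc radius in pixels (> 0, smaller than the image).
#' @param channel channel to process (default: all channels).
#' @return a background-subtracted [image_stack()].
#' @export
subtract_background <- function(stack, radius_px, channel = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (radius_px <= 0) stop("radius_px must be > 0")
  if (2 * radius_px + 1 > max(d[1], d[2]))
    stop("radius_px ", radius_px, " exceeds the image extent")
  brush <- EBImage::makeBrush(2 * floor(radius_px) + 1, shape = "disc")
  chans <- if (is.null(channel)) seq_len(d[4]) else channel
  out <- stack$voxels
  scale <- 2^stack$bit_depth - 1
  for (ch in chans) for (z in seq_len(d[3])) {
    sl <- stack$voxels[, , z, ch] / scale
    bg <- EBImage::opening(sl, brush)
    out[, , z, ch] <- pmax(sl - bg, 0) * scale
  }
  image_stack(out, stack$voxel_size_um, stack$bit_depth,
              stack$channel_labels)
}

#' Gaussian blur (slice-wise)
#'
#' Smooths every z-slice with an isotropic 2D Gaussian of the given sigma.
#' `sigma_px = 0` is the identity; total intensity is conserved away from the
#' borders (border kernels are renormalized).
#'
#' @param stack an [image_stack()].
#' @param sigma_px Gaussian sigma in pixels (>= 0).
#' @param channel channel to process (default: all channels).
#' @return a blurred [image_stack()].
#' @export
gaussian_blur <- function(stack, sigma_px, channel = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (sigma_px < 0) stop("sigma_px must be >= 0")
  if (sigma_px == 0) return(stack)
  d <- dim(stack$voxels)
  chans <- if (is.null(channel)) seq_len(d[4]) else channel
  out <- stack$voxels
  for (ch in chans) {
    vol <- stack$voxels[, , , ch, drop = TRUE]
    dim(vol) <- d[1:3]
    out[, , , ch] <- cpp_gauss3d(vol, d[1:3], sigma_px, sigma_px, 0)
  }
  image_stack(pmin(out, 2^stack$bit_depth - 1), stack$voxel_size_um,
              stack$bit_depth, stack$channel_labels)
}

# evaluate a threshold specification (method name or manual value) on a
# histogram; manual values are passed through after range checking
eval_threshold <- function(spec, histogram, bit_depth) {
  if (is.numeric(spec)) {
    if (spec < 0 || spec > 2^bit_depth - 1)
      stop("manual threshold ", spec, " outside the ", bit_depth,
           "-bit range")
    return(spec)
  }
  auto_threshold(histogram, method = spec)
}

#' Hysteresis segmentation
#'
#' Keeps the low-threshold 26-connected components (3D) that contain at least
#' one voxel above the high threshold: the high threshold finds the cilia,
#' the low threshold expands each to its full extent. The result always
#' satisfies `mask(high)` \eqn{\subseteq} result \eqn{\subseteq} `mask(low)`.
#'
#' @param stack an [image_stack()].
#' @param low,high threshold method names or manual values; evaluated low
#'   must not exceed evaluated high.
#' @param channel marker channel.
#' @param histogram_source `"max-projection"` or `"full-stack"`.
#' @return logical 3D array mask; evaluated thresholds in attributes
#'   `low`/`high`.
#' @export
hysteresis_segment <- function(stack, low, high, channel = 1L,
                               histogram_source = "max-projection") {
  stopifnot(inherits(stack, "image_stack"))
  h <- channel_histogram(stack, channel, histogram_source)
  tl <- eval_threshold(low, h, stack$bit_depth)
  th <- eval_threshold(high, h, stack$bit_depth)
  if (tl > th)
    stop("hysteresis requires low <= high after evaluation (low = ", tl,
         ", high = ", th, ")")
  vol <- stack$voxels[, , , channel, drop = TRUE]
  dim(vol) <- dim(stack$voxels)[1:3]
  mask_low <- vol > tl
  mask_high <- vol > th
  lab <- cpp_label3d(mask_low, dim(mask_low), 26L)
  keep <- unique(lab[mask_high])
  keep <- keep[keep > 0]
  res <- array(lab %in% keep, dim(mask_low))
  attr(res, "low") <- tl
  attr(res, "high") <- th
  res
}

channel_histogram <- function(stack, channel, histogram_source) {
  d <- dim(stack$voxels)
  if (channel < 1L || channel > d[4]) stop("invalid channel index ", channel)
  vol <- stack$voxels[, , , channel, drop = TRUE]
  dim(vol) <- d[1:3]
  vals <- if (histogram_source == "max-projection")
    apply(vol, c(1, 2), max) else vol
  intensity_histogram(vals, n_bins = 2^stack$bit_depth)
}

#' Segment a stack
#'
#' Computes the threshold on the configured histogram source (default: the
#' maximum-intensity projection of the marker channel), applies it voxel-wise
#' to the full 3D stack, and renders the configured segmentation style:
#' `keep-intensities` zeroes sub-threshold voxels and preserves the rest
#' (a background-removed image); `binary` sets supra-threshold voxels to the
#' maximum representable intensity. Optional preprocessing (background
#' subtraction, Gaussian blur) is applied first. The settings and evaluated
#' threshold are persisted in the returned stack's `metadata` attribute.
#'
#' An empty mask (no voxel above threshold) produces a warning, not an error.
#'
#' @param stack an [image_stack()].
#' @param settings a [segmentation_settings()].
#' @param tool_version version string recorded in the run metadata.
#' @return an [image_stack()] whose first channel is the segmented marker
#'   channel, with the unsegmented copy appended as a second channel if
#'   requested; `attr(, "metadata")` holds the [run_metadata()].
#' @export
segment_stack <- function(stack, settings, tool_version = "v0.1.7") {
  stopifnot(inherits(stack, "image_stack"),
            inherits(settings, "segmentation_settings"))
  d <- dim(stack$voxels)
  if (settings$channel_index < 1L || settings$channel_index > d[4])
    stop("invalid channel index ", settings$channel_index)
  work <- stack
  if (!is.null(settings$bg_radius_px))
    work <- subtract_background(work, settings$bg_radius_px,
                                channel = settings$channel_index)
  if (!is.null(settings$blur_sigma_px) && settings$blur_sigma_px > 0)
    work <- gaussian_blur(work, settings$blur_sigma_px,
                          channel = settings$channel_index)
  vol <- work$voxels[, , , settings$channel_index, drop = TRUE]
  dim(vol) <- d[1:3]
  if (is.list(settings$method)) {
    mask <- hysteresis_segment(work, settings$method$low,
                               settings$method$high,
                               channel = settings$channel_index,
                               histogram_source = settings$histogram_source)
    thr <- c(low = attr(mask, "low"), high = attr(mask, "high"))
    thr_label <- sprintf("hysteresis(%g,%g)", thr["low"], thr["high"])
  } else {
    h <- channel_histogram(work, settings$channel_index,
                           settings$histogram_source)
    t <- eval_threshold(settings$method, h, work$bit_depth)
    mask <- vol > t
    thr <- c(value = t)
    thr_label <- as.character(if (is.numeric(settings$method)) "manual"
                              else settings$method)
  }
  if (!any(mask))
    warning("empty mask: no voxel above threshold")
  maxint <- 2^stack$bit_depth - 1
  seg <- if (settings$style == "keep-intensities") vol * mask
         else maxint * mask
  # the unsegmented copy is the original (un-preprocessed) channel
  raw <- stack$voxels[, , , settings$channel_index, drop = TRUE]
  out <- if (settings$include_unsegmented_copy)
    array(c(seg, raw), c(d[1:3], 2L)) else array(seg, c(d[1:3], 1L))
  res <- image_stack(out, stack$voxel_size_um, stack$bit_depth,
                     if (settings$include_unsegmented_copy)
                       c("segmented", "unsegmented") else "segmented")
  attr(res, "metadata") <- run_metadata(
    tool_version,
    settings = c(list(channel_index = settings$channel_index,
                      style = settings$style,
                      histogram_source = settings$histogram_source,
                      method = thr_label),
                 if (!is.null(settings$bg_radius_px))
                   list(bg_radius_px = settings$bg_radius_px),
                 if (!is.null(settings$blur_sigma_px))
                   list(blur_sigma_px = settings$blur_sigma_px),
                 as.list(setNames(as.numeric(thr),
                                  paste0("threshold_", names(thr))))))
  res
}

#' Programmatic mask edit
#'
#' Adds or removes a voxel region from a binary mask (the scripted
#' counterpart of interactive ROI editing). All other voxels are untouched;
#' the edit is appended to the mask's edit log attribute.
#'
#' @param mask logical 3D array.
#' @param region integer matrix (n x 3) of 1-based `(y, x, z)` voxel indices.
#' @param mode `"add"` or `"remove"`.
#' @return the edited mask.
#' @export
apply_mask_edit <- function(mask, region, mode = c("add", "remove")) {
  mode <- match.arg(mode)
  region <- matrix(as.integer(region), ncol = 3L)
  d <- dim(mask)
  bad <- region[, 1] < 1L | region[, 1] > d[1] |
         region[, 2] < 1L | region[, 2] > d[2] |
         region[, 3] < 1L | region[, 3] > d[3]
  if (any(bad))
    stop("out-of-bounds voxels in edit region: ",
         paste(apply(region[bad, , drop = FALSE], 1L, paste, collapse = ","),
               collapse = "; "))
  mask[region] <- mode == "add"
  log <- c(attr(mask, "edit_log"),
           sprintf("%s %d voxel(s)", mode, nrow(region)))
  attr(mask, "edit_log") <- log
  mask
}

#' Optical resolution and Nyquist sampling interval
#'
#' Rayleigh lateral resolution `0.61 * lambda / NA` and the corresponding
#' Nyquist interval (half the resolution: the voxel size should be no larger
#' than half the optical resolution). Raw values are returned in nanometers;
#' rounding is left to the caller.
#'
#' @param emission_wavelength_nm emission wavelength in nm (> 0).
#' @param numerical_aperture objective NA (0 < NA <= 1.7).
#' @return named numeric: `resolution_nm`, `nyquist_nm`.
#' @export
compute_sampling_limits <- function(emission_wavelength_nm,
                                    numerical_aperture) {
  if (emission_wavelength_nm <= 0) stop("wavelength must be > 0")
  if (numerical_aperture <= 0 || numerical_aperture > 1.7)
    stop("numerical aperture must be in (0, 1.7]")
  res <- 0.61 * emission_wavelength_nm / numerical_aperture
  c(resolution_nm = res, nyquist_nm = res / 2)
}
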