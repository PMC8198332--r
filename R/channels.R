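#' Three-channel stack of registered fluorescence rasters
#'
#' Bundles the three grayscale channels of a follicular-tissue micrograph with
#' the physical pixel size. The marker channel carries the basal-lamina or
#' cathepsin stain (green role), the cytoplasm channel a whole-cytoplasm stain
#' such as CellMask Orange (red role), and the nuclei channel a DNA stain such
#' as Draq5 (blue role).
#'
#' @param marker,cytoplasm,nuclei Numeric matrices of identical dimensions
#'   with non-negative, finite intensities.
#' @param pixel_size Physical size of one pixel edge in micrometres (> 0).
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(marker, cytoplasm, nuclei, pixel_size) {
  check_matrix2d(marker, "marker")
  check_matrix2d(cytoplasm, "cytoplasm")
  check_matrix2d(nuclei, "nuclei")
  check_same_shape(marker, cytoplasm, "marker", "cytoplasm")
  check_same_shape(marker, nuclei, "marker", "nuclei")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop_arg("`pixel_size` must be a single positive number (um per pixel)")
  }
  for (ch in list(marker, cytoplasm, nuclei)) {
    if (anyNA(ch) || any(!is.finite(ch)) || any(ch < 0)) {
      stop_arg("channel intensities must be non-negative finite numbers")
    }
  }
  structure(
    list(marker = marker, cytoplasm = cytoplasm, nuclei = nuclei,
         pixel_size = pixel_size),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> %d x %d px, %.4g um/px\n",
              nrow(x$marker), ncol(x$marker), x$pixel_size))
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$marker)

#' Split a three-channel raster into its channel stack
#'
#' Maps the planes of an `height x width x 3` array onto the marker, cytoplasm
#' and nuclei roles according to `channel_order`, mirroring the splitting of an
#' RGB micrograph into its stain channels.
#'
#' @param image A numeric array with exactly three planes along the third
#'   dimension.
#' @param pixel_size Micrometres per pixel.
#' @param channel_order Character vector naming the role of each plane, a
#'   permutation of `c("marker", "cytoplasm", "nuclei")`.
#' @return A [channel_stack()].
#' @seealso [merge_gray()] for the grayscale merge used by the morphometry
#'   pipeline.
#' @export
split_channels <- function(image, pixel_size,
                           channel_order = c("marker", "cytoplasm", "nuclei")) {
  if (!is.array(image) || length(dim(image)) != 3L) {
    stop_arg(sprintf("`image` must be a 3-D array; got %s dimensions",
                     paste(length(dim(image)), collapse = " ")),
             class = "thyromorph_format_error")
  }
  nch <- dim(image)[3L]
  if (nch != 3L) {
    stop_arg(sprintf("`image` must have exactly 3 channels; found %d", nch),
             class = "thyromorph_format_error")
  }
  if (!setequal(channel_order, c("marker", "cytoplasm", "nuclei")) ||
      length(channel_order) != 3L) {
    stop_arg("`channel_order` must be a permutation of marker/cytoplasm/nuclei")
  }
  planes <- list(image[, , 1L], image[, , 2L], image[, , 3L])
  names(planes) <- channel_order
  channel_stack(planes$marker, planes$cytoplasm, planes$nuclei, pixel_size)
}

#' Grayscale merge of a channel stack
#'
#' Unweighted mean of the three channels; the "all tissue" image of the
#' morphometry pipeline is obtained by thresholding this merge.
#'
#' @param stack A [channel_stack()].
#' @return A numeric matrix.
#' @export
merge_gray <- function(stack) {
  stopifnot(inherits(stack, "channel_stack"))
  (stack$marker + stack$cytoplasm + stack$nuclei) / 3
}

#' Binarize a channel at a fixed threshold
#'
#' A pixel is foreground iff its intensity is greater than or equal to
#' `threshold` (inclusive, so saturated pixels are kept). The threshold is
#' recorded on the mask as provenance. In a batch run the same threshold is
#' applied to every image of the batch.
#'
#' @param channel A numeric matrix.
#' @param threshold A single finite intensity value.
#' @param source Optional provenance tag naming the source channel.
#' @return A logical matrix with attributes `source` and `threshold`.
#' @export
apply_threshold <- function(channel, threshold, source = NA_character_) {
  check_matrix2d(channel, "channel")
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    stop_arg("`threshold` must be a single finite number")
  }
  new_binary_mask(channel >= threshold, source = source, threshold = threshold)
}

#' Otsu threshold for a channel
#'
#' Automatic fallback for batches whose manual threshold is unknown. It is not
#' used by default anywhere in the pipeline: batch thresholds are configuration
#' values.
#'
#' @param channel A numeric matrix with intensities in `[0, 1]`.
#' @param levels Number of histogram bins.
#' @return A single threshold value.
#' @export
otsu_threshold <- function(channel, levels = 256L) {
  check_matrix2d(channel, "channel")
  EBImage::otsu(EBImage::Image(channel), range = c(0, 1), levels = levels)
}

#' Morphological closing followed by skeletonization
#'
#' Structures a thresholded boundary-stain mask by closing single-pixel gaps
#' (3 x 3 closing) and reducing it to a one-pixel-wide skeleton (Zhang-Suen
#' thinning). A gap-free ring stays a single closed curve; thinning runs to
#' convergence and is therefore idempotent on its own output.
#'
#' @param mask A logical matrix.
#' @return A logical matrix containing the skeleton.
#' @export
close_and_skeletonize <- function(mask) {
  mask <- as_binary_mask(mask)
  if (!any(mask)) return(new_binary_mask(mask, source = "skeleton"))
  closed <- EBImage::closing(EBImage::Image(mask * 1),
                             EBImage::makeBrush(3, shape = "box"))
  closed <- EBImage::imageData(closed) > 0.5
  new_binary_mask(cpp_thin(closed), source = "skeleton")
}

#' Logical complement of a mask
#'
#' @param mask A logical matrix.
#' @return A logical matrix.
#' @export
invert_mask <- function(mask) {
  mask <- as_binary_mask(mask)
  new_binary_mask(!mask, source = "inverted")
}

#' Boundary image for follicle propagation
#'
#' Subtracts the skeletonized boundary stain from the all-tissue mask: a pixel
#' is passable iff it is tissue and not on the skeleton. Skeleton pixels act as
#' barriers during seeded propagation ([propagate_follicles()]).
#'
#' @param all_tissue Logical matrix marking all tissue pixels.
#' @param skeleton Logical matrix containing the basal-lamina skeleton.
#' @return A logical matrix.
#' @export
build_boundary_image <- function(all_tissue, skeleton) {
  all_tissue <- as_binary_mask(all_tissue, "all_tissue")
  skeleton <- as_binary_mask(skeleton, "skeleton")
  check_same_shape(all_tissue, skeleton, "all_tissue", "skeleton")
  new_binary_mask(all_tissue & !skeleton, source = "boundary")
}
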