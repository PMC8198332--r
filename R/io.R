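#' Read a three-channel image into a channel stack
#'
#' Accepts a single multi-channel TIFF (planes in `channel_order`) or a
#' character vector of three single-channel PNG/TIFF paths, one per role in
#' `channel_order`.
#'
#' @param path One TIFF path or three per-channel paths.
#' @param pixel_size Micrometres per pixel.
#' @param channel_order Role of each plane / file.
#' @return A [channel_stack()].
#' @export
read_channel_stack <- function(path, pixel_size,
                               channel_order = c("marker", "cytoplasm", "nuclei")) {
  read_one <- function(p) {
    if (!file.exists(p)) {
      stop_arg(sprintf("no such file: '%s'", p), class = "thyromorph_io_error")
    }
    if (grepl("\\.png$", p, ignore.case = TRUE)) {
      png::readPNG(p)
    } else {
      tiff::readTIFF(p)
    }
  }
  if (length(path) == 3L) {
    planes <- lapply(path, function(p) {
      img <- read_one(p)
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      img
    })
    arr <- array(0, dim = c(dim(planes[[1]]), 3L))
    for (k in 1:3) arr[, , k] <- planes[[k]]
    split_channels(arr, pixel_size, channel_order)
  } else if (length(path) == 1L) {
    img <- read_one(path)
    if (length(dim(img)) != 3L) {
      stop_arg("single-file input must be a multi-channel image",
               class = "thyromorph_format_error")
    }
    split_channels(img, pixel_size, channel_order)
  } else {
    stop_arg("`path` must be one multi-channel file or three channel files")
  }
}

#' Write a channel stack as a multi-channel TIFF
#'
#' Planes are written in marker, cytoplasm, nuclei order.
#'
#' @param stack A [channel_stack()].
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
write_channel_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  arr <- array(0, dim = c(dim(stack$marker), 3L))
  arr[, , 1L] <- pmin(pmax(stack$marker, 0), 1)
  arr[, , 2L] <- pmin(pmax(stack$cytoplasm, 0), 1)
  arr[, , 3L] <- pmin(pmax(stack$nuclei, 0), 1)
  tiff::writeTIFF(arr, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask A logical matrix.
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a label map as a 16-bit single-channel TIFF
#'
#' Labels are stored as intensities `label / 65535`; [read_labels()] inverts
#' the scaling. Label maps with more than 65535 objects are not supported by
#' this container.
#'
#' @param labels An integer label map.
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
write_labels <- function(labels, path) {
  check_matrix2d(labels, "labels")
  if (n_labels(labels) > 65535L) {
    stop_arg("more than 65535 labels cannot be stored in 16-bit TIFF",
             class = "thyromorph_io_error")
  }
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label map written by [write_labels()]
#'
#' @param path TIFF path.
#' @param kind Object kind tag to attach.
#' @return An integer label map.
#' @export
read_labels <- function(path, kind = "lumen") {
  if (!file.exists(path)) {
    stop_arg(sprintf("no such file: '%s'", path), class = "thyromorph_io_error")
  }
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  new_label_map(matrix(as.integer(round(img * 65535)), nrow(img), ncol(img)),
                kind)
}
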