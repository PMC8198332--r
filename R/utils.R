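# internal helpers shared across modules

stop_arg <- function(msg, class = "thyromorph_argument_error") {
  rlang::abort(msg, class = class)
}

check_matrix2d <- function(x, name) {
  if (!is.matrix(x)) stop_arg(sprintf("`%s` must be a 2-D matrix", name))
}

check_same_shape <- function(a, b, na, nb) {
  if (!identical(dim(a), dim(b))) {
    stop_arg(sprintf("`%s` (%d x %d) and `%s` (%d x %d) must share shape",
                     na, nrow(a), ncol(a), nb, nrow(b), ncol(b)))
  }
}

# logical matrix carrying provenance of the thresholding step
new_binary_mask <- function(m, source = NA_character_, threshold = NA_real_) {
  storage.mode(m) <- "logical"
  attr(m, "source") <- source
  attr(m, "threshold") <- threshold
  m
}

as_binary_mask <- function(mask, name = "mask") {
  check_matrix2d(mask, name)
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) {
      stop_arg(sprintf("`%s` must be logical or 0/1", name))
    }
    mask <- mask > 0
  }
  mask
}

new_label_map <- function(m, kind) {
  storage.mode(m) <- "integer"
  attr(m, "kind") <- kind
  m
}

#' Construct an integer label map
#'
#' Wraps an integer matrix (0 = background, k >= 1 = object k) with its
#' object-kind tag. The segmentation functions return label maps of this
#' form; the constructor is mainly useful for building fixtures and for
#' importing external segmentations.
#'
#' @param m An integer matrix of non-negative labels.
#' @param kind Object kind: `"nuclei"`, `"lumen"`, `"follicle"` or
#'   `"epithelium"`.
#' @return An integer label map with a `kind` attribute.
#' @export
label_map <- function(m, kind = "lumen") {
  check_matrix2d(m, "m")
  if (any(m < 0) || anyNA(m)) stop_arg("labels must be non-negative integers")
  new_label_map(m, kind)
}

#' Kind tag of a label map
#'
#' @param labels An integer label map produced by the segmentation functions.
#' @return A string: `"nuclei"`, `"lumen"`, `"follicle"` or `"epithelium"`.
#' @export
label_kind <- function(labels) attr(labels, "kind")

# relabel a label map so the surviving labels form 1..K, preserving the
# original label order; returns the map plus the old->new lookup
relabel_map <- function(labels, keep = NULL) {
  kind <- attr(labels, "kind")
  old <- sort(unique(labels[labels > 0L]))
  if (!is.null(keep)) old <- old[old %in% keep]
  lut <- integer(if (length(old)) max(old) else 0L)
  lut[old] <- seq_along(old)
  out <- labels
  drop <- out > 0L & !(out %in% old)
  out[drop] <- 0L
  sel <- out > 0L
  out[sel] <- lut[out[sel]]
  new_label_map(out, kind)
}

n_labels <- function(labels) {
  if (!any(labels > 0L)) 0L else max(labels)
}
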