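#' Identify primary objects in a mask or channel
#'
#' Connected components (8-connectivity) of the foreground are labelled,
#' optionally after splitting touching objects by a distance-transform
#' watershed (used for nuclei declumping). Components whose equivalent
#' diameter `2 * sqrt(area / pi)` falls outside `[diameter_min, diameter_max]`
#' are discarded, and survivors are relabelled `1..K` in scan order.
#'
#' @param x A logical mask, or a numeric channel together with `threshold`.
#' @param diameter_min,diameter_max Diameter range in pixels,
#'   `0 < diameter_min < diameter_max`.
#' @param kind Object kind tag: `"nuclei"`, `"lumen"`, `"follicle"` or
#'   `"epithelium"`.
#' @param declump Split touching blobs with a distance-transform watershed.
#'   Defaults to `TRUE` for nuclei, `FALSE` otherwise.
#' @param threshold Threshold applied first when `x` is a numeric channel.
#' @param fill_holes Fill interior holes of the surviving objects (e.g. a
#'   dead-cell remnant inside a lumen leaves a hole in the inverted tissue
#'   mask that still belongs to the lumen). Applied after the size filter so
#'   an image-wide background component never swallows enclosed objects.
#' @param discard_border Discard objects touching the image border (the
#'   common primary-object identification default): cut-off partial objects
#'   are not measurable, and the inverted-tissue background component always
#'   touches the border, so it can never masquerade as a lumen.
#' @return An integer label map with a `kind` attribute. An empty foreground
#'   yields an all-zero map.
#' @export
identify_primary_objects <- function(x, diameter_min, diameter_max,
                                     kind = "lumen",
                                     declump = identical(kind, "nuclei"),
                                     threshold = NULL,
                                     fill_holes = TRUE,
                                     discard_border = TRUE) {
  if (!is.numeric(diameter_min) || !is.numeric(diameter_max) ||
      diameter_min <= 0 || diameter_min >= diameter_max) {
    stop_arg("need 0 < diameter_min < diameter_max")
  }
  if (is.numeric(x) && !is.null(threshold)) {
    x <- apply_threshold(x, threshold)
  }
  mask <- as_binary_mask(x, "x")
  if (!any(mask)) return(new_label_map(matrix(0L, nrow(mask), ncol(mask)), kind))

  if (declump) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    labs <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = 1))
    storage.mode(labs) <- "integer"
  } else {
    labs <- cpp_label8(mask)
  }

  areas <- tabulate(labs[labs > 0L], nbins = max(labs))
  eqd <- 2 * sqrt(areas / pi)
  keep <- which(eqd >= diameter_min & eqd <= diameter_max)
  if (discard_border) {
    on_border <- unique(c(labs[1, ], labs[nrow(labs), ],
                          labs[, 1], labs[, ncol(labs)]))
    keep <- setdiff(keep, on_border)
  }
  out <- relabel_map(new_label_map(labs, kind), keep = keep)
  if (fill_holes && any(out > 0L)) {
    filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(out)))
    out <- new_label_map(matrix(as.integer(filled), nrow(out), ncol(out)), kind)
  }
  out
}

# perimeter of one binary object. For convex objects (solidity >= 0.95) the
# convex-hull perimeter of the pixel squares is used, corrected by (4 - pi):
# the squares-hull measures the object dilated by a half-pixel square, which
# adds exactly 4 to a convex perimeter, whereas a smooth envelope adds pi.
# For non-convex objects the 4-direction Crofton estimate is used (the hull
# ignores concavities), floored by the corrected hull (a lower bound on any
# true perimeter). The isoperimetric bound 2*sqrt(pi*area) is always applied,
# guaranteeing form factors <= 1.
object_perimeter <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  P <- matrix(0L, nr + 1L, nc + 1L)
  P[1:nr, 1:nc] <- P[1:nr, 1:nc] + 1L * m
  P[1:nr, 2:(nc + 1)] <- P[1:nr, 2:(nc + 1)] + 4L * m
  P[2:(nr + 1), 1:nc] <- P[2:(nr + 1), 1:nc] + 2L * m
  P[2:(nr + 1), 2:(nc + 1)] <- P[2:(nr + 1), 2:(nc + 1)] + 8L * m
  h <- tabulate(P + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
             pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
             pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
  crofton <- sum(h * coefs)

  idx <- which(m > 0L, arr.ind = TRUE)
  pts <- rbind(cbind(idx[, 1] - 0.5, idx[, 2] - 0.5),
               cbind(idx[, 1] + 0.5, idx[, 2] - 0.5),
               cbind(idx[, 1] - 0.5, idx[, 2] + 0.5),
               cbind(idx[, 1] + 0.5, idx[, 2] + 0.5))
  ch <- grDevices::chull(pts)
  v <- pts[ch, , drop = FALSE]
  vn <- v[c(seq_len(nrow(v))[-1], 1L), , drop = FALSE]
  hull <- sum(sqrt(rowSums((v - vn)^2)))
  hull_area <- abs(sum(v[, 1] * vn[, 2] - vn[, 1] * v[, 2])) / 2

  area <- nrow(idx)
  # solidity against the hull interior: the hull of the pixel squares exceeds
  # the covered lattice area by ~half the hull perimeter (Pick-style margin)
  interior <- max(hull_area - hull / 2 + 1, 1)
  solidity <- area / interior
  hull_c <- hull - (4 - pi)
  p <- if (solidity >= 0.95) hull_c else max(crofton, hull_c)
  max(p, 2 * sqrt(pi * area))
}

#' Measure object size and shape
#'
#' Per-object area (pixel count and um^2), perimeter and form factor
#' `4 * pi * area / perimeter^2`, the roundness statistic that equals 1 for a
#' perfect circle. The perimeter estimator is the maximum of the 4-direction
#' Crofton estimate, the convex-hull perimeter of the object's pixel squares
#' and the isoperimetric lower bound; this combination reproduces the analytic
#' perimeter of rasterized discs, squares and thin bars within rasterization
#' tolerance and guarantees form factors in `(0, 1]`.
#'
#' @param labels An integer label map.
#' @param pixel_size Micrometres per pixel.
#' @return A tibble with columns `label`, `area_px`, `area_um2`,
#'   `perimeter_px` and `form_factor`.
#' @export
measure_shape <- function(labels, pixel_size = 1) {
  check_matrix2d(labels, "labels")
  K <- n_labels(labels)
  if (K == 0L) {
    return(tibble::tibble(label = integer(0), area_px = integer(0),
                          area_um2 = numeric(0), perimeter_px = numeric(0),
                          form_factor = numeric(0)))
  }
  areas <- tabulate(labels[labels > 0L], nbins = K)
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  per <- numeric(K)
  for (k in seq_len(K)) {
    sel <- lab == k
    ri <- range(idx[sel, 1]); rj <- range(idx[sel, 2])
    sub <- labels[ri[1]:ri[2], rj[1]:rj[2], drop = FALSE]
    per[k] <- object_perimeter((sub == k) * 1L)
  }
  tibble::tibble(
    label = seq_len(K),
    area_px = as.integer(areas),
    area_um2 = areas * pixel_size^2,
    perimeter_px = per,
    form_factor = 4 * pi * areas / per^2
  )
}

#' Filter objects by roundness
#'
#' Removes objects whose form factor is below `min_ff` (the comparison is
#' inclusive: an object at exactly `min_ff` is retained). Survivors are
#' relabelled `1..K` preserving their original order. The default 0.3 excludes
#' elongated non-follicle objects while keeping round lumina.
#'
#' @param labels An integer label map.
#' @param shapes The [measure_shape()] table computed from `labels`.
#' @param min_ff Minimum form factor, in `(0, 1.2]`.
#' @return A filtered, relabelled label map.
#' @export
filter_by_form_factor <- function(labels, shapes, min_ff = 0.3) {
  if (!is.numeric(min_ff) || length(min_ff) != 1L ||
      min_ff <= 0 || min_ff > 1.2) {
    stop_arg("`min_ff` must be in (0, 1.2]")
  }
  if (!all(shapes$label %in% seq_len(max(n_labels(labels), 0L)))) {
    stop_arg("`shapes` does not match `labels`")
  }
  keep <- shapes$label[shapes$form_factor >= min_ff]
  relabel_map(labels, keep = keep)
}

#' Grow follicles from lumen seeds by bounded propagation
#'
#' Each lumen object grows outward through passable pixels of the boundary
#' image, stopping at barrier pixels (skeletonized basal lamina or
#' non-tissue), the image edge, or a geodesic distance of `max_expansion`
#' pixels from the lumen's own boundary, whichever comes first. Distances are
#' chamfer-weighted (1 orthogonal, `sqrt(2)` diagonal), so the cap is
#' approximately Euclidean. Contested pixels go to the nearer seed, ties to
#' the lower label. Thin barrier walls adjacent to a grown follicle are
#' absorbed into it (`absorb` passes), so a follicle reaches the outer edge
#' of its basal lamina; every follicle is a superset of its lumen.
#'
#' @param lumina Integer label map of lumen seeds.
#' @param boundary Logical boundary image from [build_boundary_image()];
#'   `TRUE` pixels are passable.
#' @param max_expansion Expansion cap in pixels (>= 0); the pipeline default
#'   is 30.
#' @param absorb Barrier-absorption passes (wall thickness in px).
#' @param absorbable Logical mask of barrier pixels eligible for absorption.
#'   Defaults to every barrier pixel; the section pipeline passes the
#'   basal-lamina skeleton only, so non-tissue background is never absorbed.
#' @return A follicle label map with labels matching `lumina`.
#' @export
propagate_follicles <- function(lumina, boundary, max_expansion = 30,
                                absorb = 2L, absorbable = NULL) {
  check_matrix2d(lumina, "lumina")
  boundary <- as_binary_mask(boundary, "boundary")
  check_same_shape(lumina, boundary, "lumina", "boundary")
  if (!is.numeric(max_expansion) || max_expansion < 0) {
    stop_arg("`max_expansion` must be >= 0")
  }
  if (is.null(absorbable)) {
    absorbable <- !boundary
  } else {
    absorbable <- as_binary_mask(absorbable, "absorbable")
    check_same_shape(lumina, absorbable, "lumina", "absorbable")
  }
  out <- cpp_propagate(lumina, boundary, absorbable, max_expansion,
                       as.integer(absorb))
  new_label_map(out, "follicle")
}

#' Derive epithelium objects by subtraction
#'
#' Epithelium `k` is follicle `k` minus lumen `k`. Every lumen must lie inside
#' the follicle with the same label; a lumen pixel outside it raises a
#' consistency error naming the label. Labels whose epithelium is empty are
#' flagged in the `empty_labels` attribute.
#'
#' @param follicles,lumina Integer label maps with matching labels.
#' @return An epithelium label map.
#' @export
derive_epithelium <- function(follicles, lumina) {
  check_matrix2d(follicles, "follicles")
  check_matrix2d(lumina, "lumina")
  check_same_shape(follicles, lumina, "follicles", "lumina")
  in_lum <- lumina > 0L
  bad <- in_lum & follicles != lumina
  if (any(bad)) {
    labs <- sort(unique(lumina[bad]))
    stop_arg(sprintf("lumen label(s) %s not contained in matching follicle",
                     paste(labs, collapse = ", ")),
             class = "thyromorph_consistency_error")
  }
  epi <- follicles
  epi[in_lum] <- 0L
  epi <- new_label_map(epi, "epithelium")
  present <- sort(unique(follicles[follicles > 0L]))
  left <- sort(unique(epi[epi > 0L]))
  attr(epi, "empty_labels") <- setdiff(present, left)
  epi
}

# centroids of the objects present in a label map; robust to gaps in the
# label sequence (rows are ordered by label, see the `labels` element)
label_centroids <- function(labels) {
  idx <- which(labels > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(list(labels = integer(0), centroids = matrix(numeric(0), 0, 2)))
  }
  lab <- labels[labels > 0L]
  present <- sort(unique(lab))
  counts <- as.vector(rowsum(rep(1, length(lab)), lab))
  cen <- cbind(as.vector(rowsum(idx[, 1], lab)) / counts,
               as.vector(rowsum(idx[, 2], lab)) / counts)
  list(labels = as.integer(present), centroids = cen)
}

#' Assign child objects to parent objects by centroid
#'
#' A child is assigned to the parent object containing its centroid (rounded
#' to the nearest pixel); a centroid on background yields parent 0. Used to
#' relate nuclei to follicles and count cells per follicle.
#'
#' @param children,parents Integer label maps of identical shape.
#' @return A tibble with columns `child` and `parent`; every child label
#'   appears exactly once.
#' @export
relate_objects <- function(children, parents) {
  check_matrix2d(children, "children")
  check_matrix2d(parents, "parents")
  check_same_shape(children, parents, "children", "parents")
  cen <- label_centroids(children)
  if (length(cen$labels) == 0L) {
    return(tibble::tibble(child = integer(0), parent = integer(0)))
  }
  ri <- pmin(pmax(round(cen$centroids[, 1]), 1L), nrow(parents))
  ci <- pmin(pmax(round(cen$centroids[, 2]), 1L), ncol(parents))
  tibble::tibble(child = cen$labels,
                 parent = as.integer(parents[cbind(ri, ci)]))
}

#' Nuclei inside follicle lumina (dead-cell remnants)
#'
#' Masks the nucleus objects with the lumen objects: only nuclei whose
#' centroid lies inside a lumen are returned, each mapped to that lumen.
#' Intraluminal nuclei are counted as shed, terminally differentiated
#' thyrocytes (dead-cell remnants).
#'
#' @param nuclei,lumina Integer label maps of identical shape.
#' @return A tibble with columns `child` (nucleus label) and `parent` (lumen
#'   label), one row per intraluminal nucleus.
#' @export
mask_intraluminal_nuclei <- function(nuclei, lumina) {
  rel <- relate_objects(nuclei, lumina)
  rel[rel$parent > 0L, , drop = FALSE]
}

#' Apply a manual label override file
#'
#' Reproducible replacement for interactive object editing: a CSV listing
#' label ids to drop is applied to a label map, and survivors are relabelled
#' `1..K` preserving order.
#'
#' @param labels An integer label map.
#' @param path CSV file with a `drop` column of label ids.
#' @return The edited label map.
#' @export
apply_label_overrides <- function(labels, path) {
  if (!file.exists(path)) {
    stop_arg(sprintf("no such file: '%s'", path), class = "thyromorph_io_error")
  }
  ov <- utils::read.csv(path)
  if (!"drop" %in% names(ov)) stop_arg("override file needs a `drop` column")
  keep <- setdiff(seq_len(n_labels(labels)), as.integer(ov$drop))
  relabel_map(labels, keep = keep)
}
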