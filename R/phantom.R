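#' Specification of a synthetic follicular-tissue phantom
#'
#' Describes a three-channel phantom image that emulates a thyroid tissue
#' mid-section: round follicle lumina surrounded by an epithelial annulus
#' containing nuclei, a thin basal-lamina ring in the marker channel,
#' vesicular marker puncta in the epithelium, diffuse marker signal in the
#' lumina, optional intraluminal nuclear remnants (dead cells) and additive
#' Gaussian background noise. The defaults describe the standard validation
#' phantom: a 2048 x 2048 px field with 30 non-overlapping follicles.
#'
#' @param image_size Height and width in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param n_follicles Number of follicles to place (>= 0).
#' @param lumen_radius_range Min and max lumen radius in pixels.
#' @param epithelium_thickness_range Min and max epithelial annulus thickness
#'   in pixels.
#' @param nuclei_per_follicle_range Min and max nuclei per follicle.
#' @param dead_cell_fraction Proportion of all nuclei placed inside lumina as
#'   dead-cell remnants, in `[0, 1]`.
#' @param luminal_marker_fraction Proportion of total marker signal placed as
#'   diffuse luminal signal, in `[0, 1)`.
#' @param puncta_per_cell Number of vesicular marker puncta rendered per
#'   epithelial nucleus.
#' @param noise_sd Standard deviation of additive Gaussian noise (intensity
#'   units on the `[0, 1]` scale; clipped after addition).
#' @param seed Integer seed; identical specs produce bit-identical phantoms.
#' @param min_gap Minimum gap in pixels between the outer boundaries of any
#'   two follicles.
#' @param nucleus_diameter Rendered nucleus diameter in pixels.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(2048L, 2048L),
                         pixel_size = 0.62,
                         n_follicles = 30L,
                         lumen_radius_range = c(30, 70),
                         epithelium_thickness_range = c(14, 20),
                         nuclei_per_follicle_range = c(8L, 24L),
                         dead_cell_fraction = 0.04,
                         luminal_marker_fraction = 0.31,
                         puncta_per_cell = 3L,
                         noise_sd = 0.01,
                         seed = 42L,
                         min_gap = 5,
                         nucleus_diameter = 7) {
  spec <- list(
    image_size = as.integer(image_size),
    pixel_size = pixel_size,
    n_follicles = as.integer(n_follicles),
    lumen_radius_range = as.numeric(lumen_radius_range),
    epithelium_thickness_range = as.numeric(epithelium_thickness_range),
    nuclei_per_follicle_range = as.integer(nuclei_per_follicle_range),
    dead_cell_fraction = dead_cell_fraction,
    luminal_marker_fraction = luminal_marker_fraction,
    puncta_per_cell = as.integer(puncta_per_cell),
    noise_sd = noise_sd,
    seed = as.integer(seed),
    min_gap = min_gap,
    nucleus_diameter = nucleus_diameter
  )
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  rng_ok <- function(r) length(r) == 2L && all(is.finite(r)) && r[1] <= r[2]
  if (length(s$image_size) != 2L || any(s$image_size < 1L)) {
    stop_arg("`image_size` must be two positive integers")
  }
  if (!is.finite(s$pixel_size) || s$pixel_size <= 0) {
    stop_arg("`pixel_size` must be > 0")
  }
  if (is.na(s$n_follicles) || s$n_follicles < 0L) {
    stop_arg("`n_follicles` must be >= 0")
  }
  if (!rng_ok(s$lumen_radius_range) || s$lumen_radius_range[1] <= 0) {
    stop_arg("`lumen_radius_range` must satisfy 0 < min <= max")
  }
  if (!rng_ok(s$epithelium_thickness_range) ||
      s$epithelium_thickness_range[1] <= 0) {
    stop_arg("`epithelium_thickness_range` must satisfy 0 < min <= max")
  }
  if (!rng_ok(as.numeric(s$nuclei_per_follicle_range)) ||
      s$nuclei_per_follicle_range[1] < 0L) {
    stop_arg("`nuclei_per_follicle_range` must satisfy 0 <= min <= max")
  }
  if (!is.finite(s$dead_cell_fraction) || s$dead_cell_fraction < 0 ||
      s$dead_cell_fraction > 1) {
    stop_arg("`dead_cell_fraction` must be in [0, 1]")
  }
  if (!is.finite(s$luminal_marker_fraction) || s$luminal_marker_fraction < 0 ||
      s$luminal_marker_fraction >= 1) {
    stop_arg("`luminal_marker_fraction` must be in [0, 1)")
  }
  if (s$puncta_per_cell < 0L) stop_arg("`puncta_per_cell` must be >= 0")
  if (!is.finite(s$noise_sd) || s$noise_sd < 0) {
    stop_arg("`noise_sd` must be >= 0")
  }
  invisible(s)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %d x %d px, %d follicles, seed %d\n",
    x$image_size[1], x$image_size[2], x$n_follicles, x$seed))
  invisible(x)
}

# squared-distance matrix for a bounding box around (ci, cj)
disc_pixels <- function(nr, nc, ci, cj, radius) {
  i0 <- max(1L, floor(ci - radius)); i1 <- min(nr, ceiling(ci + radius))
  j0 <- max(1L, floor(cj - radius)); j1 <- min(nc, ceiling(cj + radius))
  ii <- i0:i1; jj <- j0:j1
  d2 <- outer((ii - ci)^2, (jj - cj)^2, "+")
  list(i = ii, j = jj, d2 = d2)
}

# linear indices of the pixels of a disc; avoids copying the full image
disc_indices <- function(nr, nc, ci, cj, radius) {
  px <- disc_pixels(nr, nc, ci, cj, radius)
  sel <- which(px$d2 <= radius^2, arr.ind = TRUE)
  px$i[sel[, 1]] + (px$j[sel[, 2]] - 1L) * nr
}

#' Generate a synthetic follicular-tissue phantom with exact ground truth
#'
#' Renders the phantom described by a [phantom_spec()] and returns the
#' three-channel image together with a ground-truth table consistent with the
#' rendered geometry: per-follicle pixel-exact areas, nucleus counts and
#' epithelial extension, and image-level total and intracellular marker
#' signal. Follicle centers are drawn by rejection sampling with a minimum
#' gap between outer boundaries, so follicles never overlap; a placement that
#' cannot be satisfied raises an error naming the follicle index.
#'
#' Ground-truth marker sums are recorded from the rendered noise-free signal;
#' with `noise_sd > 0` the integral of the marker channel exceeds the truth
#' total by the background noise.
#'
#' @param spec A [phantom_spec()].
#' @param max_tries Rejection-sampling retry limit per follicle.
#' @return A list of class `follicle_phantom` with elements `channels`
#'   (a [channel_stack()]) and `truth` (a tibble of class `phantom_truth`,
#'   one row per follicle, with image-level marker sums as attributes
#'   `total_marker_signal` and `intracellular_marker_signal`).
#' @export
generate_phantom <- function(spec, max_tries = 5000L) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  marker <- matrix(0, nr, nc)
  cytoplasm <- matrix(0, nr, nc)
  nuclei <- matrix(0, nr, nc)
  ps2 <- spec$pixel_size^2
  nuc_r <- spec$nucleus_diameter / 2

  n <- spec$n_follicles
  r_lum <- stats::runif(n, spec$lumen_radius_range[1], spec$lumen_radius_range[2])
  thick <- stats::runif(n, spec$epithelium_thickness_range[1],
                        spec$epithelium_thickness_range[2])
  r_out <- r_lum + thick

  # rejection-sample non-overlapping centers
  centers <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ci <- stats::runif(1, r_out[k] + 2, nr - r_out[k] - 1)
      cj <- stats::runif(1, r_out[k] + 2, nc - r_out[k] - 1)
      if (k == 1L) { ok <- TRUE } else {
        prev <- seq_len(k - 1L)
        dd <- sqrt((centers[prev, 1] - ci)^2 + (centers[prev, 2] - cj)^2)
        ok <- all(dd > r_out[prev] + r_out[k] + spec$min_gap)
      }
      if (ok) { centers[k, ] <- c(ci, cj); placed <- TRUE; break }
    }
    if (!placed) {
      stop_arg(sprintf(
        "could not place follicle %d after %d tries; reduce n_follicles or radii",
        k, max_tries), class = "thyromorph_placement_error")
    }
  }

  # nucleus counts and dead-cell allocation: per-follicle totals are drawn
  # from the range; round(dead_cell_fraction * grand total) of all nuclei are
  # reassigned to intraluminal (dead) positions, capped per follicle
  n_total <- if (n > 0) {
    sample(spec$nuclei_per_follicle_range[1]:spec$nuclei_per_follicle_range[2],
           n, replace = TRUE)
  } else integer(0)
  n_dead <- integer(n)
  want_dead <- round(spec$dead_cell_fraction * sum(n_total))
  while (sum(n_dead) < want_dead) {
    open <- which(n_dead < n_total)
    if (!length(open)) break
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    n_dead[pick] <- n_dead[pick] + 1L
  }
  n_epi <- n_total - n_dead

  lumen_px <- integer(n); foll_px <- integer(n)
  for (k in seq_len(n)) {
    ci <- centers[k, 1]; cj <- centers[k, 2]
    px <- disc_pixels(nr, nc, ci, cj, r_out[k])
    in_lum <- px$d2 <= r_lum[k]^2
    in_foll <- px$d2 <= r_out[k]^2
    in_ring <- in_foll & px$d2 > (r_out[k] - 1.5)^2
    lumen_px[k] <- sum(in_lum)
    foll_px[k] <- sum(in_foll)
    cy <- cytoplasm[px$i, px$j, drop = FALSE]
    cy[in_foll & !in_lum] <- 0.8
    cytoplasm[px$i, px$j] <- cy
    mk <- marker[px$i, px$j, drop = FALSE]
    mk[in_ring] <- 1
    marker[px$i, px$j] <- mk
  }

  # epithelial nuclei: one ring of evenly spaced angles with jitter, at the
  # mid-annulus radius; guarantees >= `nucleus_diameter + 1` px separation
  for (k in seq_len(n)) {
    if (n_epi[k] == 0L) next
    r_mid <- r_lum[k] + thick[k] / 2
    capacity <- floor(2 * pi * r_mid / (spec$nucleus_diameter + 2))
    m <- min(n_epi[k], capacity)
    n_epi[k] <- m
    ang <- 2 * pi * (seq_len(m) - 1) / m +
      stats::runif(m, -0.2, 0.2) * 2 * pi / max(m, 8)
    rad <- r_mid + stats::runif(m, -1.5, 1.5)
    for (q in seq_len(m)) {
      nuclei[disc_indices(nr, nc, centers[k, 1] + rad[q] * cos(ang[q]),
                          centers[k, 2] + rad[q] * sin(ang[q]), nuc_r)] <- 1
    }
  }

  # intraluminal dead-cell remnants, kept clear of the lumen boundary
  for (k in seq_len(n)) {
    if (n_dead[k] == 0L) next
    pts <- matrix(NA_real_, 0, 2)
    r_max <- max(r_lum[k] - nuc_r - 3, 1)
    for (q in seq_len(n_dead[k])) {
      for (try in seq_len(max_tries)) {
        a <- stats::runif(1, 0, 2 * pi)
        r <- r_max * sqrt(stats::runif(1))
        p <- centers[k, ] + r * c(cos(a), sin(a))
        if (nrow(pts) == 0L ||
            all(sqrt(rowSums(t(t(pts) - p)^2)) > spec$nucleus_diameter + 2)) {
          pts <- rbind(pts, p); break
        }
      }
    }
    n_dead[k] <- nrow(pts)
    for (q in seq_len(nrow(pts))) {
      nuclei[disc_indices(nr, nc, pts[q, 1], pts[q, 2], nuc_r)] <- 1
    }
  }

  # vesicular marker puncta in the epithelium
  for (k in seq_len(n)) {
    np <- spec$puncta_per_cell * n_epi[k]
    if (np == 0L) next
    a <- stats::runif(np, 0, 2 * pi)
    r <- stats::runif(np, r_lum[k] + 2, r_out[k] - 2.5)
    for (q in seq_len(np)) {
      marker[disc_indices(nr, nc, centers[k, 1] + r[q] * cos(a[q]),
                          centers[k, 2] + r[q] * sin(a[q]), 1.5)] <- 1
    }
  }

  # diffuse luminal marker so that the luminal share of total marker signal
  # equals luminal_marker_fraction
  intra_signal <- sum(marker)
  total_lumen_px <- sum(lumen_px)
  f <- spec$luminal_marker_fraction
  if (f > 0 && total_lumen_px > 0 && intra_signal > 0) {
    lum_value <- intra_signal * f / (1 - f) / total_lumen_px
    for (k in seq_len(n)) {
      px <- disc_pixels(nr, nc, centers[k, 1], centers[k, 2], r_lum[k])
      mk <- marker[px$i, px$j, drop = FALSE]
      sel <- px$d2 <= r_lum[k]^2
      mk[sel] <- mk[sel] + lum_value
      marker[px$i, px$j] <- mk
    }
  }
  total_signal <- sum(marker)

  # soften nuclei into blob-like objects
  if (any(nuclei > 0)) {
    nuclei <- EBImage::imageData(EBImage::gblur(EBImage::Image(nuclei), sigma = 1))
    nuclei[nuclei < 0] <- 0
  }

  if (spec$noise_sd > 0) {
    addnoise <- function(ch) {
      ch <- ch + stats::rnorm(length(ch), 0, spec$noise_sd)
      ch[ch < 0] <- 0; ch[ch > 1] <- 1
      ch
    }
    marker <- addnoise(marker)
    cytoplasm <- addnoise(cytoplasm)
    nuclei <- addnoise(nuclei)
  }

  lumen_area <- lumen_px * ps2
  follicle_area <- foll_px * ps2
  truth <- tibble::tibble(
    id = seq_len(n),
    center_row = centers[, 1],
    center_col = centers[, 2],
    lumen_area = lumen_area,
    follicle_area = follicle_area,
    epithelium_area = follicle_area - lumen_area,
    n_epithelial_nuclei = as.integer(n_epi),
    n_intraluminal_nuclei = as.integer(n_dead),
    true_eext = sqrt(follicle_area / pi) - sqrt(lumen_area / pi)
  )
  attr(truth, "total_marker_signal") <- total_signal
  attr(truth, "intracellular_marker_signal") <- intra_signal
  class(truth) <- c("phantom_truth", class(truth))

  structure(
    list(channels = channel_stack(marker, cytoplasm, nuclei, spec$pixel_size),
         truth = truth, spec = spec),
    class = "follicle_phantom"
  )
}

#' @export
print.follicle_phantom <- function(x, ...) {
  cat(sprintf("<follicle_phantom> %d x %d px, %d follicles\n",
              nrow(x$channels$marker), ncol(x$channels$marker),
              nrow(x$truth)))
  invisible(x)
}

#' Write a phantom ground-truth table to CSV
#'
#' One row per follicle plus one image-level summary row carrying the total
#' and intracellular marker signal. The file round-trips losslessly through
#' [read_truth()].
#'
#' @param truth A `phantom_truth` tibble from [generate_phantom()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  df <- as.data.frame(truth)
  df <- cbind(row_type = rep("follicle", nrow(df)), df)
  df$total_marker_signal <- rep(NA_real_, nrow(df))
  df$intracellular_marker_signal <- rep(NA_real_, nrow(df))
  if (nrow(df) > 0) {
    summary_row <- df[0, ]
    summary_row[1, "row_type"] <- "image"
    summary_row[1, "total_marker_signal"] <- attr(truth, "total_marker_signal")
    summary_row[1, "intracellular_marker_signal"] <-
      attr(truth, "intracellular_marker_signal")
    out <- rbind(df, summary_row)
  } else {
    out <- df
  }
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "", format(x, digits = 17, trim = TRUE, scientific = FALSE))
  })
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_arg(sprintf("cannot write truth table to '%s': %s",
                     path, conditionMessage(ok)),
             class = "thyromorph_io_error")
  }
  invisible(path)
}

#' Read a phantom ground-truth table written by [write_truth()]
#'
#' @param path CSV path.
#' @return A `phantom_truth` tibble.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) {
    stop_arg(sprintf("no such file: '%s'", path), class = "thyromorph_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  img <- df[df$row_type == "image", , drop = FALSE]
  fol <- df[df$row_type == "follicle", , drop = FALSE]
  truth <- tibble::as_tibble(fol[, c(
    "id", "center_row", "center_col", "lumen_area", "follicle_area",
    "epithelium_area", "n_epithelial_nuclei", "n_intraluminal_nuclei",
    "true_eext")])
  truth$id <- as.integer(truth$id)
  truth$n_epithelial_nuclei <- as.integer(truth$n_epithelial_nuclei)
  truth$n_intraluminal_nuclei <- as.integer(truth$n_intraluminal_nuclei)
  attr(truth, "total_marker_signal") <-
    if (nrow(img)) img$total_marker_signal[1] else NA_real_
  attr(truth, "intracellular_marker_signal") <-
    if (nrow(img)) img$intracellular_marker_signal[1] else NA_real_
  class(truth) <- c("phantom_truth", class(truth))
  truth
}
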