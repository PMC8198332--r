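#' Per-follicle morphometric records
#'
#' Combines the follicle, lumen and epithelium label maps with the
#' nucleus-to-follicle and dead-cell-to-lumen relations into one record per
#' follicle: areas in um^2, epithelial extension, cell count, thyrocyte area
#' and dead-cell count.
#'
#' The epithelial extension (EExt), a per-follicle proxy for epithelial
#' height, is defined here as the difference of equivalent-disc radii,
#' `sqrt(follicle_area / pi) - sqrt(lumen_area / pi)`, which equals the
#' epithelial height exactly for concentric circular follicles. The thyrocyte
#' area is the epithelium area divided by the number of cells of the follicle
#' (`NA` when the follicle has no assigned cells).
#'
#' @param follicles,lumina,epithelia Mutually consistent integer label maps
#'   sharing the same labels.
#' @param relations Nucleus-to-follicle table from [relate_objects()].
#' @param dead_relations Dead-cell-to-lumen table from
#'   [mask_intraluminal_nuclei()].
#' @param pixel_size Micrometres per pixel.
#' @return A tibble with one row per follicle: `follicle_id`, `lumen_area`,
#'   `follicle_area`, `epithelium_area` (um^2), `eext` (um), `n_cells`,
#'   `thyrocyte_area` (um^2 per cell) and `n_dead_cells`.
#' @export
follicle_metrics <- function(follicles, lumina, epithelia, relations,
                             dead_relations, pixel_size) {
  check_matrix2d(follicles, "follicles")
  check_same_shape(follicles, lumina, "follicles", "lumina")
  check_same_shape(follicles, epithelia, "follicles", "epithelia")
  K <- n_labels(follicles)
  if (n_labels(lumina) > K || n_labels(epithelia) > K) {
    stop_arg("label maps are inconsistent: more lumina/epithelia than follicles",
             class = "thyromorph_consistency_error")
  }
  ps2 <- pixel_size^2
  a_fol <- tabulate(follicles[follicles > 0L], nbins = K) * ps2
  a_lum <- tabulate(lumina[lumina > 0L], nbins = K) * ps2
  a_epi <- tabulate(epithelia[epithelia > 0L], nbins = K) * ps2
  n_cells <- tabulate(relations$parent[relations$parent > 0L], nbins = K)
  n_dead <- tabulate(dead_relations$parent[dead_relations$parent > 0L],
                     nbins = K)
  tibble::tibble(
    follicle_id = seq_len(K),
    lumen_area = a_lum,
    follicle_area = a_fol,
    epithelium_area = a_epi,
    eext = sqrt(a_fol / pi) - sqrt(a_lum / pi),
    n_cells = as.integer(n_cells),
    thyrocyte_area = ifelse(n_cells > 0, a_epi / n_cells, NA_real_),
    n_dead_cells = as.integer(n_dead)
  )
}

#' Section-level summary of follicle records
#'
#' Means are unweighted over follicles (each follicle counts once). The cell
#' density is `1000 * sum(n_cells) / sum(follicle_area)` cells per 1000 um^2
#' of follicle area; the dead-cell percentage normalizes the intraluminal
#' remnants to the total nucleus count of the whole section.
#'
#' @param records A [follicle_metrics()] tibble.
#' @param total_nuclei Total nucleus count of the section (>= total dead
#'   cells).
#' @return A one-row tibble: `n_follicles`, `mean_lumen_area`,
#'   `mean_follicle_area`, `mean_thyrocyte_area`, `mean_eext`,
#'   `cells_per_1000um2`, `dead_cell_pct`. An empty record list yields
#'   `n_follicles = 0` with `NA` means.
#' @export
section_summary <- function(records, total_nuclei) {
  n_dead_total <- sum(records$n_dead_cells)
  if (total_nuclei < n_dead_total) {
    stop_arg("`total_nuclei` must be >= the total number of dead cells")
  }
  if (nrow(records) == 0L) {
    return(tibble::tibble(
      n_follicles = 0L, mean_lumen_area = NA_real_,
      mean_follicle_area = NA_real_, mean_thyrocyte_area = NA_real_,
      mean_eext = NA_real_, cells_per_1000um2 = NA_real_,
      dead_cell_pct = if (total_nuclei > 0) 0 else NA_real_))
  }
  tibble::tibble(
    n_follicles = nrow(records),
    mean_lumen_area = mean(records$lumen_area),
    mean_follicle_area = mean(records$follicle_area),
    mean_thyrocyte_area = mean(records$thyrocyte_area, na.rm = TRUE),
    mean_eext = mean(records$eext),
    cells_per_1000um2 = 1000 * sum(records$n_cells) / sum(records$follicle_area),
    dead_cell_pct = if (total_nuclei > 0) {
      100 * n_dead_total / total_nuclei
    } else NA_real_
  )
}

#' Standardized lumen-area heat map
#'
#' Paints every lumen object by a monotone colormap (viridis) of its area,
#' linearly mapped on `[0, vmax_area]` and clipped at `vmax_area`, so heat
#' maps from different sections share one fixed color scale. Background is
#' black. The function is a pure function of the areas and `vmax_area`:
#' identical inputs give identical images.
#'
#' @param lumina Integer lumen label map.
#' @param records A table with columns `follicle_id` and `lumen_area` (um^2),
#'   typically from [follicle_metrics()].
#' @param vmax_area Upper limit of the color scale in um^2 (> 0).
#' @return A `height x width x 3` RGB array in `[0, 1]`, with a `legend`
#'   attribute: a tibble of `label`, `area_um2`, `value` (clipped linear
#'   position in `[0, 1]`) and `hex` color.
#' @export
lumen_heatmap <- function(lumina, records, vmax_area) {
  check_matrix2d(lumina, "lumina")
  if (!is.numeric(vmax_area) || length(vmax_area) != 1L || vmax_area <= 0) {
    stop_arg("`vmax_area` must be a single value > 0")
  }
  K <- n_labels(lumina)
  areas <- numeric(K)
  areas[records$follicle_id] <- records$lumen_area
  value <- pmin(areas / vmax_area, 1)
  ramp <- grDevices::colorRamp(viridisLite::viridis(256))
  rgb_per_label <- if (K > 0) ramp(value) / 255 else matrix(numeric(0), 0, 3)
  out <- array(0, dim = c(nrow(lumina), ncol(lumina), 3))
  sel <- which(lumina > 0L)
  if (length(sel)) {
    lab <- lumina[sel]
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- rgb_per_label[lab, ch]
      out[, , ch] <- plane
    }
  }
  hex <- if (K > 0) {
    grDevices::rgb(rgb_per_label[, 1], rgb_per_label[, 2], rgb_per_label[, 3])
  } else character(0)
  attr(out, "legend") <- tibble::tibble(
    label = seq_len(K), area_um2 = areas, value = value, hex = hex)
  attr(out, "vmax_area") <- vmax_area
  out
}
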