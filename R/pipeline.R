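#' Run the full section analysis on a channel stack
#'
#' Executes the morphometry pipeline end to end: threshold the grayscale
#' merge into an all-tissue mask; skeletonize the thresholded marker
#' (basal-lamina) channel; identify lumen primary objects in the inverted
#' all-tissue image and filter them by roundness; grow follicles from the
#' lumina by bounded propagation against the boundary image; derive
#' epithelia by subtraction; identify nuclei with watershed declumping and
#' relate them to follicles; count intraluminal dead-cell remnants; and
#' compute per-follicle records, the section summary, the marker-signal
#' compartmentalization and the standardized lumen-area heat map.
#'
#' @param stack A [channel_stack()].
#' @param config A [thyro_config()].
#' @param heatmap Also render the lumen-area heat map.
#' @return A list of class `thyro_section` with elements `lumina`,
#'   `follicles`, `epithelia`, `nuclei` (label maps), `relations`,
#'   `dead_relations`, `shapes`, `records`, `summary`, `intensity`,
#'   `heatmap` (or `NULL`) and `config`. [tidy()] returns the per-follicle
#'   records; [glance()] the one-row section summary.
#' @export
analyze_section <- function(stack, config = thyro_config(), heatmap = TRUE) {
  stopifnot(inherits(stack, "channel_stack"))
  th <- config$threshold

  gray <- merge_gray(stack)
  all_tissue <- apply_threshold(gray, th$gray, source = "gray")
  marker_mask <- apply_threshold(stack$marker, th$marker, source = "marker")
  skeleton <- close_and_skeletonize(marker_mask)
  boundary <- build_boundary_image(all_tissue, skeleton)

  lumen_cand <- identify_primary_objects(
    invert_mask(all_tissue), config$lumen_diameter[1], config$lumen_diameter[2],
    kind = "lumen")
  shapes <- measure_shape(lumen_cand, stack$pixel_size)
  lumina <- filter_by_form_factor(lumen_cand, shapes, config$min_form_factor)
  shapes <- measure_shape(lumina, stack$pixel_size)

  follicles <- propagate_follicles(lumina, boundary, config$max_expansion,
                                   absorbable = skeleton)
  epithelia <- derive_epithelium(follicles, lumina)

  nuclei <- identify_primary_objects(
    stack$nuclei, config$nucleus_diameter_range[1],
    config$nucleus_diameter_range[2], kind = "nuclei",
    threshold = th$nuclei)
  relations <- relate_objects(nuclei, follicles)
  dead_relations <- mask_intraluminal_nuclei(nuclei, lumina)

  records <- follicle_metrics(follicles, lumina, epithelia, relations,
                              dead_relations, stack$pixel_size)
  summary <- section_summary(records, total_nuclei = n_labels(nuclei))

  epi_mask <- apply_threshold(stack$cytoplasm, th$cytoplasm, source = "cytoplasm")
  intensity <- compartmentalize(stack$marker, epi_mask, n_labels(nuclei))

  hm <- if (heatmap && nrow(records) > 0) {
    lumen_heatmap(lumina, records, config$vmax_area)
  }

  structure(
    list(lumina = lumina, follicles = follicles, epithelia = epithelia,
         nuclei = nuclei, relations = relations,
         dead_relations = dead_relations, shapes = shapes, records = records,
         summary = summary, intensity = intensity, heatmap = hm,
         config = config),
    class = "thyro_section"
  )
}

#' @export
print.thyro_section <- function(x, ...) {
  cat(sprintf(
    "<thyro_section> %d follicles, %d nuclei (%d intraluminal)\n",
    nrow(x$records), n_labels(x$nuclei), nrow(x$dead_relations)))
  print(x$summary)
  invisible(x)
}

#' @rdname analyze_section
#' @param x A `thyro_section` object.
#' @param ... Unused.
#' @export
tidy.thyro_section <- function(x, ...) x$records

#' @rdname analyze_section
#' @export
glance.thyro_section <- function(x, ...) x$summary
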