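#' Analysis configuration
#'
#' Bundles the batch-level settings of the pipelines: channel order, one
#' manual threshold per channel (the same values are applied to every image
#' of a batch), pixel size, object diameter ranges, the roundness filter, the
#' propagation cap and the heat-map ceiling. Threshold defaults are
#' calibrated on the package's synthetic phantoms; real batches should set
#' their own values.
#'
#' @param pixel_size_um Micrometres per pixel.
#' @param channel_order Plane-to-role mapping for [split_channels()].
#' @param threshold Named list with entries `marker`, `cytoplasm`, `nuclei`
#'   and `gray` (intensities on the `[0, 1]` scale).
#' @param lumen_diameter Diameter range in px for lumen primary objects.
#' @param nucleus_diameter_range Diameter range in px for nucleus objects.
#' @param min_form_factor Roundness filter threshold for lumen candidates.
#' @param max_expansion Propagation cap in px for follicle growing.
#' @param vmax_area Heat-map color-scale ceiling in um^2.
#' @return A list of class `thyro_config`.
#' @export
thyro_config <- function(pixel_size_um = 0.62,
                         channel_order = c("marker", "cytoplasm", "nuclei"),
                         threshold = list(marker = 0.5, cytoplasm = 0.4,
                                          nuclei = 0.25, gray = 0.1),
                         lumen_diameter = c(25, 800),
                         nucleus_diameter_range = c(4, 20),
                         min_form_factor = 0.3,
                         max_expansion = 30,
                         vmax_area = 6000) {
  cfg <- list(pixel_size_um = pixel_size_um,
              channel_order = channel_order,
              threshold = threshold,
              lumen_diameter = lumen_diameter,
              nucleus_diameter_range = nucleus_diameter_range,
              min_form_factor = min_form_factor,
              max_expansion = max_expansion,
              vmax_area = vmax_area)
  structure(cfg, class = "thyro_config")
}

#' Read a configuration from a YAML file
#'
#' Keys absent from the file keep their [thyro_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `thyro_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_arg(sprintf("no such file: '%s'", path), class = "thyromorph_io_error")
  }
  user <- yaml::read_yaml(path)
  cfg <- unclass(thyro_config())
  for (key in names(user)) {
    if (key == "threshold") {
      for (tk in names(user$threshold)) cfg$threshold[[tk]] <- user$threshold[[tk]]
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  structure(cfg, class = "thyro_config")
}
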