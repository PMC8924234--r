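#' Write and read display specifications as JSON
#'
#' @param spec A [display_spec()].
#' @param path Output path (`.json`).
#' @export
write_display_json <- function(spec, path) {
  stopifnot(inherits(spec, "display_spec"))
  payload <- list(items = spec$items,
                  canvas_px = spec$canvas_px,
                  background_level = spec$background_level,
                  region_radius_px = spec$region_radius_px,
                  configuration = spec$configuration,
                  numerosity = spec$numerosity)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_display_json
#' @export
read_display_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  items <- as_tibble(p$items)
  for (nm in c("x", "y", "size", "inner_radius", "orientation", "width",
               "contrast")) {
    if (nm %in% names(items)) items[[nm]] <- as.numeric(items[[nm]])
  }
  items$n_vertices <- as.integer(items$n_vertices)
  display_spec(items, canvas_px = p$canvas_px,
               background_level = p$background_level,
               region_radius_px = p$region_radius_px,
               configuration = p$configuration,
               numerosity = p$numerosity)
}

#' Write and read stimulus images as 8-bit grayscale PNG
#'
#' Luminance fractions are quantized to 8 bits on writing; the round trip is
#' exact to within 1/510.
#'
#' @param img A `stimulus_image`.
#' @param path Output path (`.png`).
#' @export
write_stimulus_png <- function(img, path) {
  png::writePNG(t(unclass(img)), path)
  invisible(path)
}

#' @rdname write_stimulus_png
#' @param background_level Background level restored on reading.
#' @export
read_stimulus_png <- function(path, background_level = 0.5) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  structure(t(m), canvas_px = nrow(m), background_level = background_level,
            class = c("stimulus_image", "matrix", "array"))
}

#' Write and read voxel time-series tables
#'
#' Delimited text, one row per voxel: `voxel_id`, `map_label`, `hemisphere`,
#' `eccentricity_deg`, then BOLD columns `t1 ... tN`.
#'
#' @param ts Tibble as produced by [simulate_cohort()].
#' @param path CSV path.
#' @export
write_voxel_table <- function(ts, path) {
  utils::write.csv(ts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voxel_table
#' @export
read_voxel_table <- function(path) {
  as_tibble(utils::read.csv(path, check.names = FALSE))
}
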