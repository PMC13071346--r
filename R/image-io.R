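#' Write a multi-channel field as single-channel 8-bit grayscale PNGs
#'
#' One PNG per channel, named `<field_id>_<label>.png`, plus (when ground
#' truth is supplied) a JSON sidecar `<field_id>_truth.json` carrying the
#' generator's per-channel area fractions, pairwise overlap fractions,
#' per-channel cell counts and the master seed. The true masks themselves
#' are not serialized; they are reproducible from the seed.
#'
#' @param field A [multi_channel_field()].
#' @param dir Output directory (created if needed).
#' @param truth Optional `field_ground_truth`.
#' @return Named character vector of paths written, invisibly.
#' @export
write_field <- function(field, dir, truth = NULL) {
  stopifnot(inherits(field, "multi_channel_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (l in names(field$channels)) {
    p <- file.path(dir, paste0(field$field_id, "_", l, ".png"))
    png::writePNG(field$channels[[l]] / 255, p)
    paths[l] <- p
  }
  if (!is.null(field$merged_mask)) {
    p <- file.path(dir, paste0(field$field_id, "_merged.png"))
    png::writePNG(field$merged_mask * 1, p)
    paths["merged"] <- p
  }
  if (!is.null(truth)) {
    p <- file.path(dir, paste0(field$field_id, "_truth.json"))
    jsonlite::write_json(
      list(seed = truth$seed,
           true_area_fraction = as.list(truth$true_area_fraction),
           true_overlap_fraction = as.list(truth$true_overlap_fraction),
           n_cells = as.list(truth$n_cells)),
      p, auto_unbox = TRUE, digits = NA
    )
    paths["truth"] <- p
  }
  invisible(paths)
}

#' Read a multi-channel field from single-channel grayscale images
#'
#' @param paths Named character vector, channel label -> PNG path. 8- and
#'   16-bit grayscale images are read; intensities are rescaled to the 8-bit
#'   \[0,255\] scale.
#' @param merged_path Optional path of a pre-merged composite mask PNG
#'   (thresholded at 0.5 of full scale to a logical mask).
#' @inheritParams multi_channel_field
#' @return A [multi_channel_field()].
#' @export
read_field <- function(paths, merged_path = NULL, field_id = "field1",
                       well_id = "well1",
                       condition = list(dose_mM = NA_real_,
                                        status = NA_character_)) {
  stopifnot(!is.null(names(paths)), all(nchar(names(paths)) > 0))
  channels <- lapply(paths, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3) img <- img[, , 1] # grayscale stored as RGB
    img * 255
  })
  merged <- NULL
  if (!is.null(merged_path)) {
    m <- png::readPNG(merged_path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    merged <- m > 0.5
  }
  multi_channel_field(channels, merged_mask = merged, field_id = field_id,
                      well_id = well_id, condition = condition)
}

#' Write a membership map as a PNG plus a CSV legend
#'
#' The PNG encodes the per-pixel membership count scaled to the number of
#' channels; the CSV records the count-to-color legend.
#'
#' @param map A [membership_map()].
#' @param png_path,legend_path Output paths.
#' @param n_channels Number of channels the counts were computed from
#'   (defaults to the maximum observed count).
#' @return Invisibly, the two paths.
#' @export
write_membership_map <- function(map, png_path, legend_path,
                                 n_channels = max(map$counts, 2)) {
  stopifnot(inherits(map, "membership_map"))
  png::writePNG(map$counts / n_channels, png_path)
  utils::write.csv(
    data.frame(count = as.integer(names(map$legend)),
               color = unname(map$legend)),
    legend_path, row.names = FALSE
  )
  invisible(c(png_path, legend_path))
}

#' Write area reports / well summaries as tidy CSV
#'
#' One row per field (or well) x metric.
#'
#' @param reports A single `area_report`, a list of them, or a
#'   `well_summary`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_report_csv <- function(reports, path) {
  if (inherits(reports, "well_summary")) {
    utils::write.csv(reports, path, row.names = FALSE)
    return(invisible(path))
  }
  if (inherits(reports, "area_report")) reports <- list(reports)
  long <- dplyr::bind_rows(lapply(reports, area_report_long))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
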