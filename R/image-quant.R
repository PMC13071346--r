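#' Batch-constant segmentation parameters
#'
#' The free parameters of the fixed-threshold pipeline. They are set once per
#' batch and must be held constant across all fields being compared; there is
#' deliberately no default threshold, since the threshold is the pipeline's
#' key free parameter and silently defaulting it would fabricate results.
#'
#' @param thresholds Named numeric vector, one 8-bit threshold in \[0,255\]
#'   per channel label. Required.
#' @param gamma Gamma-correction exponent applied after min-max
#'   normalization (default 0.8; values < 1 brighten mid-tones).
#' @param resize_factor Isotropic resize factor applied before normalization
#'   (bilinear for intensities; default 1 = no resize).
#' @param threshold_mode `"gt"` (default): a pixel is suprathreshold when
#'   strictly greater than the threshold; `"ge"` uses >=.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(thresholds, gamma = 0.8, resize_factor = 1,
                                threshold_mode = c("gt", "ge")) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(is.numeric(thresholds), !is.null(names(thresholds)),
            all(nchar(names(thresholds)) > 0),
            all(thresholds >= 0 & thresholds <= 255),
            gamma > 0, resize_factor > 0)
  structure(list(thresholds = thresholds, gamma = gamma,
                 resize_factor = resize_factor,
                 threshold_mode = threshold_mode),
            class = "segmentation_params")
}

#' Preprocess an intensity raster to normalized, gamma-corrected 8-bit
#'
#' Order of operations: optional isotropic resize (bilinear), per-image
#' min-max normalization to \[0,1\], gamma correction `x^gamma`, scaling to
#' \[0,255\] with clipping and rounding. The mapping is monotone, endpoints
#' are preserved (min -> 0, max -> 255), and a constant image maps to all
#' zeros rather than dividing by zero.
#'
#' @param raster Numeric matrix of intensities (any nonnegative scale; 8- or
#'   16-bit data are both accepted).
#' @param params A [segmentation_params()].
#' @return Numeric matrix with integer values in \[0,255\].
#' @export
preprocess <- function(raster, params) {
  stopifnot(is.matrix(raster), length(raster) > 0,
            inherits(params, "segmentation_params"))
  if (params$resize_factor != 1) {
    raster <- EBImage::resize(raster,
                              w = max(1, round(nrow(raster) *
                                                 params$resize_factor)),
                              h = max(1, round(ncol(raster) *
                                                 params$resize_factor)))
    raster <- as.matrix(raster)
  }
  rng <- range(raster)
  if (rng[2] > rng[1]) {
    norm <- (raster - rng[1]) / (rng[2] - rng[1])
  } else {
    norm <- matrix(0, nrow(raster), ncol(raster))
  }
  out <- round(pmin(pmax(255 * norm^params$gamma, 0), 255))
  out
}

#' Segment a preprocessed raster by a fixed global threshold
#'
#' @param raster8 Numeric matrix with values in \[0,255\] (from
#'   [preprocess()]).
#' @param threshold Intensity threshold in \[0,255\].
#' @param mode `"gt"` (strictly above; default) or `"ge"`.
#' @return Logical matrix (the binary mask) with attributes
#'   `threshold_used` and `mode`.
#' @export
segment <- function(raster8, threshold, mode = c("gt", "ge")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(raster8), threshold >= 0, threshold <= 255)
  mask <- if (mode == "gt") raster8 > threshold else raster8 >= threshold
  attr(mask, "threshold_used") <- threshold
  attr(mask, "mode") <- mode
  mask
}

#' Percent of field area covered by a mask
#'
#' @param mask Logical matrix.
#' @return `100 * sum(mask) / length(mask)`.
#' @export
percent_area <- function(mask) {
  stopifnot(is.logical(mask), length(mask) > 0)
  100 * sum(mask) / length(mask)
}

#' Merged (denominator) mask
#'
#' Returns the provided pre-merged mask verbatim when given; otherwise the
#' pixelwise union (logical OR) of all channel masks.
#'
#' @param masks List of logical matrices of common shape.
#' @param provided Optional pre-merged logical matrix; passed through
#'   unchanged when non-NULL.
#' @return Logical matrix.
#' @export
merged_area <- function(masks, provided = NULL) {
  stopifnot(length(masks) >= 1)
  dims <- lapply(masks, dim)
  if (length(unique(dims)) != 1) stop("mask shapes disagree")
  if (!is.null(provided)) {
    if (!identical(dim(provided), dims[[1]])) {
      stop("provided merged mask shape disagrees with channel masks")
    }
    return(provided)
  }
  out <- Reduce(`|`, masks)
  attributes(out) <- list(dim = dim(out))
  out
}

#' Pairwise overlap metrics between a target mask and a comparison mask
#'
#' The overlap area is the pixel count of the bitwise AND of the two masks.
#' It is reported (1) relative to the merged denominator area (spatial
#' prevalence within the multi-label scene) and (2) relative to the target's
#' own area (fraction of target signal coincident with the comparison
#' marker). A zero denominator makes the corresponding metric undefined:
#' it is returned as `NA`, never as 0.
#'
#' @param target,other Logical matrices.
#' @param merged Logical matrix (see [merged_area()]).
#' @return List with `overlap_pct_merged`, `overlap_pct_target` and
#'   `and_px`.
#' @export
overlap_metrics <- function(target, other, merged) {
  dims <- list(dim(target), dim(other), dim(merged))
  if (length(unique(dims)) != 1) stop("mask shapes disagree")
  and_px <- sum(target & other)
  merged_px <- sum(merged)
  target_px <- sum(target)
  list(
    overlap_pct_merged = if (merged_px > 0) 100 * and_px / merged_px
                         else NA_real_,
    overlap_pct_target = if (target_px > 0) 100 * and_px / target_px
                         else NA_real_,
    and_px = and_px
  )
}

#' Per-pixel channel-membership map
#'
#' Sums mask memberships per pixel; the legend color-codes pixels belonging
#' to exactly two, three, or four channels.
#'
#' @param masks List of 2-4 logical matrices of common shape.
#' @param legend Named colors for membership counts 2-4.
#' @return List of class `membership_map`: integer matrix `counts` and the
#'   `legend`.
#' @export
membership_map <- function(masks,
                           legend = c("2" = "#FFFF00", "3" = "#FF8000",
                                      "4" = "#FF0000")) {
  if (length(masks) < 2 || length(masks) > 4) {
    stop("membership map is defined for 2-4 channels")
  }
  dims <- lapply(masks, dim)
  if (length(unique(dims)) != 1) stop("mask shapes disagree")
  counts <- Reduce(`+`, lapply(masks, function(m) {
    storage.mode(m) <- "integer"
    attributes(m) <- list(dim = dim(m))
    m
  }))
  structure(list(counts = counts, legend = legend), class = "membership_map")
}

#' Live/dead ratio from green and red channel rasters
#'
#' Both channels are preprocessed and segmented with their configured fixed
#' thresholds; the ratio of the green (live) percent area to the red (dead)
#' percent area is returned. A red area of zero makes the ratio undefined:
#' the result carries `undefined = TRUE` (ratio `Inf` when green signal is
#' present, `NaN` when both are empty) rather than raising an error.
#'
#' @param green,red Numeric intensity matrices of common shape.
#' @param params [segmentation_params()] with thresholds named "green" and
#'   "red".
#' @return List: `ratio`, `pct_green`, `pct_red`, `undefined`.
#' @export
live_dead_ratio <- function(green, red, params) {
  if (!identical(dim(green), dim(red))) stop("channel shapes disagree")
  for (ch in c("green", "red")) {
    if (!ch %in% names(params$thresholds)) {
      stop("params$thresholds must name a '", ch, "' threshold")
    }
  }
  gm <- segment(preprocess(green, params), params$thresholds[["green"]],
                params$threshold_mode)
  rm_ <- segment(preprocess(red, params), params$thresholds[["red"]],
                 params$threshold_mode)
  pg <- percent_area(gm)
  pr <- percent_area(rm_)
  list(ratio = pg / pr, pct_green = pg, pct_red = pr, undefined = pr == 0)
}

#' Quantify one multi-channel field
#'
#' Runs the full per-field pipeline: preprocess and threshold every channel,
#' build the merged denominator (the provided composite mask under
#' `merged_policy = "provided"` when present, else the union of channel
#' masks), and compute per-channel percent areas plus all ordered pairwise
#' overlap metrics.
#'
#' @param field A [multi_channel_field()].
#' @param params A [segmentation_params()] with a threshold for every
#'   channel.
#' @return List of class `area_report`: tibbles `channel_area` (channel,
#'   pct_field, pct_merged, area_px), `overlaps` (target, other,
#'   overlap_pct_merged, overlap_pct_target, and_px), plus `merged_area_px`,
#'   `field_id`, `well_id`, `condition`.
#' @param merged_policy `"provided"` (default; use `field$merged_mask` when
#'   present, else union) or `"union"` (always union).
#' @export
quantify_field <- function(field, params,
                           merged_policy = c("provided", "union")) {
  merged_policy <- match.arg(merged_policy)
  stopifnot(inherits(field, "multi_channel_field"),
            inherits(params, "segmentation_params"))
  labels <- names(field$channels)
  missing_thr <- setdiff(labels, names(params$thresholds))
  if (length(missing_thr)) {
    stop("no threshold configured for channel(s): ",
         paste(missing_thr, collapse = ", "))
  }
  masks <- lapply(labels, function(l) {
    segment(preprocess(field$channels[[l]], params),
            params$thresholds[[l]], params$threshold_mode)
  })
  names(masks) <- labels
  provided <- if (merged_policy == "provided") field$merged_mask else NULL
  if (!is.null(provided) && params$resize_factor != 1) {
    # nearest-neighbour resize keeps a mask binary
    provided <- as.matrix(EBImage::resize(
      provided + 0,
      w = max(1, round(nrow(provided) * params$resize_factor)),
      h = max(1, round(ncol(provided) * params$resize_factor)),
      filter = "none")) > 0.5
  }
  merged <- merged_area(unname(masks), provided)
  merged_px <- sum(merged)
  npix <- length(merged)

  channel_area <- tibble::tibble(
    channel = labels,
    area_px = vapply(masks, sum, numeric(1)),
    pct_field = vapply(masks, percent_area, numeric(1)),
    pct_merged = vapply(masks, function(m) {
      if (merged_px > 0) 100 * sum(m) / merged_px else NA_real_
    }, numeric(1))
  )

  ov <- NULL
  if (length(labels) >= 2) {
    grid <- expand.grid(target = labels, other = labels,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$target != grid$other, , drop = FALSE]
    res <- lapply(seq_len(nrow(grid)), function(i) {
      overlap_metrics(masks[[grid$target[i]]], masks[[grid$other[i]]], merged)
    })
    ov <- tibble::tibble(
      target = grid$target, other = grid$other,
      overlap_pct_merged = vapply(res, `[[`, numeric(1), "overlap_pct_merged"),
      overlap_pct_target = vapply(res, `[[`, numeric(1), "overlap_pct_target"),
      and_px = vapply(res, `[[`, numeric(1), "and_px")
    )
  }

  structure(
    list(channel_area = channel_area, overlaps = ov,
         merged_area_px = merged_px, n_px = npix, masks = masks,
         merged_mask = merged, field_id = field$field_id,
         well_id = field$well_id, condition = field$condition),
    class = "area_report"
  )
}

#' Tidy long form of an area report
#'
#' One row per field x metric, suitable for CSV export and aggregation.
#'
#' @param report An `area_report` from [quantify_field()].
#' @return Tibble with columns field_id, well_id, metric, channel, other,
#'   value.
#' @export
area_report_long <- function(report) {
  stopifnot(inherits(report, "area_report"))
  ca <- report$channel_area
  rows <- list(
    tibble::tibble(metric = "pct_field", channel = ca$channel,
                   other = NA_character_, value = ca$pct_field),
    tibble::tibble(metric = "pct_merged", channel = ca$channel,
                   other = NA_character_, value = ca$pct_merged)
  )
  if (!is.null(report$overlaps)) {
    ov <- report$overlaps
    rows <- c(rows, list(
      tibble::tibble(metric = "overlap_pct_merged", channel = ov$target,
                     other = ov$other, value = ov$overlap_pct_merged),
      tibble::tibble(metric = "overlap_pct_target", channel = ov$target,
                     other = ov$other, value = ov$overlap_pct_target)
    ))
  }
  out <- dplyr::bind_rows(rows)
  out$field_id <- report$field_id
  out$well_id <- report$well_id
  out[, c("field_id", "well_id", "metric", "channel", "other", "value")]
}

#' Aggregate field-level technical replicates to a well summary
#'
#' Fields of one well are technical replicates: per metric, the arithmetic
#' mean and sample standard deviation across fields are reported and used as
#' the unit of downstream statistical analysis. Undefined metrics (NA, e.g.
#' a zero-denominator overlap) are excluded pairwise, with the contributing
#' field count recorded; the sd is NA with fewer than two defined fields.
#'
#' @param reports List of `area_report`s (>= 1) from one well and one
#'   parameter set.
#' @return Tibble of class `well_summary` with columns well_id, metric,
#'   channel, other, mean, sd, n_fields.
#' @export
aggregate_fields <- function(reports) {
  if (length(reports) == 0) stop("no field reports to aggregate")
  long <- dplyr::bind_rows(lapply(reports, area_report_long))
  if (length(unique(long$well_id)) > 1) {
    stop("reports come from more than one well")
  }
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$well_id, .data$metric, .data$channel,
                    .data$other),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value[!is.na(.data$value)]),
    n_fields = sum(!is.na(.data$value)),
    .groups = "drop"
  )
  out$mean[out$n_fields == 0] <- NA_real_
  class(out) <- c("well_summary", class(out))
  out
}
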