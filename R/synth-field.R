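#' Channel specification for the synthetic field generator
#'
#' @param label Channel label (e.g. "PV", "NLGN2", "green").
#' @param intensity Peak intensity of a cell, on the 8-bit scale (0-255].
#' @param radius Cell (disc) radius in pixels.
#' @param blur_sigma Gaussian blur sigma applied to the rendered channel
#'   (pixels; 0 = none).
#' @param noise_sd Additive Gaussian read-noise sd on the 8-bit scale
#'   (0 = none).
#' @return A list of class `channel_spec`.
#' @export
channel_spec <- function(label, intensity = 200, radius = 6,
                         blur_sigma = 0, noise_sd = 0) {
  stopifnot(nchar(label) > 0, intensity > 0, intensity <= 255,
            radius >= 1, blur_sigma >= 0, noise_sd >= 0)
  structure(list(label = label, intensity = intensity, radius = radius,
                 blur_sigma = blur_sigma, noise_sd = noise_sd),
            class = "channel_spec")
}

#' Multi-channel field container
#'
#' Co-registered single-channel intensity rasters for one microscope field,
#' optionally with a pre-merged composite mask.
#'
#' @param channels Named list of numeric matrices (one per channel, common
#'   shape, intensities on the 8-bit scale).
#' @param merged_mask Optional logical matrix (pre-merged composite mask).
#' @param field_id,well_id Identifiers.
#' @param condition List describing the experimental condition, e.g.
#'   `list(dose_mM = 35, status = "Diff")`.
#' @return A list of class `multi_channel_field`.
#' @export
multi_channel_field <- function(channels, merged_mask = NULL,
                                field_id = "field1", well_id = "well1",
                                condition = list(dose_mM = NA_real_,
                                                 status = NA_character_)) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), !anyDuplicated(names(channels)))
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1) stop("all channel rasters must share one shape")
  if (!is.null(merged_mask)) {
    stopifnot(is.logical(merged_mask),
              identical(dim(merged_mask), dims[[1]]))
  }
  if (!is.na(condition$dose_mM) && condition$dose_mM < 0) {
    stop("dose_mM must be nonnegative")
  }
  structure(list(channels = channels, merged_mask = merged_mask,
                 field_id = field_id, well_id = well_id,
                 condition = condition),
            class = "multi_channel_field")
}

# Rejection-sample n centers with pairwise separation > min_sep, inside a
# margin. Errors when the requested density cannot be placed.
place_centers <- function(n, shape, min_sep, margin) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  lo <- margin + 1
  hi_r <- shape[1] - margin
  hi_c <- shape[2] - margin
  if (hi_r <= lo || hi_c <= lo) stop("field too small for cell radius")
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 400L * n
  min_sep2 <- min_sep^2
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("infeasible placement: ", n, " cells of separation ", min_sep,
           " do not fit in a ", shape[1], "x", shape[2], " field")
    }
    cand <- c(stats::runif(1, lo, hi_r), stats::runif(1, lo, hi_c))
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
        (centers[seq_len(placed), 2] - cand[2])^2
      if (any(d2 <= min_sep2)) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  centers
}

# Render Gaussian-profile discs: intensity * exp(-d^2 / (2 r^2)) inside
# radius r, exactly zero outside. The disc boundary sits at
# intensity * e^-0.5 (~61% of peak), keeping the dimmest foreground pixel
# well separated from background noise at the supported noise levels; any
# threshold in (0, intensity * e^-0.5) recovers the true mask at zero noise.
render_discs <- function(centers, radius, intensity, shape) {
  raster <- matrix(0, shape[1], shape[2])
  mask <- matrix(FALSE, shape[1], shape[2])
  if (nrow(centers) == 0) return(list(raster = raster, mask = mask))
  sigma2 <- radius^2
  for (i in seq_len(nrow(centers))) {
    cy <- centers[i, 1]; cx <- centers[i, 2]
    rr <- max(1, floor(cy - radius)):min(shape[1], ceiling(cy + radius))
    cc <- max(1, floor(cx - radius)):min(shape[2], ceiling(cx + radius))
    d2 <- outer((rr - cy)^2, (cc - cx)^2, `+`)
    inside <- d2 <= radius^2
    prof <- intensity * exp(-d2 / (2 * sigma2)) * inside
    raster[rr, cc] <- pmax(raster[rr, cc], prof)
    mask[rr, cc] <- mask[rr, cc] | inside
  }
  list(raster = raster, mask = mask)
}

# Fixed substream rule: channel i's noise stream is seeded by
# master_seed + 7919 * i (mod 2^31 - 1).
channel_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + 7919 * i) %% (2^31 - 1))
}

finish_channel <- function(raster, spec, sub_seed) {
  if (spec$blur_sigma > 0) {
    raster <- EBImage::gblur(raster, sigma = spec$blur_sigma)
  }
  if (spec$noise_sd > 0) {
    withr::with_seed(sub_seed, {
      raster <- raster + matrix(stats::rnorm(length(raster), 0, spec$noise_sd),
                                nrow(raster))
    })
  }
  pmin(pmax(raster, 0), 255)
}

#' Generate a ground-truthed multi-channel field
#'
#' Cells are Gaussian-profile discs placed without overlap within each
#' channel; pairwise colocalization is produced by co-placing a controlled
#' subset of disc centers across channel pairs. `coloc` gives, per channel
#' pair, the fraction of each channel's cells that are co-placed (with equal
#' radii this equals the realized area-overlap fraction of either channel, up
#' to rasterization of whole pixels). Non-co-placed cells of different
#' channels never touch, so a requested fraction of 0 yields exactly disjoint
#' masks. All randomness is governed by `seed` (placement under the master
#' seed, per-channel noise under documented substreams), so identical seeds
#' give bit-identical output.
#'
#' @param n_cells Cells per channel.
#' @param shape Raster dims `c(rows, cols)`, at least 64 x 64.
#' @param channels List of [channel_spec()]s with unique labels.
#' @param coloc Named numeric vector of target co-placement fractions in
#'   \[0,1\], names `"a|b"` using channel labels. Requests whose per-channel
#'   shared-cell total exceeds `n_cells` raise an infeasibility error.
#' @param seed Master seed.
#' @param field_id,well_id,condition Passed to [multi_channel_field()].
#' @return A list with `field` ([multi_channel_field()]) and `truth`
#'   (class `field_ground_truth`: `true_masks`, `true_area_fraction`,
#'   `true_overlap_fraction` as fractions of field pixels, per-channel cell
#'   counts, and the seed).
#' @export
#' @examples
#' fg <- generate_field(20, c(128, 128),
#'   channels = list(channel_spec("a"), channel_spec("b")),
#'   coloc = c("a|b" = 0.5), seed = 42)
#' fg$truth$true_area_fraction
generate_field <- function(n_cells, shape = c(256, 256), channels,
                           coloc = NULL, seed = 1L,
                           field_id = "field1", well_id = "well1",
                           condition = list(dose_mM = NA_real_,
                                            status = NA_character_)) {
  stopifnot(n_cells >= 1, length(shape) == 2)
  if (any(shape < 64)) stop("shape must be at least 64 x 64")
  labels <- vapply(channels, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  names(channels) <- labels

  pairs <- list()
  if (!is.null(coloc)) {
    if (any(coloc < 0 | coloc > 1)) stop("coloc fractions must lie in [0,1]")
    for (nm in names(coloc)) {
      ab <- strsplit(nm, "|", fixed = TRUE)[[1]]
      if (length(ab) != 2 || !all(ab %in% labels)) {
        stop("coloc name '", nm, "' must be '<label>|<label>'")
      }
      pairs[[nm]] <- list(a = ab[1], b = ab[2],
                          n_shared = round(coloc[[nm]] * n_cells))
    }
  }
  shared_per_channel <- stats::setNames(rep(0L, length(labels)), labels)
  for (p in pairs) {
    shared_per_channel[p$a] <- shared_per_channel[p$a] + p$n_shared
    shared_per_channel[p$b] <- shared_per_channel[p$b] + p$n_shared
  }
  if (any(shared_per_channel > n_cells)) {
    bad <- names(which(shared_per_channel > n_cells))
    stop("infeasible colocalization request: channel(s) ",
         paste(bad, collapse = ", "), " would need more shared cells than ",
         "n_cells = ", n_cells)
  }

  radii <- vapply(channels, `[[`, numeric(1), "radius")
  min_sep <- 2 * max(radii) + 3
  n_shared_total <- sum(vapply(pairs, `[[`, numeric(1), "n_shared"))
  n_excl <- n_cells - shared_per_channel
  n_total <- n_shared_total + sum(n_excl)

  centers <- withr::with_seed(as.integer(seed),
    place_centers(n_total, shape, min_sep, margin = max(radii) + 1))

  idx <- 1L
  centers_by_channel <- lapply(labels, function(l) matrix(numeric(0), 0, 2))
  names(centers_by_channel) <- labels
  for (p in pairs) {
    if (p$n_shared > 0) {
      take <- centers[idx:(idx + p$n_shared - 1L), , drop = FALSE]
      idx <- idx + p$n_shared
      centers_by_channel[[p$a]] <- rbind(centers_by_channel[[p$a]], take)
      centers_by_channel[[p$b]] <- rbind(centers_by_channel[[p$b]], take)
    }
  }
  for (l in labels) {
    if (n_excl[[l]] > 0) {
      take <- centers[idx:(idx + n_excl[[l]] - 1L), , drop = FALSE]
      idx <- idx + n_excl[[l]]
      centers_by_channel[[l]] <- rbind(centers_by_channel[[l]], take)
    }
  }

  rasters <- list(); masks <- list()
  for (i in seq_along(labels)) {
    l <- labels[i]
    rd <- render_discs(centers_by_channel[[l]], channels[[l]]$radius,
                       channels[[l]]$intensity, shape)
    rasters[[l]] <- finish_channel(rd$raster, channels[[l]],
                                   channel_seed(seed, i))
    masks[[l]] <- rd$mask
  }

  npix <- prod(shape)
  area_frac <- vapply(masks, function(m) sum(m) / npix, numeric(1))
  overlap_frac <- numeric(0)
  if (length(labels) >= 2) {
    cmb <- utils::combn(labels, 2)
    overlap_frac <- stats::setNames(
      apply(cmb, 2, function(ab) sum(masks[[ab[1]]] & masks[[ab[2]]]) / npix),
      apply(cmb, 2, paste, collapse = "|")
    )
  }

  field <- multi_channel_field(rasters, field_id = field_id,
                               well_id = well_id, condition = condition)
  truth <- structure(
    list(true_masks = masks,
         true_area_fraction = area_frac,
         true_overlap_fraction = overlap_frac,
         n_cells = stats::setNames(
           vapply(centers_by_channel, nrow, integer(1)), labels),
         seed = as.integer(seed)),
    class = "field_ground_truth"
  )
  list(field = field, truth = truth)
}

#' Generate a live/dead (green/red) field pair
#'
#' Emulates a calcein-AM / ethidium-homodimer viability assay: live cells
#' fluoresce in the green channel and dead cells in the red channel, with
#' disjoint masks. `round(live_fraction * n_cells)` cells are allocated to
#' the green channel and the remainder to red.
#'
#' @param live_fraction Fraction of live cells in \[0,1\].
#' @param n_cells Total cells (> 0).
#' @inheritParams generate_field
#' @param radius,intensity,blur_sigma,noise_sd Shared channel rendering
#'   parameters.
#' @return As [generate_field()]: `field` with channels "green" and "red"
#'   plus `truth`.
#' @export
generate_live_dead <- function(live_fraction, n_cells, shape = c(256, 256),
                               seed = 1L, radius = 6, intensity = 200,
                               blur_sigma = 0, noise_sd = 0,
                               field_id = "field1", well_id = "well1",
                               condition = list(dose_mM = NA_real_,
                                                status = "Diff")) {
  if (live_fraction < 0 || live_fraction > 1) {
    stop("live_fraction must lie in [0,1]")
  }
  if (n_cells < 1) stop("n_cells must be positive")
  n_live <- round(live_fraction * n_cells)
  n_dead <- n_cells - n_live

  centers <- withr::with_seed(as.integer(seed),
    place_centers(n_cells, shape, 2 * radius + 3, margin = radius + 1))
  g_centers <- centers[seq_len(n_live), , drop = FALSE]
  r_centers <- centers[setdiff(seq_len(n_cells), seq_len(n_live)), ,
                       drop = FALSE]

  specs <- list(
    green = channel_spec("green", intensity, radius, blur_sigma, noise_sd),
    red = channel_spec("red", intensity, radius, blur_sigma, noise_sd)
  )
  g <- render_discs(g_centers, radius, intensity, shape)
  r <- render_discs(r_centers, radius, intensity, shape)
  rasters <- list(
    green = finish_channel(g$raster, specs$green, channel_seed(seed, 1)),
    red = finish_channel(r$raster, specs$red, channel_seed(seed, 2))
  )
  npix <- prod(shape)
  field <- multi_channel_field(rasters, field_id = field_id,
                               well_id = well_id, condition = condition)
  truth <- structure(
    list(true_masks = list(green = g$mask, red = r$mask),
         true_area_fraction = c(green = sum(g$mask) / npix,
                                red = sum(r$mask) / npix),
         true_overlap_fraction = c("green|red" =
                                     sum(g$mask & r$mask) / npix),
         n_cells = c(green = n_live, red = n_dead),
         seed = as.integer(seed)),
    class = "field_ground_truth"
  )
  list(field = field, truth = truth)
}
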