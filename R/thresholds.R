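# Positive/negative threshold placement. Where antigens lack a clearly
# defined positive population, thresholds come either from an in-tube
# negative population or from a fluorescence-minus-one (FMO) control tube;
# valley detection between density modes is available as an opt-in
# alternative. All density work happens on the asinh display scale;
# thresholds are returned on the raw intensity scale.

#' Kernel-density modes and minima of a marker distribution
#'
#' Gaussian kernel density on the asinh scale (Silverman bandwidth); local
#' maxima below `min_peak_frac` of the tallest peak are ignored.
#'
#' @param x Raw intensities.
#' @param cofactor asinh cofactor.
#' @param min_peak_frac Minimum relative height for a peak to count.
#' @param n_grid Density grid size.
#' @return List with `peaks` (tibble: `location`, `height`, asinh scale),
#'   and the density grid (`grid_x`, `grid_y`).
#' @keywords internal
density_modes <- function(x, cofactor = 150, min_peak_frac = 0.01,
                          n_grid = 512) {
  y <- asinh_trans(x, cofactor)
  d <- density(y, n = n_grid)
  g <- d$y
  is_max <- c(FALSE, g[2:(n_grid - 1)] > g[1:(n_grid - 2)] &
    g[2:(n_grid - 1)] >= g[3:n_grid], FALSE)
  # boundary bins can hold a genuine mode (background piles up near zero)
  if (g[1] > g[2]) is_max[1] <- TRUE
  if (g[n_grid] > g[n_grid - 1]) is_max[n_grid] <- TRUE
  keep <- is_max & g >= min_peak_frac * max(g)
  list(
    peaks = tibble(location = d$x[keep], height = g[keep]),
    grid_x = d$x,
    grid_y = g
  )
}

# Merge adjacent density peaks that lack a genuine dip between them:
# kernel-density ripples along a shoulder or plateau are not expression
# peaks. Two neighbours are kept separate only when the density between
# them drops below `dip_frac` of the smaller peak; ripples barely dip
# (ratio near 1) while genuine expression peaks are cut by a deep valley.
prune_modes <- function(modes, dip_frac = 0.9) {
  pk <- arrange(modes$peaks, .data$location)
  repeat {
    if (nrow(pk) < 2) {
      return(pk)
    }
    merged <- FALSE
    for (i in seq_len(nrow(pk) - 1)) {
      lo <- pk$location[i]
      hi <- pk$location[i + 1]
      between <- modes$grid_x > lo & modes$grid_x < hi
      dip <- min(modes$grid_y[between])
      if (dip > dip_frac * min(pk$height[i], pk$height[i + 1])) {
        keep <- if (pk$height[i] >= pk$height[i + 1]) i else i + 1
        pk <- pk[-setdiff(c(i, i + 1), keep), ]
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      return(pk)
    }
  }
}

# Deepest density minimum strictly between two asinh locations; returns the
# asinh location of the minimum.
deepest_minimum <- function(modes, lo, hi) {
  between <- modes$grid_x > lo & modes$grid_x < hi
  xs <- modes$grid_x[between]
  ys <- modes$grid_y[between]
  xs[which.min(ys)]
}

#' Place a positivity threshold for one marker
#'
#' @param events An [event_table()] (the stained tube being analyzed).
#' @param marker Marker (or channel id) to threshold.
#' @param method `"fmo_quantile"` (quantile of the matched FMO tube's
#'   channel), `"negative_population_quantile"` (same quantile on a
#'   designated in-tube negative reference), or `"valley"` (deepest
#'   kernel-density minimum between the two largest modes).
#' @param quantile Quantile for the two quantile methods (default 0.995,
#'   bounding the false-positive rate on negatives at 0.5%).
#' @param reference For `fmo_quantile`: the FMO tube's `events` (an
#'   `event_tbl`). For `negative_population_quantile`: either a logical
#'   vector selecting the negative events of `events`, or a numeric vector
#'   of reference intensities.
#' @param cofactor asinh cofactor for valley detection.
#' @param min_peak_frac Valley detection: peaks below this fraction of the
#'   tallest peak are ignored.
#' @return Threshold on the raw intensity scale; events at or above it are
#'   called positive.
#' @examples
#' tube <- simulate_tube(default_profile("healthy_blood"), "Myeloid",
#'   n_events = 5000, seed = 1
#' )
#' place_threshold(tube$events, "CD14", method = "valley")
#' @export
place_threshold <- function(events, marker,
                            method = c(
                              "fmo_quantile",
                              "negative_population_quantile", "valley"
                            ),
                            quantile = 0.995, reference = NULL,
                            cofactor = 150, min_peak_frac = 0.01) {
  method <- rlang::arg_match(method)
  stopifnot(quantile > 0, quantile < 1)
  x <- marker_values(events, marker)
  if (method == "fmo_quantile") {
    if (is.null(reference)) abort("fmo_quantile needs an FMO tube.")
    ref <- if (inherits(reference, "event_tbl")) {
      marker_values(reference, marker)
    } else {
      reference
    }
    return(unname(quantile(ref, quantile)))
  }
  if (method == "negative_population_quantile") {
    if (is.null(reference)) {
      abort("negative_population_quantile needs a negative reference.")
    }
    ref <- if (is.logical(reference)) x[reference] else reference
    return(unname(quantile(ref, quantile)))
  }
  modes <- density_modes(x, cofactor, min_peak_frac)
  if (nrow(modes$peaks) < 2) {
    abort(c(
      sprintf("Channel %s looks unimodal; no valley to place.", marker),
      i = "Use an FMO tube (fmo_quantile) or a negative population instead."
    ))
  }
  two <- modes$peaks %>%
    arrange(dplyr::desc(.data$height)) %>%
    head(2) %>%
    arrange(.data$location)
  asinh_inv(deepest_minimum(modes, two$location[1], two$location[2]), cofactor)
}

# Negative reference used by the automatic threshold map: events in the
# lowest density mode of the marker (below the first minimum after the
# lowest peak); falls back to all events when the channel is unimodal.
# The peak floor is deliberately low so that rare positive populations
# (well under 1% of events) still register as a mode.
lowest_mode_reference <- function(x, cofactor = 150) {
  modes <- density_modes(x, cofactor, min_peak_frac = 0.001)
  if (nrow(modes$peaks) < 2) {
    return(rep(TRUE, length(x)))
  }
  pk <- arrange(modes$peaks, .data$location)
  cut <- deepest_minimum(modes, pk$location[1], pk$location[2])
  asinh_trans(x, cofactor) < cut
}

#' Side-scatter class cutpoints
#'
#' Places the SS-low/medium and SS-medium/high boundaries by valley
#' detection on asinh side scatter within the CD45-positive leukocytes
#' (scatter units are arbitrary, so boundaries are data-driven).
#'
#' @param events An [event_table()].
#' @param cd45_threshold CD45 positivity threshold (raw scale).
#' @param cofactor asinh cofactor for SS.
#' @return Named numeric `c(lo_med = , med_hi = )`, raw SS scale.
#' @export
ss_cutpoints <- function(events, cd45_threshold, cofactor = 150) {
  ss <- marker_values(events, "SS")
  keep <- marker_values(events, "CD45") >= cd45_threshold
  modes <- density_modes(ss[keep], cofactor)
  pk <- modes$peaks %>%
    arrange(dplyr::desc(.data$height)) %>%
    head(3) %>%
    arrange(.data$location)
  if (nrow(pk) < 3) {
    abort("Fewer than three side-scatter modes among CD45+ events.")
  }
  c(
    lo_med = asinh_inv(
      deepest_minimum(modes, pk$location[1], pk$location[2]), cofactor
    ),
    med_hi = asinh_inv(
      deepest_minimum(modes, pk$location[2], pk$location[3]), cofactor
    )
  )
}

#' Automatic threshold map for a tube
#'
#' Builds the named threshold map consumed by [apply_tree()]: a CD45
#' threshold (valley between debris and leukocytes), the two side-scatter
#' class boundaries, and one positivity threshold per requested marker. Per
#' marker the default is the 0.995 FMO quantile when a matched FMO tube is
#' supplied, otherwise the 0.995 quantile of the in-tube lowest-density-mode
#' negative reference.
#'
#' @param events An [event_table()].
#' @param markers Markers to threshold; defaults to every stained marker on
#'   the tube's panel except CD45.
#' @param fmo Named list of FMO tubes (`marker = event_tbl`).
#' @param valley_markers Markers with a clearly defined, well-separated
#'   positive population, gated at the density valley instead of a
#'   negative-reference quantile (an FMO tube, when supplied, still takes
#'   precedence).
#' @param quantile Quantile for FMO / negative-population thresholds.
#' @param cofactor asinh cofactor.
#' @return Named numeric vector: `CD45`, `SS.lo_med`, `SS.med_hi`, and one
#'   entry per marker.
#' @export
auto_thresholds <- function(events, markers = NULL, fmo = list(),
                            valley_markers = character(),
                            quantile = 0.995, cofactor = 150) {
  panel <- load_panel(attr(events, "panel"))
  if (is.null(markers)) {
    markers <- setdiff(panel_markers(panel), "CD45")
  }
  cd45 <- place_threshold(events, "CD45", "valley", cofactor = cofactor)
  ss <- ss_cutpoints(events, cd45, cofactor)
  out <- c(
    CD45 = cd45,
    SS.lo_med = unname(ss[["lo_med"]]), SS.med_hi = unname(ss[["med_hi"]])
  )
  for (m in markers) {
    out[m] <- if (!is.null(fmo[[m]])) {
      place_threshold(events, m,
        method = "fmo_quantile",
        quantile = quantile, reference = fmo[[m]]
      )
    } else if (m %in% valley_markers) {
      place_threshold(events, m,
        method = "valley",
        cofactor = cofactor, min_peak_frac = 0.001
      )
    } else {
      place_threshold(events, m,
        method = "negative_population_quantile", quantile = quantile,
        reference = lowest_mode_reference(
          marker_values(events, m), cofactor
        )
      )
    }
  }
  out
}
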