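# Star-coordinate ("radar") projection: each of up to 13 marker axes
# contributes a unit direction vector scaled by the event's normalized
# intensity; an event's 2D position is the unnormalized vector sum. This
# reproduces the two documented behaviors of the display: brighter markers
# push events farther from the center, and two bright markers on axes 180
# degrees apart cancel, so the event appears negative for both.

MAX_RADAR_AXES <- 13L

#' Configure radar axes
#'
#' @param events_for_scaling An [event_table()] used to anchor the per-axis
#'   intensity scale: anchors are the 1st and 99th percentiles of the asinh
#'   intensities on that tube.
#' @param markers Up to 13 markers.
#' @param angles Axis angles in radians; distinct modulo 2 pi. Default:
#'   evenly spaced starting at 90 degrees.
#' @param cofactor asinh display cofactor.
#' @return A `radar_config`: tibble with `marker`, `angle`, `scale_lo`,
#'   `scale_hi` and a `cofactor` attribute.
#' @export
configure_axes <- function(events_for_scaling, markers, angles = NULL,
                           cofactor = 150) {
  k <- length(markers)
  if (k < 1 || k > MAX_RADAR_AXES) {
    abort(sprintf(
      "A radar plot takes 1 to %d axes; got %d.", MAX_RADAR_AXES, k
    ))
  }
  if (is.null(angles)) {
    angles <- (pi / 2 + 2 * pi * (seq_len(k) - 1) / k) %% (2 * pi)
  }
  if (length(angles) != k) abort("markers and angles differ in length.")
  angles <- angles %% (2 * pi)
  if (k > 1 && min(stats::dist(angles)) < 1e-9) {
    abort("Duplicate axis angles.")
  }
  anchors <- purrr::map_dfr(markers, function(m) {
    y <- asinh_trans(marker_values(events_for_scaling, m), cofactor)
    qs <- quantile(y, c(0.01, 0.99))
    tibble(
      marker = m, scale_lo = unname(qs[1]),
      scale_hi = unname(qs[2])
    )
  })
  if (any(anchors$scale_hi <= anchors$scale_lo)) {
    abort("Degenerate axis scale: upper anchor not above lower anchor.")
  }
  cfg <- tibble(
    marker = markers, angle = angles,
    scale_lo = anchors$scale_lo, scale_hi = anchors$scale_hi
  )
  structure(cfg,
    cofactor = cofactor,
    class = c("radar_config", class(tibble()))
  )
}

#' The six-axis TBNK radar preset
#'
#' The incremental lymphocyte/monocyte arrangement: CD3, CD19 and CD56 at
#' 90, 210 and 330 degrees (the x,y,z-like tripod), with CD14, CD4 and CD8
#' interleaved at 30, 150 and 270 degrees.
#'
#' @inheritParams configure_axes
#' @return A `radar_config`.
#' @export
radar_preset_tbnk6 <- function(events_for_scaling, cofactor = 150) {
  configure_axes(
    events_for_scaling,
    markers = c("CD3", "CD14", "CD19", "CD4", "CD56", "CD8"),
    angles = c(90, 30, 210, 150, 330, 270) * pi / 180,
    cofactor = cofactor
  )
}

#' Project events onto radar coordinates
#'
#' Coordinate of event e: `sum_i s_i * (cos a_i, sin a_i)` where `s_i`
#' clips the asinh-scaled intensity into `[0, 1]` via the axis anchors. An
#' event at or below the lower anchor on every axis maps exactly to the
#' origin; an event fully positive on exactly two axes 180 degrees apart
#' also maps to the origin.
#'
#' @param events An [event_table()].
#' @param config A `radar_config`.
#' @param labels Optional per-event population labels carried through to
#'   the output (e.g. `tube$truth$label`).
#' @return Tibble with `.x`, `.y` (and `population` when labels are given),
#'   of class `radar_projection`.
#' @export
project <- function(events, config, labels = NULL) {
  s <- vapply(seq_len(nrow(config)), function(i) {
    y <- asinh_trans(
      marker_values(events, config$marker[i]), attr(config, "cofactor")
    )
    pmin(pmax(
      (y - config$scale_lo[i]) / (config$scale_hi[i] - config$scale_lo[i]),
      0
    ), 1)
  }, numeric(n_events(events)))
  s <- matrix(s, nrow = n_events(events))
  out <- tibble(
    .x = as.vector(s %*% cos(config$angle)),
    .y = as.vector(s %*% sin(config$angle))
  )
  if (!is.null(labels)) out$population <- labels
  class(out) <- c("radar_projection", class(out))
  out
}

#' Rotate a radar configuration
#'
#' Shifts every axis angle by `delta` (mod 2 pi). The projection rotates
#' rigidly: pairwise distances between projected events are invariant.
#'
#' @param config A `radar_config`.
#' @param delta Rotation in radians.
#' @return The rotated `radar_config`.
#' @export
rotate <- function(config, delta) {
  config$angle <- (config$angle + delta) %% (2 * pi)
  config
}

#' Scatter plot of a radar projection
#'
#' @param object A `radar_projection` from [project()].
#' @param ... Unused.
#' @return A ggplot, colored by population when labels were attached.
#' @exportS3Method ggplot2::autoplot
autoplot.radar_projection <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$.x, .data$.y)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if ("population" %in% names(object)) {
    p + ggplot2::geom_point(
      ggplot2::aes(color = .data$population),
      size = 0.3, alpha = 0.5
    )
  } else {
    p + ggplot2::geom_point(size = 0.3, alpha = 0.5)
  }
}
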