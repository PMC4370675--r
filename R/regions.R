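# Region-based marker profiling: per-marker histogram regions (N for the
# no-expression peak, then R1..R3 for successive positive peaks) and
# back-gating of region members onto forward/side scatter.

#' Derive expression regions for one marker
#'
#' Detects peaks of the marker's kernel density on the asinh scale and cuts
#' region boundaries at the density minima between successive peaks. The
#' lowest peak is the no-expression region N; higher peaks become R1, R2,
#' R3. Together the regions partition `[0, Inf)`.
#'
#' @param events An [event_table()].
#' @param marker Marker to profile.
#' @param cofactor asinh cofactor.
#' @param min_peak_frac Peaks below this fraction of the tallest peak are
#'   ignored.
#' @return A `marker_regions` tibble: `marker`, `label` (N, R1, ...), `lo`,
#'   `hi` (half-open raw-scale intervals, `hi = Inf` for the last). Errors
#'   with no detectable peak or more than four peaks.
#' @examples
#' tube <- simulate_tube(default_profile("healthy_blood"), "Myeloid",
#'   n_events = 20000, seed = 1
#' )
#' derive_marker_regions(tube$events, "CD33")
#' @export
derive_marker_regions <- function(events, marker, cofactor = 150,
                                  min_peak_frac = 0.01) {
  x <- marker_values(events, marker)
  modes <- density_modes(x, cofactor, min_peak_frac)
  pk <- prune_modes(modes)
  modes$peaks <- pk
  if (nrow(pk) < 1) abort(sprintf("No expression peak found for %s.", marker))
  if (nrow(pk) > 4) {
    abort(sprintf(
      "%d peaks found for %s; at most N plus three positive regions (R1-R3) are supported.",
      nrow(pk), marker
    ))
  }
  cuts <- purrr::map_dbl(seq_len(nrow(pk) - 1), function(i) {
    asinh_inv(
      deepest_minimum(modes, pk$location[i], pk$location[i + 1]), cofactor
    )
  })
  lo <- c(0, cuts)
  hi <- c(cuts, Inf)
  positive <- if (nrow(pk) > 1) paste0("R", seq_len(nrow(pk) - 1)) else NULL
  out <- tibble(
    marker = marker,
    label = c("N", positive),
    lo = lo,
    hi = hi
  )
  class(out) <- c("marker_regions", class(out))
  out
}

#' Assign each event to a marker region
#'
#' @param events An [event_table()].
#' @param regions A `marker_regions` tibble from [derive_marker_regions()].
#' @return Character vector of region labels, one per event; every event
#'   falls in exactly one region (intervals are half-open `[lo, hi)`).
#' @export
assign_regions <- function(events, regions) {
  x <- marker_values(events, regions$marker[1])
  lab <- regions$label[findInterval(x, c(regions$lo, Inf),
    rightmost.closed = FALSE
  )]
  lab
}

#' Back-gate a population onto forward/side scatter
#'
#' Summarizes where a gated set of events sits on FS x SS: the centroid,
#' dispersion, and (when side-scatter class boundaries are supplied) the
#' scatter class of the centroid. This is the histogram-region back-gating
#' used to read which scatter compartment each expression region occupies.
#'
#' @param events An [event_table()].
#' @param gate Logical event membership (a region or gate).
#' @param ss_cuts Optional `c(lo_med =, med_hi =)` from [ss_cutpoints()].
#' @return One-row tibble: `n`, `fs_centroid`, `ss_centroid`, `fs_sd`,
#'   `ss_sd`, and `ss_class` (`"SS_lo"`, `"SS_med"`, `"SS_hi"`, or `NA`
#'   without cutpoints). Empty gate: zero-row tibble.
#' @export
backgate_scatter <- function(events, gate, ss_cuts = NULL) {
  fs <- events$FS[gate]
  ss <- events$SS[gate]
  if (length(fs) == 0) {
    return(tibble(
      n = integer(), fs_centroid = double(), ss_centroid = double(),
      fs_sd = double(), ss_sd = double(), ss_class = character()
    ))
  }
  ctr <- median(ss)
  cls <- if (is.null(ss_cuts)) {
    NA_character_
  } else if (ctr < ss_cuts[["lo_med"]]) {
    "SS_lo"
  } else if (ctr < ss_cuts[["med_hi"]]) {
    "SS_med"
  } else {
    "SS_hi"
  }
  tibble(
    n = length(fs),
    fs_centroid = median(fs), ss_centroid = ctr,
    fs_sd = stats::sd(fs), ss_sd = stats::sd(ss),
    ss_class = cls
  )
}
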