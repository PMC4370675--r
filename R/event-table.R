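# Event tables: one row per acquired event, one column per channel
# (FS, SS, TIME, FL1..FL10). Values are compensated linear fluorescence
# intensities in arbitrary units; compensation itself is out of scope and
# inputs are assumed compensated.

#' Construct an event table
#'
#' An event table is a tibble with one row per event and one column per
#' cytometer channel, carrying the panel's channel-to-marker map as
#' attributes so downstream operations can address channels by marker name.
#'
#' @param values A data frame or matrix whose columns are channel ids
#'   (`FS`, `SS`, `TIME`, and the panel's `FL` channels).
#' @param panel A `panel_definition` or panel name; defines the
#'   channel-to-marker map.
#' @details Negative values (possible in externally compensated data) are
#'   clipped at zero with a warning: all gates and projections here are
#'   defined on non-negative scales.
#' @return A tibble of class `event_tbl` with attributes `panel` (name) and
#'   `channel_map`.
#' @export
event_table <- function(values, panel) {
  panel <- as_panel(panel)
  values <- as_tibble(as.data.frame(values))
  needed <- panel$channels$channel_id
  missing <- setdiff(needed, names(values))
  if (length(missing) > 0) {
    abort(sprintf(
      "Event data is missing channel(s): %s", paste(missing, collapse = ", ")
    ))
  }
  values <- values[needed]
  if (anyNA(values)) {
    abort("Event data contains missing values.")
  }
  neg <- vapply(values, function(v) any(v < 0), logical(1))
  if (any(neg)) {
    warn(sprintf(
      "Negative intensities clipped to 0 on channel(s): %s",
      paste(names(values)[neg], collapse = ", ")
    ))
    values <- dplyr::mutate(values, dplyr::across(
      dplyr::everything(), ~ pmax(., 0)
    ))
  }
  new_event_tbl(values, panel)
}

new_event_tbl <- function(values, panel) {
  structure(
    values,
    panel = panel$name,
    channel_map = panel$channels,
    class = c("event_tbl", class(tibble()))
  )
}

#' @export
print.event_tbl <- function(x, ...) {
  cat(sprintf(
    "<event_tbl> %d events, panel %s\n", nrow(x), attr(x, "panel")
  ))
  NextMethod()
}

#' Number of events in an event table
#' @param events An `event_tbl`.
#' @return Integer count.
#' @export
n_events <- function(events) nrow(events)

#' Look up the channel carrying a marker
#'
#' @param events An `event_tbl`.
#' @param marker A marker name (e.g. `"CD123"`) or a channel id
#'   (`"FS"`, `"SS"`, `"TIME"`, `"FL1"`..).
#' @return The channel id as a string.
#' @export
marker_channel <- function(events, marker) {
  cm <- attr(events, "channel_map")
  if (is.null(cm)) abort("Not an event table: no channel map attribute.")
  if (marker %in% cm$channel_id) {
    return(marker)
  }
  hit <- cm$channel_id[cm$marker == marker]
  if (length(hit) != 1L) {
    abort(sprintf(
      "Marker '%s' is not on panel %s.", marker, attr(events, "panel")
    ))
  }
  hit
}

#' Per-event intensities for a marker
#'
#' @inheritParams marker_channel
#' @return Numeric vector of length `n_events(events)`.
#' @export
marker_values <- function(events, marker) {
  events[[marker_channel(events, marker)]]
}

#' Subset an event table by row, keeping its channel map
#'
#' @param events An `event_tbl`.
#' @param keep Logical or integer row index.
#' @return An `event_tbl` with the selected events.
#' @export
subset_events <- function(events, keep) {
  out <- as_tibble(as.data.frame(events)[keep, , drop = FALSE])
  attr(out, "panel") <- attr(events, "panel")
  attr(out, "channel_map") <- attr(events, "channel_map")
  class(out) <- c("event_tbl", class(tibble()))
  out
}

#' Validate an event table against a panel
#'
#' Report-based validation: checks the channel set against the panel, flags
#' negative intensities beyond a tolerance, and checks that acquisition TIME
#' is non-decreasing.
#'
#' @param events A tibble of event data (need not be a built `event_tbl`).
#' @param panel A `panel_definition` or panel name.
#' @param neg_tol Magnitude of negative values tolerated (arbitrary units).
#' @return A tibble with columns `check`, `pass`, `detail`; the table passes
#'   iff all rows pass (see [validation_passed()]).
#' @export
validate_events <- function(events, panel, neg_tol = 1e-6) {
  panel <- as_panel(panel)
  needed <- panel$channels$channel_id
  missing <- setdiff(needed, names(events))
  checks <- tibble(
    check = "channels",
    pass = length(missing) == 0,
    detail = if (length(missing) == 0) "" else
      paste("missing:", paste(missing, collapse = ", "))
  )
  present <- intersect(needed, names(events))
  num <- as.data.frame(events)[present]
  bad_neg <- names(num)[vapply(num, function(v) any(v < -neg_tol), logical(1))]
  checks <- bind_rows(checks, tibble(
    check = "non_negative",
    pass = length(bad_neg) == 0,
    detail = if (length(bad_neg) == 0) "" else
      paste("negative beyond tolerance:", paste(bad_neg, collapse = ", "))
  ))
  time_ok <- !("TIME" %in% names(events)) || !is.unsorted(events$TIME)
  checks <- bind_rows(checks, tibble(
    check = "time_monotone",
    pass = time_ok,
    detail = if (time_ok) "" else "TIME is not non-decreasing"
  ))
  checks
}

#' @rdname validate_events
#' @param report A report returned by [validate_events()].
#' @export
validation_passed <- function(report) all(report$pass)
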