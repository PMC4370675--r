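# Registry of the eight published 10-color staining panels plus the two
# instrument-verification tubes. The registry ships as a structured text
# resource (inst/extdata/panels.tsv); each row assigns a marker to each of
# the ten fluorescence channels FL1..FL10. The pan gamma/delta T-cell
# receptor antibody is written "gdTCR" throughout.

the <- new.env(parent = emptyenv())

panel_registry_path <- function() {
  system.file("extdata", "panels.tsv", package = "leukogate", mustWork = TRUE)
}

read_panel_registry <- function() {
  if (!is.null(the$registry)) {
    return(the$registry)
  }
  reg <- readr::read_tsv(panel_registry_path(), col_types = readr::cols(
    name = "c", wash_mode = "c", is_verify = "l", .default = "c"
  ))
  the$registry <- reg
  reg
}

fl_channels <- function() paste0("FL", 1:10)

#' List the registered panels
#'
#' @param include_verify Include the instrument-verification tubes
#'   (`Verify-LNW`, `Verify-LW`)? They are excluded from analysis-panel
#'   enumeration by default.
#' @return A tibble with one row per panel: `name`, `wash_mode`
#'   (`lyse_no_wash` or `lyse_wash`), `is_verify`, and the marker assigned to
#'   each fluorescence channel `FL1`..`FL10` (`"unstained"` for empty
#'   channels).
#' @examples
#' list_analysis_panels()
#' @export
list_analysis_panels <- function(include_verify = FALSE) {
  reg <- read_panel_registry()
  if (!include_verify) {
    reg <- dplyr::filter(reg, !.data$is_verify)
  }
  reg
}

#' Load a panel definition
#'
#' Looks a staining panel up by name and returns its definition, including
#' the channel-to-marker map used by the simulator, the gating trees and the
#' radar projection.
#'
#' @param name Panel name, e.g. `"TBNK/M/G"` or `"Myeloid"`.
#' @return An object of class `panel_definition`: a list with `name`,
#'   `wash_mode`, `is_verify` and `channels` (a tibble with `channel_id`,
#'   `marker`, `fluorochrome`). Scatter (`FS`, `SS`) and `TIME` channels are
#'   always present. Fluorochrome assignments are optional metadata and left
#'   blank by default.
#' @examples
#' load_panel("Myeloid")$channels
#' @export
load_panel <- function(name) {
  reg <- read_panel_registry()
  row <- dplyr::filter(reg, .data$name == !!name)
  if (nrow(row) != 1L) {
    abort(c(
      sprintf("Unknown panel '%s'.", name),
      i = paste("Valid panels:", paste(reg$name, collapse = ", "))
    ))
  }
  markers <- unlist(row[fl_channels()], use.names = FALSE)
  channels <- tibble(
    channel_id = c("FS", "SS", "TIME", fl_channels()),
    marker = c("scatter", "scatter", "time", markers),
    fluorochrome = ""
  )
  structure(
    list(
      name = row$name,
      wash_mode = row$wash_mode,
      is_verify = row$is_verify,
      channels = channels
    ),
    class = "panel_definition"
  )
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf(
    "<panel_definition> %s (%s%s)\n", x$name, x$wash_mode,
    if (x$is_verify) ", verify" else ""
  ))
  fl <- dplyr::filter(x$channels, grepl("^FL", .data$channel_id))
  cat(paste(sprintf("%s=%s", fl$channel_id, fl$marker), collapse = " "), "\n")
  invisible(x)
}

#' Markers stained in a panel
#'
#' @param panel A `panel_definition` or panel name.
#' @return Character vector of stained markers (composite cocktails such as
#'   `LIN2` count as one marker; `"unstained"` channels are dropped).
#' @export
panel_markers <- function(panel) {
  panel <- as_panel(panel)
  fl <- dplyr::filter(panel$channels, grepl("^FL", .data$channel_id))
  setdiff(fl$marker, "unstained")
}

as_panel <- function(panel) {
  if (inherits(panel, "panel_definition")) panel else load_panel(panel)
}
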