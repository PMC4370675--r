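# Cohort reports: the same saved tree and threshold policy applied
# identically across samples, with absolute counts from in-tube beads
# (lyse/no-wash) or anchored to a matched counting tube (lyse/wash).
# The analysis path is seed-free: the same inputs give a byte-identical
# report.

#' Run a gating protocol over a cohort
#'
#' @param samples Named list of tubes: [event_table()]s, results of
#'   [simulate_tube()], or file paths readable by [read_events()]. Names
#'   become sample ids.
#' @param panel Panel all samples were stained with (consistency is
#'   enforced).
#' @param tree The `gating_tree` to apply.
#' @param fmo Named list of FMO tubes shared across samples, for
#'   thresholds.
#' @param bead_conc_per_ul Fluorosphere lot concentration; when given
#'   (lyse/no-wash), beads are gated per tube and absolute counts computed
#'   with the counting formula.
#' @param anchor_cd45_per_ul Named numeric: CD45+ cells/ul per sample from
#'   the matched counting tube. When given (lyse/wash), counts are
#'   anchored: `pct_of_CD45 / 100 * CD45_per_ul`.
#' @param timepoints Optional vector parallel to `samples`.
#' @return A `cohort_report` tibble: one row per (sample, timepoint,
#'   population) with `n_events`, `pct_of_parent`, `pct_of_grandparent`
#'   (0.1% granularity) and `cells_per_ul` (whole cells) when computable.
#'   The applied thresholds are attached as attribute `"log"`.
#' @export
run_protocol <- function(samples, panel, tree, fmo = list(),
                         bead_conc_per_ul = NULL,
                         anchor_cd45_per_ul = NULL, timepoints = NULL) {
  panel <- as_panel(panel)
  if (is.null(names(samples)) || any(names(samples) == "")) {
    abort("`samples` must be a fully named list.")
  }
  if (is.null(timepoints)) timepoints <- seq_along(samples)
  if (!is.null(bead_conc_per_ul) && panel$wash_mode != "lyse_no_wash") {
    abort("Bead-based counting needs the lyse/no-wash panel.")
  }
  fmo <- lapply(fmo, function(t) {
    if (inherits(t, "event_tbl")) t else t$events
  })
  root <- tree$nodes$name[is.na(tree$nodes$parent)]
  tubes <- purrr::imap(samples, function(s, id) {
    events <- if (is.character(s)) {
      read_events(s)
    } else if (inherits(s, "event_tbl")) {
      s
    } else {
      s$events
    }
    if (!identical(attr(events, "panel"), panel$name)) {
      abort(sprintf(
        "Sample '%s' was stained with panel %s, not %s: one panel per run.",
        id, attr(events, "panel"), panel$name
      ))
    }
    events
  })
  logs <- list()
  rows <- purrr::map2_dfr(names(samples), seq_along(samples), function(id, i) {
    events <- tubes[[i]]
    beads <- if (!is.null(bead_conc_per_ul)) gate_beads(events) else NULL
    res <- gate_tube(events, tree, fmo = fmo, beads = beads)
    logs[[id]] <<- res$thresholds
    out <- tidy(res)
    out$cells_per_ul <- if (!is.null(bead_conc_per_ul)) {
      round(absolute_count(out$n_events, bead_conc_per_ul, beads$n))
    } else if (!is.null(anchor_cd45_per_ul)) {
      n_root <- out$n_events[out$population == root]
      round(anchor_counts(
        100 * out$n_events / max(n_root, 1), anchor_cd45_per_ul[[id]]
      ))
    } else {
      NA_real_
    }
    dplyr::mutate(out,
      sample = id, timepoint = timepoints[i],
      pct_of_parent = round(.data$pct_of_parent, 1),
      pct_of_grandparent = round(.data$pct_of_grandparent, 1),
      .before = 1
    )
  })
  structure(
    dplyr::select(
      rows, "sample", "timepoint", "population", "n_events",
      "pct_of_parent", "pct_of_grandparent", "cells_per_ul"
    ),
    log = list(
      thresholds = logs,
      package_version = as.character(utils::packageVersion("leukogate"))
    ),
    class = c("cohort_report", class(tibble()))
  )
}
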