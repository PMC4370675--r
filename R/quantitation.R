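# Single-platform absolute counting with Flow-Count style fluorospheres,
# plus geometric MFI and rank correlation.
#
#   cells/ul = count(phenotype) x (fluorospheres/ul) / count(CAL)
#
# where count(CAL) is the total number of fluorospheres counted during the
# run.

#' Gate counting beads
#'
#' Two sequential gates isolate the fluorospheres: a bright FL2 band across
#' acquisition TIME, then the bright FL4 x forward-scatter cluster. The
#' second step removes any leukocytes or debris left in the FL2 band.
#'
#' @param events An [event_table()] from a lyse/no-wash tube.
#' @param cofactor asinh cofactor for the FL2 valley search.
#' @param cell_quantile The FL4 bead cut is this quantile of FL4 among the
#'   events outside the FL2 band (the cells): beads are engineered to be
#'   multi-channel bright, far above stained cells.
#' @param fs_k Width of the forward-scatter cluster filter, in robust SDs
#'   (median absolute deviations) around the candidate median.
#' @return A `bead_gate`: list with `n` (the CAL count), `index` (logical
#'   event membership) and the two channel thresholds. Errors when no bead
#'   cluster is found.
#' @export
gate_beads <- function(events, cofactor = 150, cell_quantile = 0.9999,
                       fs_k = 5) {
  no_cluster <- function() {
    abort(c(
      "No bead cluster found on FL2/FL4.",
      i = "Was this tube acquired with counting beads (lyse/no-wash)?"
    ))
  }
  fl2_thr <- tryCatch(
    place_threshold(events, "FL2", "valley", cofactor = cofactor),
    error = function(e) no_cluster()
  )
  band <- events$FL2 >= fl2_thr
  if (sum(band) < 10) no_cluster()
  fl4_thr <- unname(quantile(events$FL4[!band], cell_quantile))
  cand <- band & events$FL4 >= fl4_thr
  if (sum(cand) < 10) no_cluster()
  fs <- events$FS[cand]
  ctr <- median(fs)
  spread <- mad(fs)
  idx <- cand & abs(events$FS - ctr) <= fs_k * max(spread, 1)
  structure(
    list(
      n = sum(idx), index = idx,
      fl2_threshold = fl2_thr, fl4_threshold = fl4_thr
    ),
    class = "bead_gate"
  )
}

#' @export
print.bead_gate <- function(x, ...) {
  cat(sprintf("<bead_gate> %d fluorospheres counted\n", x$n))
  invisible(x)
}

#' Absolute cell concentration from bead counts
#'
#' `cells/ul = n_phenotype * beads_conc_per_ul / n_beads_counted`: the
#' single-platform counting formula. Linear in `n_phenotype` and invariant
#' under joint scaling of phenotype and bead counts.
#'
#' @param n_phenotype Events counted in the phenotype gate.
#' @param beads_conc_per_ul Fluorosphere lot concentration (per ul of
#'   prepared sample).
#' @param n_beads_counted Total fluorospheres counted during the run
#'   ("CAL"); must be positive.
#' @return Cells per microliter (vectorized over `n_phenotype`).
#' @examples
#' absolute_count(4000, 1000, 2000) # 2000 cells/ul
#' @export
absolute_count <- function(n_phenotype, beads_conc_per_ul, n_beads_counted) {
  if (any(n_beads_counted <= 0)) {
    abort("n_beads_counted must be positive: no fluorospheres were counted.")
  }
  n_phenotype * beads_conc_per_ul / n_beads_counted
}

#' Anchor lyse/wash percentages to counting-tube concentrations
#'
#' Lyse/wash panels carry no beads; their phenotypes are converted to
#' absolute counts through the CD45+ concentration measured on the matched
#' lyse/no-wash counting tube.
#'
#' @param lw_pct_of_cd45 Phenotype size as percent of CD45+ leukocytes on
#'   the lyse/wash tube.
#' @param tbnk_cd45_per_ul CD45+ leukocytes per ul from the counting tube.
#' @return Cells per microliter.
#' @examples
#' anchor_counts(50, 6000) # 3000
#' @export
anchor_counts <- function(lw_pct_of_cd45, tbnk_cd45_per_ul) {
  stopifnot(all(lw_pct_of_cd45 >= 0), all(tbnk_cd45_per_ul >= 0))
  lw_pct_of_cd45 / 100 * tbnk_cd45_per_ul
}

#' Geometric mean fluorescence intensity within a gate
#'
#' `exp(mean(log(x)))` over the gated events' intensities: the standard
#' summary for log-normally distributed fluorescence. Scale-equivariant:
#' scaling all intensities by k scales the geometric MFI by k.
#'
#' @param events An [event_table()].
#' @param gate Logical event membership (e.g. from [gate_membership()]), or
#'   `NULL` for all events.
#' @param marker Marker or channel to summarize.
#' @param population Optional population label for the output.
#' @return One-row tibble: `population`, `marker`, `geo_mfi`, `n`. With an
#'   empty gate, `n` is 0 and `geo_mfi` is `NA`.
#' @export
geometric_mfi <- function(events, gate, marker, population = NA_character_) {
  x <- marker_values(events, marker)
  if (!is.null(gate)) x <- x[gate]
  x <- x[x > 0]
  tibble(
    population = population,
    marker = marker,
    geo_mfi = if (length(x) == 0) NA_real_ else exp(mean(log(x))),
    n = length(x)
  )
}

#' Geometric MFI of several populations and markers
#'
#' @param result A `gating_result`.
#' @param events The gated [event_table()].
#' @param populations Population names from the tree.
#' @param markers Markers to summarize.
#' @return Tibble with one row per population x marker.
#' @export
population_mfi <- function(result, events, populations, markers) {
  purrr::map_dfr(populations, function(p) {
    m <- gate_membership(result, p)
    purrr::map_dfr(markers, function(mk) {
      geometric_mfi(events, m, mk, population = p)
    })
  })
}

#' Spearman rank correlation
#'
#' Standard two-sided Spearman test, as used to relate phenotype
#' percentages to absolute counts across a cohort. Exact p-values for
#' n <= 10; the large-sample t approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  if (length(x) < 3) abort("Need at least 3 pairs.")
  ct <- suppressWarnings(cor.test(x, y,
    method = "spearman",
    alternative = "two.sided", exact = length(x) <= 10
  ))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
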