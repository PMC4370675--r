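# The non-overlapping myeloid phenotype nomenclature: nine classes (CM1 -
# CM9) defined by scatter class and per-marker expression levels, shipped
# as a structured-text table. Levels in the catalog are "-", "lo", "+",
# "++", with "+/-" and "-/+" matching anything and "lo/neg" matching
# no-to-dim expression. CM4 is the subset of CM1-CM3 where HLA-DR has been
# lost. Basophils are flagged as a contamination within CM7 rather than a
# tenth class.

catalog_path <- function() {
  system.file("extdata", "myeloid_catalog.tsv",
    package = "leukogate",
    mustWork = TRUE
  )
}

#' The myeloid phenotype catalog
#'
#' @return Tibble of the nine myeloid classes: `code` (CM1..CM9),
#'   `common_name`, `function_note`, scatter class `ss` and one level
#'   column per discriminating marker.
#' @export
myeloid_catalog <- function() {
  if (is.null(the$catalog)) {
    the$catalog <- readr::read_tsv(
      catalog_path(),
      col_types = readr::cols(.default = "c")
    )
  }
  the$catalog
}

catalog_markers <- function() {
  setdiff(names(myeloid_catalog()), c("code", "common_name", "function_note", "ss"))
}

level_rank <- function(level) {
  switch(level, "lo" = 1L, "+" = 2L, "++" = 3L, NA_integer_)
}

# Region labels a catalog level matches, interpreted per marker: the
# positive levels that appear in a marker's catalog column are ranked
# (lo < + < ++) and assigned ascending regions R1, R2, ...; the highest
# level present also matches any brighter region. "-" is the N region;
# "lo/neg" spans N and the dimmest positive region; "+/-" and "-/+" match
# any region.
allowed_regions <- function(level, column) {
  if (level %in% c("+/-", "-/+")) {
    return(c("N", "R1", "R2", "R3"))
  }
  if (level == "-") {
    return("N")
  }
  ranks <- sort(unique(stats::na.omit(c(
    vapply(column, level_rank, integer(1)),
    if (any(column == "lo/neg")) 1L
  ))))
  if (level == "lo/neg") {
    return(c("N", "R1"))
  }
  i <- match(level_rank(level), ranks)
  if (i == length(ranks)) paste0("R", i:3) else paste0("R", i)
}

#' Build a region profile
#'
#' @param ss Scatter class: `"lo"`, `"med"` or `"hi"` (alternatively
#'   `"SS_lo"` etc.).
#' @param ... Marker region assignments, e.g. `CD33 = "R2"`. Values are
#'   region labels `"N"`, `"R1"`, `"R2"`, `"R3"` or `"any"`. Markers not
#'   given are treated as `"any"`.
#' @return A `region_profile` list.
#' @export
region_profile <- function(ss, ...) {
  ss <- sub("^SS_", "", ss)
  stopifnot(ss %in% c("lo", "med", "hi"))
  assignments <- c(...)
  bad <- setdiff(assignments, c("N", "R1", "R2", "R3", "any"))
  if (length(bad) > 0) {
    abort(paste("Invalid region label(s):", paste(bad, collapse = ", ")))
  }
  structure(
    list(ss = ss, assignments = assignments),
    class = "region_profile"
  )
}

#' Classify a region profile into the myeloid nomenclature
#'
#' Matches a scatter class plus per-marker region profile against the nine
#' catalog classes. The catalog is pairwise disjoint: a profile matches at
#' most one class. Contradictory or out-of-catalog profiles return
#' `"unclassified"`.
#'
#' @param profile A [region_profile()].
#' @return One-row tibble: `code`, `common_name`, `function_note` (all
#'   `"unclassified"` when nothing matches).
#' @examples
#' classify_myeloid(region_profile("lo",
#'   CD33 = "R1", CD11b = "R2", CD14 = "N", CD16 = "N",
#'   `HLA-DR` = "N", CD15 = "N", CD66b = "N", CD123 = "R1"
#' ))
#' @export
classify_myeloid <- function(profile) {
  stopifnot(inherits(profile, "region_profile"))
  cat <- myeloid_catalog()
  hit <- purrr::map_lgl(seq_len(nrow(cat)), function(i) {
    row <- cat[i, ]
    if (row$ss != profile$ss) {
      return(FALSE)
    }
    all(purrr::map_lgl(catalog_markers(), function(m) {
      p <- if (m %in% names(profile$assignments)) {
        unname(profile$assignments[[m]])
      } else {
        "any"
      }
      if (is.na(p) || p == "any") {
        return(TRUE)
      }
      p %in% allowed_regions(row[[m]], cat[[m]])
    }))
  })
  if (sum(hit) == 0) {
    return(tibble(
      code = "unclassified", common_name = "unclassified",
      function_note = "unclassified"
    ))
  }
  if (sum(hit) > 1) {
    abort(paste(
      "Profile matches several classes:",
      paste(cat$code[hit], collapse = ", ")
    ))
  }
  dplyr::select(cat[hit, ], "code", "common_name", "function_note")
}

#' Dominant region profile of a gated population
#'
#' Builds the [region_profile()] a gated population presents: per marker,
#' the modal region of its events; the scatter class comes from
#' [backgate_scatter()].
#'
#' @param events An [event_table()].
#' @param gate Logical event membership.
#' @param regions_list Named list of `marker_regions`
#'   (see [derive_marker_regions()]).
#' @param ss_cuts Side-scatter class boundaries from [ss_cutpoints()].
#' @return A `region_profile`.
#' @export
profile_population <- function(events, gate, regions_list, ss_cuts) {
  bg <- backgate_scatter(events, gate, ss_cuts)
  if (nrow(bg) == 0) abort("Empty gate: no profile to derive.")
  sub <- subset_events(events, gate)
  labs <- purrr::map_chr(regions_list, function(r) {
    lab <- assign_regions(sub, r)
    names(which.max(table(lab)))
  })
  names(labs) <- purrr::map_chr(regions_list, ~ .$marker[1])
  do.call(region_profile, c(list(ss = bg$ss_class), as.list(labs)))
}

#' Count the phenotypes a gating tree reports
#'
#' All named populations, parents and leaves alike: the non-overlapping
#' phenotype count of the hierarchy.
#'
#' @param tree A `gating_tree`.
#' @return Integer count.
#' @export
enumerate_phenotypes <- function(tree) {
  validate_tree(tree)
  length(tree_populations(tree))
}

#' Combinatorial bound on measurable phenotypes
#'
#' With n informative markers per 10-color protocol (CD45 excluded) and p
#' protocols, ordered marker combinations bound the number of definable
#' phenotypes at `n! * p`: 9! x 8 = 2,903,040 across the full panel set.
#'
#' @param n_markers Markers per protocol (>= 0).
#' @param n_protocols Number of protocols.
#' @return `factorial(n_markers) * n_protocols`.
#' @examples
#' combinatorial_bound(9, 8)
#' @export
combinatorial_bound <- function(n_markers, n_protocols) {
  stopifnot(n_markers >= 0)
  factorial(n_markers) * n_protocols
}
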