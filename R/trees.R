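# The three encoded gating hierarchies. Threshold names referenced here are
# supplied at apply time: marker names (from auto_thresholds), the
# side-scatter class boundaries SS.lo_med / SS.med_hi, and the bright/dim
# cutpoints CD14.hi (TBNK, Monocytes) and LIN2.hi (Myeloid), which separate
# classical from non-classical monocytes.

root_cd45 <- function() {
  gate_node("CD45+ WBC", clauses = list(gate_clause("CD45", ">=", "CD45")))
}

ss_split <- function() {
  bind_rows(
    gate_node(
      "Mononuclear cells", "CD45+ WBC", "ss",
      list(gate_clause("SS", "<", "SS.med_hi"))
    ),
    gate_node(
      "Granulocytes", "CD45+ WBC", "ss",
      list(gate_clause("SS", ">=", "SS.med_hi")),
      color = "brown"
    )
  )
}

granulocyte_leaves <- function() {
  quadrant_nodes(
    "Granulocytes", "cd15xcd16", "CD15", "CD16",
    c(
      "Neutrophils", "Eosinophils",
      "CD15- CD16+ granulocytes", "CD15- CD16- granulocytes"
    )
  )
}

#' The TBNK/M/G gating tree
#'
#' Encodes the lyse/no-wash counting protocol's hierarchy: CD45+ leukocytes
#' split by side scatter into mononuclear cells and granulocytes; a CD14
#' histogram removes monocytes from the lymphocyte compartment; CD19xCD3
#' and CD4xCD8 quadrants enumerate B and T subsets with a gamma/delta TCR
#' histogram overlay reported alongside the quadrants (gamma/delta T cells
#' may express CD4 or CD8 abnormally); CD16xCD56 quadrants resolve the NK
#' compartment and lineage-negative lymphocytes; CD14xCD16 resolves
#' classical, intermediate and non-classical monocytes; and CD15xCD16
#' resolves neutrophils and eosinophils within high side scatter. Yields
#' more than 20 distinct, non-overlapping named phenotypes.
#'
#' @return A `gating_tree`.
#' @examples
#' build_tbnk_tree()
#' @export
build_tbnk_tree <- function() {
  nodes <- bind_rows(
    root_cd45(),
    ss_split(),
    gate_node(
      "Lymphocytes", "Mononuclear cells", "cd14",
      list(gate_clause("CD14", "<", "CD14")),
      color = "orange"
    ),
    gate_node(
      "CD14+ monocytes", "Mononuclear cells", "cd14",
      list(gate_clause("CD14", ">=", "CD14")),
      color = "purple"
    ),
    quadrant_nodes(
      "Lymphocytes", "cd19xcd3", "CD19", "CD3",
      c(
        "CD19+CD3+ cells", "B cells", "T cells",
        "CD3-CD19- lymphocytes"
      ),
      colors = c(NA, "blue", "red", NA)
    ),
    quadrant_nodes(
      "T cells", "cd4xcd8", "CD4", "CD8",
      c(
        "CD4+CD8+ T cells", "CD4+ T cells", "CD8+ T cells",
        "CD4-CD8- T cells"
      )
    ),
    gate_node(
      "gamma-delta T cells", "T cells", NA_character_,
      list(gate_clause("gdTCR", ">=", "gdTCR"))
    ),
    quadrant_nodes(
      "CD3-CD19- lymphocytes", "cd16xcd56", "CD56", "CD16",
      c(
        "CD56+CD16+ NK cells", "CD56+CD16- NK cells",
        "CD16+CD56- cells", "Lineage-negative lymphocytes"
      ),
      colors = c("black", "black", NA, NA)
    ),
    quadrant_nodes(
      "CD14+ monocytes", "cd14xcd16", "CD14", "CD16",
      c(
        "Intermediate monocytes", "Classical monocytes",
        "Non-classical monocytes", "CD14lo CD16- monocytes"
      ),
      thrx = "CD14.hi",
      colors = c("orange", "blue", "purple", NA)
    ),
    granulocyte_leaves()
  )
  # gamma/delta TCR shows a clearly separated bright population in its
  # channel, so its gate sits at the density valley
  new_gating_tree("TBNK/M/G", nodes, valley_markers = "gdTCR")
}

#' The Myeloid gating tree
#'
#' Myeloid cells are separated from other mononuclear cells on LIN2xCD33
#' (the CD33+ gate); LIN2xHLA-DR quadrants then resolve mature monocytes
#' (LIN2+HLA-DR+), HLA-DRlo/neg monocytes (monocytic MDSC; LIN2+HLA-DR-),
#' circulating dendritic cells (LIN2-HLA-DR+) and the combined MDSC/imMC
#' gate (LIN2-HLA-DR-). The SS-low subset of the MDSC/imMC gate is the
#' immature myeloid cell gate (SSlo LIN2- CD33+ HLA-DR-). Mature monocytes
#' are subgrouped on LIN2xCD16 (LIN2 serving as a CD14 surrogate on this
#' panel), dendritic cells on CD16 and CD11cxCD123, and granulocytes on
#' CD15xCD16 within high side scatter. CD33xCD11b is deliberately not a
#' gating step: those two markers alone do not separate MDSCs from other
#' myeloid subsets (use [backgate_scatter()] to inspect them).
#'
#' @return A `gating_tree`.
#' @export
build_myeloid_tree <- function() {
  nodes <- bind_rows(
    root_cd45(),
    ss_split(),
    gate_node(
      "Myeloid cells", "Mononuclear cells", NA_character_,
      list(gate_clause("CD33", ">=", "CD33"))
    ),
    quadrant_nodes(
      "Myeloid cells", "lin2xdr", "LIN2", "HLA-DR",
      c(
        "Mature monocytes", "HLA-DRlo/neg monocytes",
        "Dendritic cells", "MDSC/imMC"
      ),
      thry = "HLA-DR",
      colors = c(NA, "darkgreen", "red", "black")
    ),
    gate_node(
      "Immature myeloid cells", "MDSC/imMC", NA_character_,
      list(gate_clause("SS", "<", "SS.lo_med"))
    ),
    quadrant_nodes(
      "Mature monocytes", "lin2xcd16", "LIN2", "CD16",
      c(
        "Intermediate monocytes", "Classical monocytes",
        "Non-classical monocytes", "LIN2lo CD16- monocytes"
      ),
      thrx = "LIN2.hi",
      colors = c("orange", "blue", "purple", NA)
    ),
    gate_node(
      "CD16+ DC", "Dendritic cells", "cd16dc",
      list(gate_clause("CD16", ">=", "CD16"))
    ),
    gate_node(
      "CD16- DC", "Dendritic cells", "cd16dc",
      list(gate_clause("CD16", "<", "CD16"))
    ),
    quadrant_nodes(
      "CD16- DC", "cd11cxcd123", "CD11c", "CD123",
      c(
        "CD11c+CD123+ DC", "Myeloid DC", "Plasmacytoid DC",
        "CD11c-CD123- DC"
      )
    ),
    granulocyte_leaves()
  )
  new_gating_tree("Myeloid", nodes)
}

#' The Monocytes-1/-2 gating trees
#'
#' CD14+ monocytes are gated from CD45+ mononuclear cells, then resolved
#' two ways in parallel: against HLA-DR to capture the HLA-DRlo/neg
#' (suppressive) population, and on CD14xCD16 into classical, intermediate
#' and non-classical subsets. Per-subset summaries of the panel's variable
#' markers (CD86, TNFR2, CD40, ...) are obtained with [population_mfi()].
#'
#' @param variant `"Monocytes-1"` or `"Monocytes-2"`.
#' @return A `gating_tree`.
#' @export
build_monocyte_tree <- function(variant = c("Monocytes-1", "Monocytes-2")) {
  variant <- rlang::arg_match(variant)
  nodes <- bind_rows(
    root_cd45(),
    ss_split(),
    gate_node(
      "CD14+ monocytes", "Mononuclear cells", NA_character_,
      list(gate_clause("CD14", ">=", "CD14"))
    ),
    gate_node(
      "HLA-DRlo/neg monocytes", "CD14+ monocytes", "dr",
      list(gate_clause("HLA-DR", "<", "HLA-DR")),
      color = "darkgreen"
    ),
    gate_node(
      "HLA-DR+ monocytes", "CD14+ monocytes", "dr",
      list(gate_clause("HLA-DR", ">=", "HLA-DR"))
    ),
    quadrant_nodes(
      "CD14+ monocytes", "cd14xcd16", "CD14", "CD16",
      c(
        "Intermediate monocytes", "Classical monocytes",
        "Non-classical monocytes", "CD14lo CD16- monocytes"
      ),
      thrx = "CD14.hi",
      colors = c("black", "red", "blue", NA)
    )
  )
  new_gating_tree(variant, nodes)
}

# Cutpoints the encoded trees need beyond auto_thresholds(): the CD14 (or
# LIN2) bright/dim boundary, placed by valley detection within the gated
# CD14+ (LIN2+ CD33+) monocytes.
tree_extra_thresholds <- function(events, tree, thresholds, cofactor = 150) {
  need <- unlist(lapply(tree$nodes$clauses, function(cls) {
    vapply(cls, function(cl) cl$thr, character(1))
  }))
  out <- thresholds
  if ("CD14.hi" %in% need && !"CD14.hi" %in% names(out)) {
    cd14 <- marker_values(events, "CD14")
    keep <- marker_values(events, "CD45") >= out[["CD45"]] &
      marker_values(events, "SS") < out[["SS.med_hi"]] &
      cd14 >= out[["CD14"]]
    out[["CD14.hi"]] <- place_threshold(
      subset_events(events, keep), "CD14", "valley", cofactor = cofactor
    )
  }
  if ("LIN2.hi" %in% need && !"LIN2.hi" %in% names(out)) {
    keep <- marker_values(events, "CD45") >= out[["CD45"]] &
      marker_values(events, "SS") < out[["SS.med_hi"]] &
      marker_values(events, "CD33") >= out[["CD33"]] &
      marker_values(events, "LIN2") >= out[["LIN2"]]
    out[["LIN2.hi"]] <- place_threshold(
      subset_events(events, keep), "LIN2", "valley", cofactor = cofactor
    )
  }
  out
}

#' Gate a tube with a tree and automatic thresholds
#'
#' Convenience pipeline: builds the automatic threshold map
#' ([auto_thresholds()]) plus any tree-specific cutpoints, removes counting
#' beads first when `beads` is given (they are bright on every channel and
#' would otherwise land in the leukocyte gates), and applies the tree.
#'
#' @param tube A list with `events` (and optionally `truth`) as returned by
#'   [simulate_tube()], or an [event_table()].
#' @param tree A `gating_tree`.
#' @param fmo Named list of FMO tubes passed to [auto_thresholds()].
#' @param beads A `bead_gate` from [gate_beads()], or `TRUE` to gate beads
#'   here.
#' @param thresholds Optional pre-computed threshold map (a saved template);
#'   missing tree-specific cutpoints are still derived.
#' @return A `gating_result`.
#' @export
gate_tube <- function(tube, tree, fmo = list(), beads = NULL,
                      thresholds = NULL) {
  events <- if (inherits(tube, "event_tbl")) tube else tube$events
  fmo <- lapply(fmo, function(t) {
    if (inherits(t, "event_tbl")) t else t$events
  })
  exclude <- NULL
  if (isTRUE(beads)) beads <- gate_beads(events)
  if (inherits(beads, "bead_gate")) exclude <- beads$index
  # thresholds are placed on the cells: beads are bright on every channel
  # and would distort the density estimates
  cells <- if (is.null(exclude)) events else subset_events(events, !exclude)
  if (is.null(thresholds)) {
    thresholds <- auto_thresholds(
      cells,
      fmo = fmo, valley_markers = tree$valley_markers %||% character()
    )
  }
  thresholds <- tree_extra_thresholds(cells, tree, thresholds)
  apply_tree(events, tree, thresholds, exclude = exclude)
}
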