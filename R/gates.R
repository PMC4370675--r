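# Gate evaluation. A gating tree is a set of named nodes with parent links;
# each node restricts its parent by one or two half-open interval clauses
# on marker channels. The half-open convention [lo, hi) makes quadrant
# partitions exact: an event exactly at a threshold belongs to the positive
# side, and sibling nodes drawn from one quadrant or histogram split are
# mutually exclusive and exhaustive over their parent.

gate_clause <- function(marker, op, thr) {
  stopifnot(op %in% c(">=", "<"))
  list(marker = marker, op = op, thr = thr)
}

gate_node <- function(name, parent = NA_character_, group = NA_character_,
                      clauses = list(), color = NA_character_) {
  tibble(
    name = name, parent = parent, group = group,
    clauses = list(clauses), color = color
  )
}

# The four exhaustive quadrant children of `parent` over markers mx x my,
# in ++, +-, -+, -- order of (mx, my).
quadrant_nodes <- function(parent, group, mx, my, names4,
                           thrx = mx, thry = my, colors = rep(NA, 4)) {
  bind_rows(
    gate_node(names4[1], parent, group, list(
      gate_clause(mx, ">=", thrx), gate_clause(my, ">=", thry)
    ), colors[1]),
    gate_node(names4[2], parent, group, list(
      gate_clause(mx, ">=", thrx), gate_clause(my, "<", thry)
    ), colors[2]),
    gate_node(names4[3], parent, group, list(
      gate_clause(mx, "<", thrx), gate_clause(my, ">=", thry)
    ), colors[3]),
    gate_node(names4[4], parent, group, list(
      gate_clause(mx, "<", thrx), gate_clause(my, "<", thry)
    ), colors[4])
  )
}

new_gating_tree <- function(name, nodes, valley_markers = character()) {
  tree <- structure(
    list(name = name, nodes = nodes, valley_markers = valley_markers),
    class = "gating_tree"
  )
  validate_tree(tree)
  tree
}

#' Validate a gating tree
#'
#' Checks node-name uniqueness, a single root, and acyclicity (every node
#' reaches the root through parent links).
#'
#' @param tree A `gating_tree`.
#' @return The tree, invisibly; errors describe any violation.
#' @export
validate_tree <- function(tree) {
  nodes <- tree$nodes
  if (anyDuplicated(nodes$name)) abort("Duplicate node names in tree.")
  roots <- nodes$name[is.na(nodes$parent)]
  if (length(roots) != 1) abort("Tree must have exactly one root.")
  bad <- setdiff(nodes$parent[!is.na(nodes$parent)], nodes$name)
  if (length(bad) > 0) {
    abort(paste("Unknown parent node(s):", paste(bad, collapse = ", ")))
  }
  order <- topological_order(nodes)
  if (length(order) != nrow(nodes)) abort("Tree contains a cycle.")
  invisible(tree)
}

topological_order <- function(nodes) {
  placed <- character(0)
  remaining <- nodes$name
  repeat {
    ready <- remaining[is.na(nodes$parent[match(remaining, nodes$name)]) |
      nodes$parent[match(remaining, nodes$name)] %in% placed]
    if (length(ready) == 0) {
      return(placed)
    }
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
    if (length(remaining) == 0) {
      return(placed)
    }
  }
}

#' @export
print.gating_tree <- function(x, ...) {
  cat(sprintf(
    "<gating_tree> %s: %d named populations\n", x$name, nrow(x$nodes)
  ))
  print_branch <- function(parent, depth) {
    kids <- x$nodes$name[!is.na(x$nodes$parent) & x$nodes$parent == parent]
    for (k in kids) {
      cat(strrep("  ", depth), k, "\n", sep = "")
      print_branch(k, depth + 1)
    }
  }
  root <- x$nodes$name[is.na(x$nodes$parent)]
  cat(root, "\n")
  print_branch(root, 1)
  invisible(x)
}

#' Named populations of a tree
#' @param tree A `gating_tree`.
#' @return Character vector of all node names (parents and leaves).
#' @export
tree_populations <- function(tree) tree$nodes$name

#' Apply a gating tree to a tube
#'
#' Assigns every event along the hierarchy and reports per-population event
#' counts and percentages of the parent and grandparent populations. A
#' saved tree plus threshold map applied to the same tube twice is
#' bit-identical; applied to another tube it differs only through the data.
#'
#' @param events An [event_table()].
#' @param tree A `gating_tree` (see [build_tbnk_tree()] and friends).
#' @param thresholds Named numeric map of thresholds, e.g. from
#'   [auto_thresholds()] (plus any tree-specific cutpoints such as
#'   `CD14.hi`).
#' @param exclude Optional logical vector of events to drop before gating
#'   (used to remove counting beads from lyse/no-wash tubes).
#' @return A `gating_result`; see [tidy.gating_result()],
#'   [gate_membership()], [glance.gating_result()].
#' @export
apply_tree <- function(events, tree, thresholds, exclude = NULL) {
  validate_tree(tree)
  nodes <- tree$nodes
  n <- n_events(events)
  base <- rep(TRUE, n)
  if (!is.null(exclude)) {
    stopifnot(length(exclude) == n)
    base <- !exclude
  }
  membership <- list()
  for (nm in topological_order(nodes)) {
    row <- nodes[nodes$name == nm, ]
    m <- if (is.na(row$parent)) base else membership[[row$parent]]
    for (clause in row$clauses[[1]]) {
      thr <- if (clause$thr %in% names(thresholds)) {
        thresholds[[clause$thr]]
      }
      if (is.null(thr) || is.na(thr)) {
        abort(sprintf(
          "Missing threshold '%s' for node '%s'.", clause$thr, nm
        ))
      }
      v <- marker_values(events, clause$marker)
      m <- m & if (clause$op == ">=") v >= thr else v < thr
    }
    membership[[nm]] <- m
  }
  counts <- vapply(membership, sum, integer(1))
  pct <- function(child, anc) {
    if (is.na(anc)) {
      return(NA_real_)
    }
    if (counts[[anc]] == 0) {
      return(0)
    }
    100 * counts[[child]] / counts[[anc]]
  }
  grandparent <- nodes$parent[match(nodes$parent, nodes$name)]
  populations <- tibble(
    population = nodes$name,
    parent = nodes$parent,
    group = nodes$group,
    n_events = as.integer(counts[nodes$name]),
    pct_of_parent = purrr::map2_dbl(nodes$name, nodes$parent, pct),
    pct_of_grandparent = purrr::map2_dbl(nodes$name, grandparent, pct)
  )
  structure(
    list(
      populations = populations,
      membership = membership,
      tree = tree,
      thresholds = thresholds,
      n_total = n,
      n_gated = sum(base)
    ),
    class = "gating_result"
  )
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf(
    "<gating_result> %s: %d events, %d populations\n",
    x$tree$name, x$n_total, nrow(x$populations)
  ))
  print(tidy(x), n = nrow(x$populations))
  invisible(x)
}

#' Tidy a gating result
#'
#' @param x A `gating_result`.
#' @param ... Unused.
#' @return A tibble with one row per population: `population`, `parent`,
#'   `n_events`, `pct_of_parent`, `pct_of_grandparent`, and `cells_per_ul`
#'   when absolute counts have been attached.
#' @exportS3Method generics::tidy
tidy.gating_result <- function(x, ...) {
  dplyr::select(x$populations, -"group")
}

#' One-row summary of a gating result
#' @param x A `gating_result`.
#' @param ... Unused.
#' @return A tibble with total events, gated (root) events and population
#'   count.
#' @exportS3Method generics::glance
glance.gating_result <- function(x, ...) {
  root <- x$tree$nodes$name[is.na(x$tree$nodes$parent)]
  tibble(
    n_events = x$n_total,
    n_root = x$populations$n_events[x$populations$population == root],
    n_populations = nrow(x$populations)
  )
}

#' Event membership of one gated population
#'
#' @param result A `gating_result`.
#' @param population Node name.
#' @return Logical vector over the tube's events.
#' @export
gate_membership <- function(result, population) {
  m <- result$membership[[population]]
  if (is.null(m)) abort(sprintf("No population '%s' in result.", population))
  m
}

#' Bar chart of gated population sizes
#'
#' @param object A `gating_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gating_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$population, .data$n_events),
    y = .data$n_events
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Events", title = object$tree$name) +
    ggplot2::theme_minimal()
}
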