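# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) assign(name, force(expr), envir = .fx)
  .fx[[name]]
}

blood_profile <- function() fixture("prof", default_profile("healthy_blood"))

tbnk_tube <- function() {
  fixture("tbnk_tube", simulate_tube(
    blood_profile(), "TBNK/M/G",
    n_events = 30000, seed = 11, bead_conc_per_ul = 1000
  ))
}

tbnk_beads <- function() fixture("tbnk_beads", gate_beads(tbnk_tube()$events))

tbnk_result <- function() {
  fixture(
    "tbnk_result",
    gate_tube(tbnk_tube(), build_tbnk_tree(), beads = tbnk_beads())
  )
}

myeloid_tube <- function() {
  fixture("my_tube", simulate_tube(
    blood_profile(), "Myeloid",
    n_events = 30000, seed = 21
  ))
}

myeloid_fmo <- function() {
  fixture("my_fmo", list(
    CD123 = simulate_fmo(
      blood_profile(), "Myeloid", "CD123",
      n_events = 30000, seed = 521
    ),
    CD15 = simulate_fmo(
      blood_profile(), "Myeloid", "CD15",
      n_events = 30000, seed = 522
    )
  ))
}

myeloid_result <- function() {
  fixture(
    "my_result",
    gate_tube(myeloid_tube(), build_myeloid_tree(), fmo = myeloid_fmo())
  )
}

# A minimal event table carrying given values on one marker's channel.
toy_events <- function(x, marker = "CD14", panel = "TBNK/M/G") {
  p <- load_panel(panel)
  n <- length(x)
  values <- as.data.frame(matrix(0, n, nrow(p$channels)))
  names(values) <- p$channels$channel_id
  values$TIME <- seq_len(n)
  ch <- p$channels$channel_id[p$channels$marker == marker][1]
  values[[ch]] <- x
  event_table(values, p)
}

# F1 score of a gated population against simulator truth. The truth side is
# the union of simulator populations that satisfy the leaf's marker
# definition: on TBNK, dendritic cells, immature myeloid cells and
# basophils are CD14-CD3-CD19-CD16-CD56- by construction, so they belong
# to the lineage-negative phenotype; HLA-DRlo/neg monocytes are CD14+CD16-
# (TBNK carries no HLA-DR); CD16+ DC fall in the CD16+CD56- phenotype.
tbnk_leaf_truth <- list(
  "CD4+ T cells" = "CD4+ T cells",
  "CD8+ T cells" = "CD8+ T cells",
  "CD4+CD8+ T cells" = "CD4+CD8+ T cells",
  "CD4-CD8- T cells" = c("CD4-CD8- T cells", "gamma-delta T cells"),
  "gamma-delta T cells" = "gamma-delta T cells",
  "B cells" = "B cells",
  "CD56+CD16+ NK cells" = "CD56+CD16+ NK cells",
  "CD56+CD16- NK cells" = "CD56+CD16- NK cells",
  "CD16+CD56- cells" = c("CD16+CD56- cells", "CD16+ DC"),
  "Lineage-negative lymphocytes" = c(
    "Lineage-negative lymphocytes", "Myeloid DC", "Plasmacytoid DC",
    "Immature myeloid cells", "Basophils"
  ),
  "Classical monocytes" = c(
    "Classical monocytes", "HLA-DRlo/neg monocytes"
  ),
  "Intermediate monocytes" = "Intermediate monocytes",
  "Non-classical monocytes" = "Non-classical monocytes",
  "Neutrophils" = "Neutrophils",
  "Eosinophils" = "Eosinophils"
)

gate_f1 <- function(result, truth_labels, population, truth_populations) {
  pred <- gate_membership(result, population)
  tr <- truth_labels %in% truth_populations
  2 * sum(pred & tr) / (sum(pred) + sum(tr))
}

# Leaf populations at or above an abundance floor (fraction of CD45+).
tbnk_leaves_at_least <- function(min_abundance = 0.005) {
  ab <- blood_profile()$templates
  keep <- vapply(tbnk_leaf_truth, function(tp) {
    sum(ab$abundance[ab$population %in% tp]) >= min_abundance
  }, logical(1))
  names(tbnk_leaf_truth)[keep]
}

# The nine canonical region profiles, one per catalog row, written out
# from the published level grid.
canonical_profiles <- list(
  CM1 = region_profile("med",
    CD33 = "R2", CD11b = "R2", CD11c = "R2", CD14 = "R2", CD16 = "N",
    `HLA-DR` = "R2", CD15 = "N", CD66b = "N", CD123 = "N"
  ),
  CM2 = region_profile("med",
    CD33 = "R2", CD11b = "R2", CD11c = "R2", CD14 = "R2", CD16 = "R1",
    `HLA-DR` = "R2", CD15 = "N", CD66b = "N", CD123 = "N"
  ),
  CM3 = region_profile("med",
    CD33 = "R2", CD11b = "R2", CD11c = "R2", CD14 = "R1", CD16 = "R1",
    `HLA-DR` = "R2", CD15 = "N", CD66b = "N", CD123 = "N"
  ),
  CM4 = region_profile("med",
    CD33 = "R2", CD11b = "R2", CD11c = "R2", CD14 = "R2", CD16 = "N",
    `HLA-DR` = "R1", CD15 = "N", CD66b = "N", CD123 = "N"
  ),
  CM5 = region_profile("lo",
    CD33 = "R2", CD11b = "N", CD11c = "R2", CD14 = "N", CD16 = "N",
    `HLA-DR` = "R2", CD15 = "N", CD66b = "N", CD123 = "N"
  ),
  CM6 = region_profile("lo",
    CD33 = "R1", CD11b = "N", CD11c = "R2", CD14 = "N", CD16 = "R1",
    `HLA-DR` = "R2", CD15 = "N", CD66b = "N", CD123 = "N"
  ),
  CM7 = region_profile("lo",
    CD33 = "R1", CD11b = "R2", CD11c = "R1", CD14 = "N", CD16 = "N",
    `HLA-DR` = "N", CD15 = "N", CD66b = "N", CD123 = "R1"
  ),
  CM8 = region_profile("hi",
    CD33 = "R1", CD11b = "R2", CD11c = "R1", CD14 = "N", CD16 = "R1",
    `HLA-DR` = "N", CD15 = "R1", CD66b = "R1", CD123 = "N"
  ),
  CM9 = region_profile("hi",
    CD33 = "R1", CD11b = "R2", CD11c = "R1", CD14 = "N", CD16 = "N",
    `HLA-DR` = "N", CD15 = "R1", CD66b = "R1", CD123 = "N"
  )
)

# Per-donor CD123 recovery on the Myeloid protocol: percent CD123+ within
# the SS-low LIN2- CD33+ HLA-DR- gate (threshold from a matched CD123 FMO
# tube), the imMC/monocyte geometric-MFI fold, and percent CD15+CD123+.
myeloid_recovery <- function(tube_seed, fmo_seed_base, n_events = 50000) {
  prof <- blood_profile()
  tube <- simulate_tube(prof, "Myeloid", n_events = n_events, seed = tube_seed)
  fmo <- list(
    CD123 = simulate_fmo(prof, "Myeloid", "CD123",
      n_events = n_events, seed = fmo_seed_base + 1
    ),
    CD15 = simulate_fmo(prof, "Myeloid", "CD15",
      n_events = n_events, seed = fmo_seed_base + 2
    )
  )
  res <- gate_tube(tube, build_myeloid_tree(), fmo = fmo)
  imm <- gate_membership(res, "Immature myeloid cells")
  mono <- gate_membership(res, "Mature monocytes")
  cd123 <- marker_values(tube$events, "CD123")
  cd15 <- marker_values(tube$events, "CD15")
  thr123 <- res$thresholds[["CD123"]]
  thr15 <- res$thresholds[["CD15"]]
  tibble::tibble(
    pct_cd123 = 100 * mean(cd123[imm] >= thr123),
    fold = geometric_mfi(tube$events, imm, "CD123")$geo_mfi /
      geometric_mfi(tube$events, mono, "CD123")$geo_mfi,
    pct_cd15_cd123 = 100 * mean(cd123[imm] >= thr123 & cd15[imm] >= thr15)
  )
}
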