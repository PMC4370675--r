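test_that("CD33 resolves into N, R1 and R2 with monocytes brightest", {
  tube <- myeloid_tube()
  r <- derive_marker_regions(tube$events, "CD33")
  expect_equal(r$label, c("N", "R1", "R2"))
  # disjoint, ordered, covering [0, Inf)
  expect_equal(r$lo[1], 0)
  expect_equal(r$hi[nrow(r)], Inf)
  expect_equal(r$lo[-1], r$hi[-nrow(r)])
  lab <- assign_regions(tube$events, r)
  truth <- tube$truth$label
  modal <- function(pop) names(which.max(table(lab[truth == pop])))
  expect_equal(modal("Classical monocytes"), "R2")
  expect_equal(modal("Neutrophils"), "R1")
  expect_equal(modal("CD4+ T cells"), "N")
  # every event falls in exactly one region
  expect_false(anyNA(lab))
  expect_equal(length(lab), n_events(tube$events))
})

test_that("region boundaries match a brute-force density-minimum scan", {
  tube <- myeloid_tube()
  r <- derive_marker_regions(tube$events, "CD33")
  y <- asinh(marker_values(tube$events, "CD33") / 150)
  d <- stats::density(y, n = 512)
  step <- diff(d$x[1:2])
  for (cut in r$hi[is.finite(r$hi)]) {
    # oracle: argmin of the density in a window around the cut
    sel <- abs(d$x - asinh(cut / 150)) < 0.5
    oracle <- d$x[sel][which.min(d$y[sel])]
    expect_lt(abs(asinh(cut / 150) - oracle), 1.5 * step)
  }
})

test_that("a single positive mode yields N and R1 only", {
  tube <- tbnk_tube()
  cells <- subset_events(tube$events, !tbnk_beads()$index)
  r <- derive_marker_regions(cells, "CD19")
  expect_equal(r$label, c("N", "R1"))
})

test_that("back-gating places regions in their scatter compartments", {
  tube <- myeloid_tube()
  thr <- myeloid_result()$thresholds
  cuts <- c(lo_med = thr[["SS.lo_med"]], med_hi = thr[["SS.med_hi"]])
  # CD15 bright cells (R2) are granulocytes: SS-high
  r15 <- derive_marker_regions(tube$events, "CD15")
  lab15 <- assign_regions(tube$events, r15)
  top15 <- tail(r15$label, 1)
  bg <- backgate_scatter(tube$events, lab15 == top15, cuts)
  expect_equal(bg$ss_class, "SS_hi")
  # CD123+ cells are neither granulocytes nor typical lymphocytes (the
  # CD123+ compartment is well under 1% of events, so the peak floor is
  # lowered accordingly)
  r123 <- derive_marker_regions(tube$events, "CD123", min_peak_frac = 0.001)
  lab123 <- assign_regions(tube$events, r123)
  bg123 <- backgate_scatter(tube$events, lab123 != "N", cuts)
  expect_false(identical(bg123$ss_class, "SS_hi"))
  lymph <- backgate_scatter(
    tube$events, tube$truth$label == "CD4+ T cells", cuts
  )
  expect_gt(bg123$ss_centroid, lymph$ss_centroid)
  # empty gate gives an empty summary
  empty <- backgate_scatter(tube$events, rep(FALSE, n_events(tube$events)))
  expect_equal(nrow(empty), 0)
})

test_that("a gated imMC population profiles as CM7", {
  tube <- myeloid_tube()
  res <- myeloid_result()
  # build the profile from the gate's modal regions
  imm <- gate_membership(res, "Immature myeloid cells")
  sub <- subset_events(tube$events, imm)
  modal <- function(m) {
    r <- derive_marker_regions(tube$events, m, min_peak_frac = 0.001)
    names(which.max(table(assign_regions(sub, r))))
  }
  prof <- region_profile("lo",
    CD33 = modal("CD33"), CD123 = modal("CD123"), CD15 = modal("CD15"),
    `HLA-DR` = "N", CD14 = "N", CD16 = "N", CD66b = modal("CD66b")
  )
  expect_equal(classify_myeloid(prof)$code, "CM7")
})
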