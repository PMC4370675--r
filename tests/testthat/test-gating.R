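test_that("the encoded trees have the published structure", {
  tbnk <- build_tbnk_tree()
  expect_gte(enumerate_phenotypes(tbnk), 20)
  expect_silent(validate_tree(tbnk))
  # eosinophils are CD15+CD16- within high side scatter
  eos <- tbnk$nodes[tbnk$nodes$name == "Eosinophils", ]
  expect_equal(eos$parent, "Granulocytes")
  cls <- eos$clauses[[1]]
  expect_equal(
    vapply(cls, function(cl) paste(cl$marker, cl$op), character(1)),
    c("CD15 >=", "CD16 <")
  )

  my <- build_myeloid_tree()
  expect_true("MDSC/imMC" %in% tree_populations(my))
  mdsc <- my$nodes[my$nodes$name == "MDSC/imMC", ]$clauses[[1]]
  expect_equal(
    vapply(mdsc, function(cl) paste(cl$marker, cl$op), character(1)),
    c("LIN2 <", "HLA-DR <")
  )
  dc <- my$nodes[my$nodes$name == "Dendritic cells", ]$clauses[[1]]
  expect_equal(
    vapply(dc, function(cl) paste(cl$marker, cl$op), character(1)),
    c("LIN2 <", "HLA-DR >=")
  )

  m1 <- build_monocyte_tree("Monocytes-1")
  expect_true(all(c(
    "Classical monocytes", "Intermediate monocytes",
    "Non-classical monocytes", "HLA-DRlo/neg monocytes"
  ) %in% tree_populations(m1)))
  expect_error(build_monocyte_tree("Monocytes-3"))
})

test_that("an empty tube gates to all-zero counts with defined percentages", {
  empty <- toy_events(numeric(0))
  thr <- c(
    CD45 = 1, SS.lo_med = 1, SS.med_hi = 2, CD14 = 1, CD14.hi = 2,
    CD3 = 1, CD19 = 1, CD4 = 1, CD8 = 1, gdTCR = 1, CD16 = 1, CD56 = 1,
    CD15 = 1
  )
  res <- apply_tree(empty, build_tbnk_tree(), thr)
  td <- tidy(res)
  expect_true(all(td$n_events == 0))
  expect_true(all(td$pct_of_parent[-1] == 0))
})

test_that("exclusive partitions conserve their parent exactly", {
  for (res in list(tbnk_result(), myeloid_result())) {
    pops <- res$populations
    groups <- unique(stats::na.omit(pops$group))
    expect_gt(length(groups), 0)
    for (g in groups) {
      kids <- pops[!is.na(pops$group) & pops$group == g, ]
      parent_n <- pops$n_events[pops$population == kids$parent[1]]
      expect_identical(sum(kids$n_events), parent_n)
    }
  }
})

test_that("gate membership equals brute-force interval checks", {
  tube <- tbnk_tube()
  sub <- subset_events(tube$events, seq_len(2000))
  thr <- tbnk_result()$thresholds
  res <- apply_tree(sub, build_tbnk_tree(), thr)
  got <- gate_membership(res, "B cells")
  want <- vapply(seq_len(2000), function(i) {
    sub$FL10[i] >= thr[["CD45"]] && # CD45
      sub$SS[i] < thr[["SS.med_hi"]] && # mononuclear
      sub$FL4[i] < thr[["CD14"]] && # lymphocyte
      sub$FL6[i] >= thr[["CD19"]] && # CD19+
      sub$FL8[i] < thr[["CD3"]] # CD3-
  }, logical(1))
  expect_identical(got, want)
})

test_that("a saved template reapplies deterministically", {
  tube <- tbnk_tube()
  thr <- tbnk_result()$thresholds
  r1 <- apply_tree(tube$events, build_tbnk_tree(), thr,
    exclude = tbnk_beads()$index
  )
  r2 <- apply_tree(tube$events, build_tbnk_tree(), thr,
    exclude = tbnk_beads()$index
  )
  expect_identical(tidy(r1), tidy(r2))
  # the same template on a different tube differs only through the data
  other <- simulate_tube(blood_profile(), "TBNK/M/G",
    n_events = 5000, seed = 99, bead_conc_per_ul = 1000
  )
  r3 <- gate_tube(other, build_tbnk_tree(), beads = TRUE, thresholds = thr)
  expect_false(identical(tidy(r1)$n_events, tidy(r3)$n_events))
  expect_error(
    apply_tree(tube$events, build_tbnk_tree(), thr[-4]),
    "Missing threshold"
  )
})

test_that("gating recovers the simulated populations", {
  res <- tbnk_result()
  truth <- tbnk_tube()$truth$label
  for (leaf in tbnk_leaves_at_least(0.005)) {
    expect_gt(
      gate_f1(res, truth, leaf, tbnk_leaf_truth[[leaf]]), 0.95
    )
  }
  # the imMC gate is essentially pure immature myeloid cells + basophils
  imm <- gate_membership(myeloid_result(), "Immature myeloid cells")
  frac <- mean(
    myeloid_tube()$truth$label[imm] %in%
      c("Immature myeloid cells", "Basophils")
  )
  expect_gte(frac, 0.90)
})

test_that("gating results tidy, glance and plot", {
  res <- tbnk_result()
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("population", "n_events", "pct_of_parent") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_populations, 26)
  expect_lt(gl$n_root, gl$n_events)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
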