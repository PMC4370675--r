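test_that("default profiles encode the expected expression structure", {
  prof <- blood_profile()
  expr <- prof$expression
  geo <- function(pop, m) {
    expr$geo_mean[expr$population == pop & expr$marker == m]
  }
  # CD123: immature myeloid cells 20x monocytes/granulocytes (which are at
  # background), half of plasmacytoid DCs
  bg <- 150
  expect_equal(geo("Immature myeloid cells", "CD123") / bg, 20)
  expect_equal(
    geo("Immature myeloid cells", "CD123") /
      geo("Plasmacytoid DC", "CD123"), 0.5
  )
  expect_length(geo("Classical monocytes", "CD123"), 0) # background
  # abundances sum to one, basophil template present
  expect_equal(sum(prof$templates$abundance), 1, tolerance = 1e-12)
  expect_gt(prof$basophil_fraction, 0)

  # pleural fluid is T-cell dominated; blood is granulocyte dominated
  t_of <- function(p) {
    sum(p$templates$abundance[grepl("T cells$", p$templates$population)])
  }
  g_of <- function(p) {
    sum(p$templates$abundance[
      p$templates$population %in% c("Neutrophils", "Eosinophils")
    ])
  }
  pleural <- default_profile("pleural")
  expect_gt(t_of(pleural), g_of(pleural))
  expect_gt(g_of(prof), t_of(prof))
  expect_error(default_profile("lymph_node"))
})

test_that("identical seeds reproduce bit-identical tubes", {
  prof <- blood_profile()
  a <- simulate_tube(prof, "TBNK/M/G", n_events = 2000, seed = 5,
    bead_conc_per_ul = 1000
  )
  b <- simulate_tube(prof, "TBNK/M/G", n_events = 2000, seed = 5,
    bead_conc_per_ul = 1000
  )
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
  expect_identical(a$truth, b$truth)
  c <- simulate_tube(prof, "TBNK/M/G", n_events = 2000, seed = 6,
    bead_conc_per_ul = 1000
  )
  expect_false(identical(as.data.frame(a$events), as.data.frame(c$events)))
})

test_that("labels are multinomial in the template abundances", {
  tube <- simulate_tube(blood_profile(), "Myeloid",
    n_events = 50000, seed = 1
  )
  # conservation
  expect_equal(sum(table(tube$truth$label)), 50000)
  expect_equal(nrow(tube$truth), n_events(tube$events))
  # neutrophil fraction within 3 binomial SDs of its expectation
  p <- 0.98 * blood_profile()$templates$abundance[
    blood_profile()$templates$population == "Neutrophils"
  ]
  x <- mean(tube$truth$label == "Neutrophils")
  expect_lt(abs(x - p), 3 * sqrt(p * (1 - p) / 50000))
  # time is non-decreasing and the tube validates
  expect_true(validation_passed(validate_events(tube$events, "Myeloid")))
})

test_that("a degenerate single-population profile yields only that label", {
  prof <- blood_profile()
  tpl <- prof$templates[prof$templates$population == "Neutrophils", ]
  tpl$abundance <- 1
  solo <- donor_profile("solo", "blood", 6000, tpl, prof$expression)
  tube <- simulate_tube(solo, "TBNK/M/G", n_events = 100000, seed = 3)
  labs <- unique(tube$truth$label)
  expect_setequal(labs, c("Neutrophils", "debris"))
  # log-normal moments: sample geometric mean within 2% of the template
  cd15 <- marker_values(tube$events, "CD15")[tube$truth$label == "Neutrophils"]
  expect_equal(exp(mean(log(cd15))) / 3e5, 1, tolerance = 0.02)
})

test_that("bead spike-ins appear at their expected concentration", {
  prof <- blood_profile()
  tube <- tbnk_tube() # 30000 events, 1000 beads/ul, WBC 6000/ul
  r <- 0.98 * 1000 / 6000
  expected <- 30000 * r / (1 + r)
  n_beads <- sum(tube$truth$label == "bead")
  expect_lt(abs(n_beads - expected), 4 * sqrt(expected))
  # CV at default settings is far below 5%
  expect_lt(sqrt(expected) / expected, 0.05)
  # beads are uniform in time: mean time near mid-acquisition
  tt <- tube$events$TIME[tube$truth$label == "bead"]
  expect_equal(mean(tt) / max(tube$events$TIME), 0.5, tolerance = 0.05)
  # beads only on the lyse/no-wash panel
  expect_error(
    simulate_tube(prof, "Myeloid", n_events = 100, bead_conc_per_ul = 1000),
    "lyse/no-wash"
  )
})

test_that("FMO tubes carry background on the omitted channel only", {
  prof <- blood_profile()
  stained <- simulate_tube(prof, "Myeloid", n_events = 30000, seed = 77)
  fmo <- simulate_fmo(prof, "Myeloid", "CD123", n_events = 30000, seed = 77)
  # same seed: every other channel bit-identical
  for (ch in setdiff(names(stained$events), "FL2")) {
    expect_identical(stained$events[[ch]], fmo$events[[ch]])
  }
  expect_false(identical(stained$events$FL2, fmo$events$FL2))
  # pDC CD123 indistinguishable from a background population in the FMO
  pdc <- fmo$events$FL2[fmo$truth$label == "Plasmacytoid DC"]
  bgv <- fmo$events$FL2[fmo$truth$label == "CD4+ T cells"][
    seq_len(1000)
  ]
  expect_gt(stats::wilcox.test(pdc, bgv)$p.value, 0.01)
  expect_error(
    simulate_fmo(prof, "Myeloid", "CD19", n_events = 100),
    "not stained"
  )
})
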