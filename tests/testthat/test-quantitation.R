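test_that("the counting formula is exact, linear and scale-invariant", {
  # n_phenotype = n_beads collapses to the lot concentration
  expect_equal(absolute_count(1000, 950, 1000), 950)
  expect_equal(absolute_count(4000, 1000, 2000), 2000)
  expect_equal(anchor_counts(50, 6000), 3000)
  expect_equal(anchor_counts(0, 123456), 0)
  # linear in the phenotype count
  expect_equal(
    absolute_count(c(1, 2, 7) * 100, 1000, 5000),
    c(1, 2, 7) * absolute_count(100, 1000, 5000)
  )
  # invariant under joint scaling of counts
  expect_equal(
    absolute_count(300, 1000, 600), absolute_count(3000, 1000, 6000)
  )
  expect_error(absolute_count(10, 1000, 0), "positive")
})

test_that("bead gating recovers the spiked fluorospheres", {
  tube <- tbnk_tube()
  b <- tbnk_beads()
  truth <- tbnk_tube()$truth$label == "bead"
  # F1 against ground truth
  f1 <- 2 * sum(b$index & truth) / (sum(b$index) + sum(truth))
  expect_gte(f1, 0.99)
  # count within a Poisson-scale interval of its expectation
  r <- 0.98 * 1000 / 6000
  expected <- 30000 * r / (1 + r)
  expect_lt(abs(b$n - expected), 4 * sqrt(expected))
  # a tube without beads has no cluster
  no_beads <- simulate_tube(blood_profile(), "TBNK/M/G",
    n_events = 5000, seed = 2
  )
  expect_error(gate_beads(no_beads$events), "No bead cluster")
})

test_that("end-to-end absolute counts recover the profile concentration", {
  # total CD45+ cells/ul vs the profile's WBC (mean over seeds)
  est <- vapply(1:3, function(sd) {
    tube <- simulate_tube(blood_profile(), "TBNK/M/G",
      n_events = 30000, seed = sd, bead_conc_per_ul = 1000
    )
    b <- gate_beads(tube$events)
    res <- gate_tube(tube, build_tbnk_tree(), beads = b)
    absolute_count(glance(res)$n_root, 1000, b$n)
  }, numeric(1))
  expect_equal(mean(est) / 6000, 1, tolerance = 0.05)
})

test_that("anchoring lyse/wash phenotypes to the counting tube works", {
  prof <- blood_profile()
  est <- vapply(1:3, function(sd) {
    tbnk <- simulate_tube(prof, "TBNK/M/G",
      n_events = 30000, seed = sd, bead_conc_per_ul = 1000
    )
    b <- gate_beads(tbnk$events)
    rt <- gate_tube(tbnk, build_tbnk_tree(), beads = b)
    cd45_per_ul <- absolute_count(glance(rt)$n_root, 1000, b$n)
    my <- simulate_tube(prof, "Myeloid", n_events = 30000, seed = 100 + sd)
    rm <- gate_tube(my, build_myeloid_tree(), fmo = myeloid_fmo())
    td <- tidy(rm)
    pct_cd45 <- 100 * td$n_events[td$population == "Classical monocytes"] /
      td$n_events[td$population == "CD45+ WBC"]
    anchor_counts(pct_cd45, cd45_per_ul)
  }, numeric(1))
  truth <- 6000 * prof$templates$abundance[
    prof$templates$population == "Classical monocytes"
  ]
  expect_equal(mean(est) / truth, 1, tolerance = 0.10)
})

test_that("geometric MFI is the log-scale mean and scale-equivariant", {
  ev <- toy_events(c(10, 1000), marker = "CD14")
  expect_equal(geometric_mfi(ev, NULL, "CD14")$geo_mfi, 100)
  ev2 <- toy_events(rep(7, 5), marker = "CD14")
  expect_equal(geometric_mfi(ev2, NULL, "CD14")$geo_mfi, 7)
  # closed-form log-normal agreement at n = 1e5
  set.seed(31)
  x <- rlnorm(1e5, log(100), 0.7)
  got <- geometric_mfi(toy_events(x, "CD14"), NULL, "CD14")$geo_mfi
  expect_equal(got / 100, 1, tolerance = 0.02)
  # equivariance under intensity scaling
  k <- 3.7
  got_k <- geometric_mfi(toy_events(k * x, "CD14"), NULL, "CD14")$geo_mfi
  expect_equal(got_k, k * got, tolerance = 1e-12)
  # empty gate
  out <- geometric_mfi(ev, rep(FALSE, 2), "CD14")
  expect_equal(out$n, 0)
  expect_true(is.na(out$geo_mfi))
})

test_that("rank correlation matches its definition", {
  expect_equal(rank_correlation(1:10, (1:10)^3)$rho, 1)
  expect_equal(rank_correlation(1:10, -(1:10))$rho, -1)
  expect_error(rank_correlation(1:4, 1:5), "equal length")
  # synthetic cohort with built-in negative percent-vs-count dependence
  set.seed(64)
  counts <- rlnorm(64, log(500), 0.5)
  pct <- 100 / (1 + counts / 300) * exp(rnorm(64, 0, 0.2))
  out <- rank_correlation(counts, pct)
  expect_lt(out$rho, 0)
  expect_lt(out$p_value, 0.01)
})

test_that("population MFI summarizes monocyte subsets", {
  tube <- myeloid_tube()
  res <- myeloid_result()
  mfi <- population_mfi(
    res, tube$events,
    c("Classical monocytes", "Non-classical monocytes"), "HLA-DR"
  )
  expect_equal(nrow(mfi), 2)
  expect_true(all(mfi$geo_mfi > 0))
})
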