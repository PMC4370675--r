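# A hand-built two-axis configuration with known anchors, for exact checks.
fixed_config <- function(markers, angles, lo = 1, hi = 2) {
  structure(
    tibble::tibble(
      marker = markers, angle = angles,
      scale_lo = lo, scale_hi = hi
    ),
    cofactor = 150,
    class = c("radar_config", class(tibble::tibble()))
  )
}

test_that("axis configuration enforces the 13-axis limit", {
  tube <- myeloid_tube()
  ms <- panel_markers("Myeloid")
  cfg13 <- configure_axes(tube$events, c(ms, ms[1:3]))
  expect_equal(nrow(cfg13), 13)
  expect_error(
    configure_axes(tube$events, c(ms, ms[1:4])), "13"
  )
  cfg3 <- configure_axes(
    tube$events, c("CD33", "CD123", "HLA-DR"),
    angles = c(90, 210, 330) * pi / 180
  )
  expect_equal(nrow(cfg3), 3)
  expect_error(
    configure_axes(tube$events, c("CD33", "CD123"), angles = c(1, 1)),
    "Duplicate"
  )
  # anchors bracket the data scale
  expect_true(all(cfg3$scale_hi > cfg3$scale_lo))
})

test_that("projection maps negatives to the origin and cancels opposites", {
  # below the lower anchor on every axis: exactly the origin
  cfg <- fixed_config(c("CD4", "CD8"), c(0, pi))
  ev <- toy_events(c(0, 0), marker = "CD4")
  pr <- project(ev, cfg)
  expect_identical(pr$.x, c(0, 0))
  expect_identical(pr$.y, c(0, 0))
  # fully positive on two axes 180 degrees apart: cancels to the origin
  vals <- as.data.frame(toy_events(c(1e6, 1e6), marker = "CD4"))
  vals$FL7 <- c(1e6, 1e6) # CD8 channel on TBNK
  ev2 <- event_table(vals, "TBNK/M/G")
  pr2 <- project(ev2, cfg)
  expect_lt(max(abs(pr2$.x)), 1e-9)
  expect_lt(max(abs(pr2$.y)), 1e-9)
  # s = 1 on a single axis at 0 degrees: the unit vector
  cfg1 <- fixed_config("CD4", 0)
  pr3 <- project(toy_events(1e6, marker = "CD4"), cfg1)
  expect_equal(pr3$.x, 1)
  expect_lt(abs(pr3$.y), 1e-9)
})

test_that("rotation is rigid", {
  tube <- tbnk_tube()
  sub <- subset_events(tube$events, which(!tbnk_beads()$index)[1:100])
  cfg <- radar_preset_tbnk6(sub)
  pr <- project(sub, cfg)
  # full turn: identical projection
  pr_turn <- project(sub, rotate(cfg, 2 * pi))
  expect_equal(pr_turn$.x, pr$.x, tolerance = 1e-9)
  # quarter turn rotates coordinates by the rotation matrix
  pr_q <- project(sub, rotate(cfg, pi / 2))
  expect_equal(pr_q$.x, -pr$.y, tolerance = 1e-9)
  expect_equal(pr_q$.y, pr$.x, tolerance = 1e-9)
  # pairwise distances invariant for an arbitrary angle
  for (delta in c(0.3, 1.7, 4.4)) {
    pr_d <- project(sub, rotate(cfg, delta))
    d0 <- stats::dist(cbind(pr$.x, pr$.y))
    d1 <- stats::dist(cbind(pr_d$.x, pr_d$.y))
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
})

test_that("projection is monotone along each axis", {
  cfg <- fixed_config(c("CD4", "CD8"), c(0, pi / 2), lo = 1, hi = 8)
  x <- 150 * sinh(seq(1, 8, length.out = 20)) # spans the axis scale
  pr <- project(toy_events(x, marker = "CD4"), cfg)
  expect_true(all(diff(pr$.x) > 0))
  expect_true(all(pr$.y == 0))
})

test_that("the six-axis preset separates the main blood populations", {
  tube <- tbnk_tube()
  cells <- subset_events(tube$events, !tbnk_beads()$index)
  labels <- tbnk_tube()$truth$label[!tbnk_beads()$index]
  cfg <- radar_preset_tbnk6(cells)
  pr <- project(cells, cfg, labels = labels)
  grp <- list(
    T = c("CD4+ T cells", "CD8+ T cells"),
    B = "B cells",
    NK = c("CD56+CD16+ NK cells", "CD56+CD16- NK cells"),
    Mono = c("Classical monocytes", "Intermediate monocytes")
  )
  cent <- lapply(grp, function(g) {
    sel <- pr$population %in% g
    c(mean(pr$.x[sel]), mean(pr$.y[sel]))
  })
  disp <- mean(vapply(grp, function(g) {
    sel <- pr$population %in% g
    mean(sqrt(
      (pr$.x[sel] - mean(pr$.x[sel]))^2 + (pr$.y[sel] - mean(pr$.y[sel]))^2
    ))
  }, numeric(1)))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      d <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      expect_gt(d, disp)
    }
  }
  p <- ggplot2::autoplot(pr)
  expect_s3_class(p, "ggplot")
})
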