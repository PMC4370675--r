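# Synthetic cytometer: draws labeled tubes with the statistical structure
# the gating method assumes. One master seed per tube; every source of
# randomness (labels, time, scatter, each fluorescence channel) runs on its
# own substream derived from the master seed, in fixed order, so a tube is
# bit-reproducible and an FMO variant changes only the omitted channel.

# Fluorospheres are engineered to be far brighter than any stained cell on
# every channel, and very tight.
BEAD_GEO <- 5e6
BEAD_CV <- 0.05
LIN2_COMPONENTS <- c("CD3", "CD14", "CD19", "CD56")

#' Simulate a stained tube
#'
#' Draws `n_events` events from a donor profile stained with a panel.
#' Population counts are multinomial in the template abundances (after
#' reserving a debris fraction and, for lyse/no-wash tubes, counting beads).
#' Stained-marker intensities are log-normal per population; unstained
#' markers follow the shared background model. The composite `LIN2` cocktail
#' channel (CD3/CD14/CD19/CD56) reports the maximum of its component stain
#' intensities. Counting beads, when requested, form a tight cluster bright
#' on every fluorescence channel, interleaved uniformly in acquisition time,
#' with expected count `n_cells * bead_conc_per_ul / wbc_per_ul`.
#'
#' @param profile A [donor_profile()].
#' @param panel A `panel_definition` or panel name.
#' @param n_events Total number of events to draw (> 0).
#' @param seed Integer master seed; identical seeds give bit-identical
#'   tubes.
#' @param bead_conc_per_ul Counting-bead concentration (fluorospheres/ul of
#'   prepared sample), only valid for lyse/no-wash panels. `NULL` for no
#'   beads.
#' @param fmo_omit Marker to leave unstained (fluorescence-minus-one
#'   control), or `NULL`.
#' @param debris_frac Fraction of non-bead events that are CD45-negative
#'   debris with low scatter.
#' @param acquisition_s Nominal acquisition time span (seconds) for the
#'   uniform TIME channel.
#' @return A list with `events` (an [event_table()]) and `truth` (a tibble
#'   with one `label` per event, including `"bead"` and `"debris"`).
#' @examples
#' tube <- simulate_tube(default_profile("healthy_blood"), "Myeloid",
#'   n_events = 1000, seed = 1
#' )
#' table(tube$truth$label)[1:3]
#' @export
simulate_tube <- function(profile, panel, n_events = 50000, seed = 1,
                          bead_conc_per_ul = NULL, fmo_omit = NULL,
                          debris_frac = 0.02, acquisition_s = 100) {
  stopifnot(inherits(profile, "donor_profile"), n_events > 0)
  panel <- as_panel(panel)
  if (!is.null(bead_conc_per_ul) && panel$wash_mode != "lyse_no_wash") {
    abort("Counting beads are only added to lyse/no-wash tubes.")
  }
  if (!is.null(fmo_omit) && !fmo_omit %in% panel_markers(panel)) {
    abort(sprintf(
      "FMO marker '%s' is not stained on panel %s.", fmo_omit, panel$name
    ))
  }
  n <- as.integer(n_events)
  tpl <- profile$templates

  # Bead share: solves E[beads] = E[leukocytes] * conc / wbc given that a
  # debris_frac share of non-bead events is debris.
  r <- if (is.null(bead_conc_per_ul)) 0 else
    bead_conc_per_ul / profile$wbc_per_ul
  p_bead <- (1 - debris_frac) * r / (1 + (1 - debris_frac) * r)

  classes <- c("bead", "debris", tpl$population)
  prob <- c(p_bead, (1 - p_bead) * debris_frac,
            (1 - p_bead) * (1 - debris_frac) * tpl$abundance)
  label <- with_seed(
    stream_seed(seed, 1L),
    sample(classes, n, replace = TRUE, prob = prob)
  )

  tt <- with_seed(stream_seed(seed, 2L), sort(runif(n, 0, acquisition_s)))

  sc <- tibble(
    population = c("bead", "debris", tpl$population),
    fs_mu = c(250, 80, tpl$fs_mu), fs_sigma = c(8, 25, tpl$fs_sigma),
    ss_mu = c(150, 60, tpl$ss_mu), ss_sigma = c(8, 20, tpl$ss_sigma)
  )
  idx <- match(label, sc$population)
  fs <- with_seed(
    stream_seed(seed, 3L),
    pmax(rnorm(n, sc$fs_mu[idx], sc$fs_sigma[idx]), 0)
  )
  ss <- with_seed(
    stream_seed(seed, 4L),
    pmax(rnorm(n, sc$ss_mu[idx], sc$ss_sigma[idx]), 0)
  )

  expr <- profile$expression
  if (!is.null(fmo_omit)) {
    omit <- if (fmo_omit == "LIN2") LIN2_COMPONENTS else fmo_omit
    # an FMO tube simply leaves the antibody out: cells revert to
    # background on that channel; beads are intrinsically fluorescent
    expr <- dplyr::filter(expr, !.data$marker %in% omit)
  }

  draw_marker <- function(m) {
    # per-event log-normal parameters: background unless (population,
    # marker) has a stained level; beads bright and tight on every channel
    meanlog <- rep(log(BG_GEO), n)
    sdlog <- rep(geo_cv_to_sdlog(BG_CV), n)
    rows <- expr[expr$marker == m, ]
    if (nrow(rows) > 0) {
      j <- match(label, rows$population)
      hit <- !is.na(j)
      meanlog[hit] <- log(rows$geo_mean[j[hit]])
      sdlog[hit] <- geo_cv_to_sdlog(rows$geo_cv[j[hit]])
    }
    beads <- label == "bead"
    meanlog[beads] <- log(BEAD_GEO)
    sdlog[beads] <- geo_cv_to_sdlog(BEAD_CV)
    rlnorm(n, meanlog, sdlog)
  }

  fl <- lapply(seq_along(fl_channels()), function(jc) {
    ch <- fl_channels()[jc]
    m <- panel$channels$marker[panel$channels$channel_id == ch]
    with_seed(stream_seed(seed, 10L + jc), {
      if (m == "LIN2" && !(!is.null(fmo_omit) && fmo_omit == "LIN2")) {
        do.call(pmax, lapply(LIN2_COMPONENTS, draw_marker))
      } else if (m == "LIN2") {
        draw_marker("LIN2") # omitted cocktail: background for all cells
      } else if (m == "unstained") {
        draw_marker("unstained")
      } else {
        draw_marker(m)
      }
    })
  })
  names(fl) <- fl_channels()

  values <- tibble(FS = fs, SS = ss, TIME = tt, !!!fl)
  list(
    events = new_event_tbl(values, panel),
    truth = tibble(label = label),
    panel = panel$name,
    profile = profile$name,
    seed = seed,
    bead_conc_per_ul = bead_conc_per_ul
  )
}

#' Simulate a fluorescence-minus-one control tube
#'
#' Identical to [simulate_tube()] except that the omitted marker's channel
#' carries the background-only distribution for every cell population. At a
#' matched seed, all other channels are bit-identical to the stained tube.
#'
#' @inheritParams simulate_tube
#' @param omit Marker left unstained.
#' @param ... Passed to [simulate_tube()].
#' @export
simulate_fmo <- function(profile, panel, omit, ...) {
  simulate_tube(profile, panel, fmo_omit = omit, ...)
}
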