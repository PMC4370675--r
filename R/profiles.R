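# Donor profiles: the population structure the simulator draws from.
#
# Intensities are in arbitrary units; only ratios and region structure are
# meaningful. Each population carries a bivariate-normal scatter location
# and, per stained marker, a log-normal intensity model (geometric mean,
# geometric CV). Markers without an entry are drawn from the shared
# background (unstained) model, whose geometric mean is 1/50 of the dimmest
# positive peak so FMO thresholds separate cleanly.

# Intensity ladder (arbitrary units, typical digital-cytometer scale; the
# asinh display cofactor of 150 puts the unstained background at the foot
# of the scale with a width comparable to the positive peaks).
BG_GEO <- 150
BG_CV <- 0.75
LVL_LO <- 30 * BG_GEO
LVL_DIM <- 60 * BG_GEO
LVL_MID <- 200 * BG_GEO
LVL_POS <- 600 * BG_GEO
LVL_BRIGHT <- 2000 * BG_GEO
CV_POS <- 0.55

# CD123 structure: immature myeloid cells sit 20-fold above monocytes and
# granulocytes (which are background for CD123) and at half the level of
# plasmacytoid DCs. The geometric CV 0.84 places ~96% of immature myeloid
# cells above a 0.995-quantile FMO threshold of the background model.
CD123_IMMC_GEO <- 20 * BG_GEO
CD123_IMMC_CV <- 0.84
CD123_PDC_GEO <- 2 * CD123_IMMC_GEO

geo_cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Construct a donor profile
#'
#' @param name Profile label.
#' @param tissue One of `"blood"`, `"marrow"`, `"pleural"`.
#' @param wbc_per_ul Leukocyte concentration of the sample (cells/ul).
#' @param templates Tibble with one row per population: `population`,
#'   `abundance` (fraction of CD45+ leukocytes; must sum to 1 within 1e-9),
#'   `fs_mu`, `fs_sigma`, `ss_mu`, `ss_sigma`.
#' @param expression Long tibble of stained-marker levels: `population`,
#'   `marker`, `geo_mean`, `geo_cv`. Omitted (population, marker) pairs use
#'   the background model.
#' @return A `donor_profile` object.
#' @export
donor_profile <- function(name, tissue, wbc_per_ul, templates, expression) {
  stopifnot(wbc_per_ul > 0)
  tot <- sum(templates$abundance)
  if (abs(tot - 1) > 1e-9) {
    abort(sprintf("Population abundances sum to %.12f, not 1.", tot))
  }
  if (any(templates$abundance < 0)) abort("Negative abundance.")
  baso <- templates$abundance[templates$population == "Basophils"]
  structure(
    list(
      name = name,
      tissue = tissue,
      wbc_per_ul = wbc_per_ul,
      basophil_fraction = if (length(baso) == 1) baso else 0,
      templates = templates,
      expression = expression
    ),
    class = "donor_profile"
  )
}

#' @export
print.donor_profile <- function(x, ...) {
  cat(sprintf(
    "<donor_profile> %s (%s), WBC %g/ul, %d populations\n",
    x$name, x$tissue, x$wbc_per_ul, nrow(x$templates)
  ))
  invisible(x)
}

# Scatter placements (arbitrary units). Lymphoid cells sit low on side
# scatter, monocytes intermediate, granulocytes high; DC-like and immature
# populations are placed in the SS-low band per their published scatter
# class.
scatter_defaults <- function(population) {
  lymph <- c(450, 60, 150, 25)
  mono <- c(550, 70, 400, 55)
  gran <- c(700, 90, 1000, 100)
  dcish <- c(500, 60, 180, 30)
  sc <- switch(population,
    "Neutrophils" = gran,
    "Eosinophils" = c(700, 90, 1050, 100),
    "Classical monocytes" = ,
    "Intermediate monocytes" = ,
    "Non-classical monocytes" = ,
    "HLA-DRlo/neg monocytes" = mono,
    "Myeloid DC" = ,
    "CD16+ DC" = ,
    "Plasmacytoid DC" = ,
    "Immature myeloid cells" = ,
    "Basophils" = dcish,
    lymph
  )
  names(sc) <- c("fs_mu", "fs_sigma", "ss_mu", "ss_sigma")
  sc
}

blood_abundances <- function() {
  c(
    "Neutrophils" = 0.58,
    "Eosinophils" = 0.02,
    "Classical monocytes" = 0.068,
    "Intermediate monocytes" = 0.004,
    "Non-classical monocytes" = 0.008,
    "HLA-DRlo/neg monocytes" = 0.004,
    "CD4+ T cells" = 0.1323,
    "CD8+ T cells" = 0.0630,
    "CD4+CD8+ T cells" = 0.0021,
    "CD4-CD8- T cells" = 0.0063,
    "gamma-delta T cells" = 0.0063,
    "B cells" = 0.036,
    "CD56+CD16+ NK cells" = 0.0338,
    "CD56+CD16- NK cells" = 0.0112,
    "CD16+CD56- cells" = 0.004,
    "Myeloid DC" = 0.003,
    "CD16+ DC" = 0.002,
    "Plasmacytoid DC" = 0.0025,
    "Immature myeloid cells" = 0.005,
    "Basophils" = 0.000104
  )
}

marrow_abundances <- function() {
  c(
    "Neutrophils" = 0.60,
    "Eosinophils" = 0.02,
    "Classical monocytes" = 0.05,
    "Intermediate monocytes" = 0.003,
    "Non-classical monocytes" = 0.005,
    "HLA-DRlo/neg monocytes" = 0.003,
    "CD4+ T cells" = 0.07,
    "CD8+ T cells" = 0.035,
    "CD4+CD8+ T cells" = 0.001,
    "CD4-CD8- T cells" = 0.003,
    "gamma-delta T cells" = 0.003,
    "B cells" = 0.05,
    "CD56+CD16+ NK cells" = 0.015,
    "CD56+CD16- NK cells" = 0.005,
    "CD16+CD56- cells" = 0.002,
    "Myeloid DC" = 0.002,
    "CD16+ DC" = 0.001,
    "Plasmacytoid DC" = 0.002,
    "Immature myeloid cells" = 0.02,
    "Basophils" = 0.0005
  )
}

pleural_abundances <- function() {
  c(
    "Neutrophils" = 0.13,
    "Eosinophils" = 0.01,
    "Classical monocytes" = 0.10,
    "Intermediate monocytes" = 0.005,
    "Non-classical monocytes" = 0.01,
    "HLA-DRlo/neg monocytes" = 0.005,
    "CD4+ T cells" = 0.34,
    "CD8+ T cells" = 0.17,
    "CD4+CD8+ T cells" = 0.002,
    "CD4-CD8- T cells" = 0.006,
    "gamma-delta T cells" = 0.012,
    "B cells" = 0.04,
    "CD56+CD16+ NK cells" = 0.03,
    "CD56+CD16- NK cells" = 0.01,
    "CD16+CD56- cells" = 0.003,
    "Myeloid DC" = 0.003,
    "CD16+ DC" = 0.002,
    "Plasmacytoid DC" = 0.002,
    "Immature myeloid cells" = 0.003,
    "Basophils" = 0.0002
  )
}

# Stained-marker levels shared by all tissue profiles. Encodes the region
# structure of the published marker histograms: e.g. CD33 is bright (R2) on
# monocytes, moderate (R1) on granulocytes and immature myeloid cells;
# granulocytes are strongly CD15+/CD66b+ with a dim CD15/CD66b fraction on
# monocytes; CD123 is carried by immature myeloid cells, basophils and
# (brightest) plasmacytoid DCs.
default_expression <- function() {
  L <- function(population, marker, geo_mean, geo_cv = CV_POS) {
    tibble(
      population = population, marker = marker,
      geo_mean = geo_mean, geo_cv = geo_cv
    )
  }
  all_pops <- names(blood_abundances())
  bind_rows(
    L(c(all_pops, "Lineage-negative lymphocytes"), "CD45", LVL_POS),
    # granulocytes
    L("Neutrophils", "CD15", LVL_BRIGHT),
    L("Neutrophils", "CD16", LVL_BRIGHT),
    L("Neutrophils", "CD66b", LVL_BRIGHT),
    L("Neutrophils", "CD33", LVL_MID),
    L("Neutrophils", "CD11b", LVL_BRIGHT),
    L("Neutrophils", "CD11c", LVL_MID),
    L("Eosinophils", "CD15", LVL_BRIGHT),
    L("Eosinophils", "CD66b", LVL_BRIGHT),
    L("Eosinophils", "CD33", LVL_MID),
    L("Eosinophils", "CD11b", LVL_BRIGHT),
    L("Eosinophils", "CD11c", LVL_MID),
    L("Eosinophils", "CCR3", LVL_POS),
    # monocytes
    L("Classical monocytes", "CD14", LVL_POS),
    L("Intermediate monocytes", "CD14", LVL_POS),
    L("Non-classical monocytes", "CD14", LVL_LO),
    L("HLA-DRlo/neg monocytes", "CD14", LVL_POS),
    L("Intermediate monocytes", "CD16", LVL_POS),
    L("Non-classical monocytes", "CD16", LVL_BRIGHT),
    L(
      c(
        "Classical monocytes", "Intermediate monocytes",
        "Non-classical monocytes", "HLA-DRlo/neg monocytes"
      ),
      "CD33", LVL_BRIGHT
    ),
    L(
      c(
        "Classical monocytes", "Intermediate monocytes",
        "Non-classical monocytes", "HLA-DRlo/neg monocytes"
      ),
      "CD11b", LVL_BRIGHT
    ),
    L(
      c(
        "Classical monocytes", "Intermediate monocytes",
        "Non-classical monocytes", "HLA-DRlo/neg monocytes"
      ),
      "CD11c", LVL_BRIGHT
    ),
    L("Classical monocytes", "HLA-DR", LVL_POS),
    L("Intermediate monocytes", "HLA-DR", LVL_BRIGHT),
    L("Non-classical monocytes", "HLA-DR", LVL_POS),
    L("HLA-DRlo/neg monocytes", "HLA-DR", 2 * BG_GEO, BG_CV),
    L(
      c(
        "Classical monocytes", "Intermediate monocytes",
        "Non-classical monocytes", "HLA-DRlo/neg monocytes"
      ),
      "CD4", LVL_DIM
    ),
    L(c("Classical monocytes", "Intermediate monocytes"), "CD15", LVL_DIM),
    L(c("Classical monocytes", "Intermediate monocytes"), "CD66b", LVL_DIM),
    L("Classical monocytes", "CD64", LVL_POS),
    L("Classical monocytes", "CD32", LVL_POS),
    L(
      c(
        "Classical monocytes", "Intermediate monocytes",
        "Non-classical monocytes"
      ),
      "CD86", LVL_POS
    ),
    L(
      c(
        "Classical monocytes", "Intermediate monocytes",
        "Non-classical monocytes"
      ),
      "CD40", LVL_MID
    ),
    L(
      c(
        "Classical monocytes", "Intermediate monocytes",
        "Non-classical monocytes"
      ),
      "TNFR2", LVL_MID
    ),
    # T cells
    L(
      c(
        "CD4+ T cells", "CD8+ T cells", "CD4+CD8+ T cells",
        "CD4-CD8- T cells", "gamma-delta T cells"
      ),
      "CD3", LVL_BRIGHT
    ),
    L(c("CD4+ T cells", "CD4+CD8+ T cells"), "CD4", LVL_BRIGHT),
    L(c("CD8+ T cells", "CD4+CD8+ T cells"), "CD8", LVL_BRIGHT),
    L("gamma-delta T cells", "gdTCR", LVL_POS),
    # B and NK
    L("B cells", "CD19", LVL_BRIGHT),
    L("B cells", "CD20", LVL_BRIGHT),
    L("B cells", "HLA-DR", LVL_BRIGHT),
    L("CD56+CD16+ NK cells", "CD56", LVL_POS),
    L("CD56+CD16+ NK cells", "CD16", LVL_BRIGHT),
    L("CD56+CD16+ NK cells", "CD8", LVL_DIM),
    L("CD56+CD16- NK cells", "CD56", LVL_BRIGHT),
    L("CD16+CD56- cells", "CD16", LVL_BRIGHT),
    # dendritic and immature myeloid compartment
    L("Myeloid DC", "CD33", LVL_BRIGHT),
    L("Myeloid DC", "CD11c", LVL_BRIGHT),
    L("Myeloid DC", "HLA-DR", LVL_BRIGHT),
    L("Myeloid DC", "CD11b", LVL_MID),
    L("CD16+ DC", "CD33", LVL_MID),
    L("CD16+ DC", "CD11c", LVL_BRIGHT),
    L("CD16+ DC", "CD16", LVL_POS),
    L("CD16+ DC", "HLA-DR", LVL_BRIGHT),
    L("CD16+ DC", "CD123", 10 * BG_GEO),
    L("CD16+ DC", "CD11b", LVL_MID),
    L("Plasmacytoid DC", "CD123", CD123_PDC_GEO, 0.5),
    L("Plasmacytoid DC", "CD33", LVL_MID),
    L("Plasmacytoid DC", "HLA-DR", LVL_BRIGHT),
    L("Immature myeloid cells", "CD33", LVL_MID),
    L("Immature myeloid cells", "CD11b", LVL_BRIGHT),
    L("Immature myeloid cells", "CD11c", LVL_MID),
    L("Immature myeloid cells", "CD123", CD123_IMMC_GEO, CD123_IMMC_CV),
    L("Basophils", "CD33", LVL_MID),
    L("Basophils", "CD123", CD123_PDC_GEO, 0.5),
    L("Basophils", "CD15", 100 * BG_GEO, 0.5),
    L("Basophils", "CD11b", LVL_MID),
    L("Basophils", "CD203c", LVL_POS)
  )
}

#' Default donor profiles
#'
#' Built-in profiles for the three simulated tissues: healthy peripheral
#' blood (granulocyte-dominated), bone marrow (granulocyte-rich with an
#' enlarged immature myeloid compartment), and pleural fluid (T-cell
#' dominated). A lineage-negative lymphoid filler population absorbs the
#' residual abundance so fractions sum to exactly one.
#'
#' @param kind One of `"healthy_blood"`, `"marrow"`, `"pleural"`.
#' @return A [donor_profile()].
#' @examples
#' default_profile("healthy_blood")
#' @export
default_profile <- function(kind = c("healthy_blood", "marrow", "pleural")) {
  kind <- rlang::arg_match(kind)
  ab <- switch(kind,
    healthy_blood = blood_abundances(),
    marrow = marrow_abundances(),
    pleural = pleural_abundances()
  )
  wbc <- switch(kind, healthy_blood = 6000, marrow = 25000, pleural = 1500)
  tissue <- switch(kind,
    healthy_blood = "blood", marrow = "marrow", pleural = "pleural"
  )
  ab <- c(ab, "Lineage-negative lymphocytes" = unname(1 - sum(ab)))
  templates <- purrr::map2_dfr(names(ab), unname(ab), function(p, a) {
    sc <- scatter_defaults(p)
    tibble(population = p, abundance = a, !!!as.list(sc))
  })
  donor_profile(
    name = kind, tissue = tissue, wbc_per_ul = wbc,
    templates = templates, expression = default_expression()
  )
}

#' Adjust one population's abundance
#'
#' Sets a population's fraction and rebalances the remaining populations
#' proportionally so abundances still sum to one. Useful for longitudinal
#' scenarios such as therapeutic B-cell depletion.
#'
#' @param profile A [donor_profile()].
#' @param population Population name.
#' @param abundance New fraction in `[0, 1)`.
#' @return The modified profile.
#' @export
set_abundance <- function(profile, population, abundance) {
  tpl <- profile$templates
  i <- which(tpl$population == population)
  if (length(i) != 1) abort(sprintf("Unknown population '%s'.", population))
  rest <- sum(tpl$abundance[-i])
  tpl$abundance[-i] <- tpl$abundance[-i] * (1 - abundance) / rest
  tpl$abundance[i] <- abundance
  profile$templates <- tpl
  profile$basophil_fraction <-
    tpl$abundance[tpl$population == "Basophils"] %||% 0
  donor_profile(
    profile$name, profile$tissue, profile$wbc_per_ul, tpl, profile$expression
  )
}

`%||%` <- function(a, b) if (length(a) == 0 || is.null(a)) b else a
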