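## Spatial flux budgets: homogeneous / mosaic / interactive models

#' Choose a spatial model for a heterogeneous system
#'
#' Decision tree: spatial heterogeneity can be ignored (homogeneous model)
#' only when there are no lateral fluxes, no spatially variable drivers and no
#' nonlinearities; nonlinearity or variable drivers without significant
#' lateral fluxes call for a mosaic model (per-ecosystem budgets summed);
#' significant lateral fluxes call for an interactive model (composition and
#' configuration both considered).
#'
#' @param has_lateral Significant lateral fluxes present?
#' @param has_variable_drivers Spatially variable drivers present?
#' @param has_nonlinearity Nonlinear process responses present?
#' @return `"homogeneous"`, `"mosaic"` or `"interactive"`.
#' @export
#' @examples
#' select_spatial_model(TRUE, TRUE, FALSE) # "interactive"
select_spatial_model <- function(has_lateral, has_variable_drivers,
                                 has_nonlinearity) {
  if (isTRUE(has_lateral)) return("interactive")
  if (isTRUE(has_variable_drivers) || isTRUE(has_nonlinearity))
    return("mosaic")
  "homogeneous"
}

#' Bundle areal/lineal flux intensities with areas and interface lengths
#'
#' @param areal Data frame with columns `compartment`, `process`, `value`:
#'   areal intensities in g C m-2 yr-1.
#' @param lineal Data frame with the same columns: lineal (per-shoreline)
#'   intensities in g C m-1 yr-1, keyed by the donor compartment.
#' @param areas Named numeric vector of compartment areas in m^2.
#' @param lengths Named numeric vector of donor-interface lengths in km.
#' @return An object of class `intensity_set`.
#' @export
intensity_set <- function(areal, lineal = NULL, areas = numeric(),
                          lengths = numeric()) {
  stopifnot(is.data.frame(areal),
            all(c("compartment", "process", "value") %in% names(areal)))
  if (any(areas < 0, na.rm = TRUE) || any(lengths < 0, na.rm = TRUE))
    stop("areas and interface lengths must be >= 0")
  structure(list(areal = areal, lineal = lineal,
                 areas = areas, lengths = lengths),
            class = "intensity_set")
}

# fetch one intensity value; error names the missing symbol
.rho <- function(is, compartment, process, basis = "areal") {
  tab <- if (basis == "areal") is$areal else is$lineal
  v <- tab$value[tab$compartment == compartment & tab$process == process]
  if (length(v) != 1 || is.na(v))
    stop(sprintf("missing %s intensity rho_{%s,%s}", basis, compartment,
                 process))
  v
}

.area <- function(is, compartment) {
  a <- is$areas[compartment]
  if (is.na(a)) stop("missing area A_{", compartment, "}")
  unname(a)
}

.length_km <- function(is, compartment) {
  l <- is$lengths[compartment]
  if (is.na(l)) stop("missing interface length L_{", compartment, "}")
  unname(l)
}

# grams per gigagram
.G_PER_GG <- 1e9

#' Homogeneous (spatially invariable) flux
#'
#' Total flux from a single mean intensity: `rho * area`, converted from g to
#' Gg (1 Gg = 1e9 g).
#'
#' @param rho Areal intensity in g C m-2 yr-1.
#' @param area Surface area in m^2.
#' @return Flux in Gg C yr-1.
#' @export
#' @examples
#' homogeneous_flux(1.8, 3.454e9) # ~6.2 Gg C yr-1 of C precipitation
homogeneous_flux <- function(rho, area) {
  stopifnot(is.finite(rho), area >= 0)
  rho * area / .G_PER_GG
}

#' Mosaic model: per-compartment vertical budgets
#'
#' Net vertical carbon exchange of the forest, wetland and surface-water
#' compartments with the atmosphere, each modelled separately from its own
#' intensities and area, plus the atmosphere balance that closes the column:
#' `F_a,v = -(F_f,v + F_w,v + F_s,v)`. Forest: precipitation + GPP -
#' respiration. Wetland: precipitation + GPP - respiration - CH4. Surface
#' waters: precipitation - CO2 evasion - CH4 evasion (no aquatic GPP/R
#' intensities are distinguished; gas evasion is the estimated net term).
#'
#' @param intensities An [intensity_set()] with compartments `forest`,
#'   `wetland`, `surface_waters`.
#' @return An object of class `spatial_budget` with vertical fields
#'   `F_f_v`, `F_w_v`, `F_s_v`, `F_a_v` in Gg C yr-1.
#' @export
mosaic_vertical_budget <- function(intensities) {
  is <- intensities
  rho_P <- .rho(is, "all", "precipitation")
  f <- (rho_P + .rho(is, "forest", "GPP") - .rho(is, "forest", "respiration")) *
    .area(is, "forest") / .G_PER_GG
  w <- (rho_P + .rho(is, "wetland", "GPP") - .rho(is, "wetland", "respiration") -
          .rho(is, "wetland", "CH4")) * .area(is, "wetland") / .G_PER_GG
  s <- (rho_P - .rho(is, "surface_waters", "CO2_evasion") -
          .rho(is, "surface_waters", "CH4")) *
    .area(is, "surface_waters") / .G_PER_GG
  structure(list(model = "mosaic",
                 F_f_v = f, F_w_v = w, F_s_v = s, F_a_v = -(f + w + s)),
            class = "spatial_budget")
}

#' Interactive model: lateral budgets with interface terms
#'
#' Lateral carbon budgets of the donor compartments (negative totals: DIC and
#' DOC runoff by area, litter subsidy by interface length) and of the
#' receiving surface waters (receipts minus the downstream export):
#' `F_f,l + F_w,l + F_s,l + F_d,l = 0` by construction.
#'
#' @inheritParams mosaic_vertical_budget
#' @param downstream_export Regional riverine export `F_d,l` in Gg C yr-1.
#' @return An object of class `spatial_budget` with lateral fields `F_f_l`,
#'   `F_w_l`, `F_s_l`, `F_d_l` in Gg C yr-1.
#' @export
interactive_lateral_budget <- function(intensities, downstream_export) {
  is <- intensities
  lat_out <- function(comp) {
    (.rho(is, comp, "DIC_runoff") * .area(is, comp) +
       .rho(is, comp, "DOC_runoff") * .area(is, comp) +
       .rho(is, comp, "litter", basis = "lineal") *
         .length_km(is, comp) * 1000) / .G_PER_GG
  }
  f <- -lat_out("forest")
  w <- -lat_out("wetland")
  s <- -(f + w) - downstream_export
  structure(list(model = "interactive",
                 F_f_l = f, F_w_l = w, F_s_l = s, F_d_l = downstream_export),
            class = "spatial_budget")
}

#' @export
print.spatial_budget <- function(x, ...) {
  cat("<spatial_budget> model:", x$model, "\n")
  for (nm in setdiff(names(x), "model"))
    cat(sprintf("  %-6s %10.3f Gg C yr-1\n", nm, x[[nm]]))
  invisible(x)
}
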