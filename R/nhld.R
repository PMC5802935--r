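## The packaged NHLD carbon-budget example

#' NHLD carbon-flux network
#'
#' The carbon budget of the Northern Highlands Lake District (NHLD) of
#' Wisconsin and Michigan — a lake-rich landscape of forests (53% by area),
#' wetlands (28%) and surface waters (13%) — encoded as a flux network: three
#' internal ecosystems, one undifferentiated exterior pool, and 21 flow
#' records (best estimate plus range, Gg C yr-1), including the storage
#' self-flows (accumulation, sediment). Back-derived compartment areas are
#' attached (see `nhld_intensities()` for the derivation).
#'
#' @return A `flux_network` with compartments `forest`, `wetland`,
#'   `surface_waters`, `external`.
#' @export
#' @examples
#' net <- nhld_network()
#' compartment_throughput(net, "wetland") # 1669.9
nhld_network <- function() {
  path <- system.file("extdata", "nhld_carbon_fluxes.csv",
                      package = "metaflux", mustWork = TRUE)
  net <- read_flow_table(path, exterior_ids = "external",
                         provenance = "NHLD regional carbon budget")
  ints <- nhld_intensities()
  i <- match(names(ints$areas), net$compartments$id)
  net$compartments$area[i] <- unname(ints$areas)
  net
}

#' NHLD flux intensities and geometry
#'
#' Local areal intensities (g C m-2 yr-1), per-shoreline lineal litter
#' intensities (g C m-1 yr-1), back-derived compartment areas (m2) and
#' donor-to-surface-water interface lengths (km) for the NHLD budget, for use
#' with the spatial budget models.
#'
#' @return An [intensity_set()].
#' @export
nhld_intensities <- function() {
  path <- system.file("extdata", "nhld_intensities.csv",
                      package = "metaflux", mustWork = TRUE)
  read_intensity_table(path)
}

#' Read an intensity table
#'
#' CSV with columns `compartment`, `process`, `basis`, `value`, `units`;
#' `basis` is one of `areal`, `lineal`, `area`, `length`.
#'
#' @param path CSV file path.
#' @return An [intensity_set()].
#' @export
read_intensity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  pick <- function(b) df[df$basis == b, c("compartment", "process", "value")]
  vec <- function(b) {
    rows <- df[df$basis == b, ]
    stats::setNames(rows$value, rows$compartment)
  }
  intensity_set(areal = pick("areal"), lineal = pick("lineal"),
                areas = vec("area"), lengths = vec("length"))
}

#' Total NHLD carbon pool
#'
#' The regional carbon stock (380.05 Tg C = 380050 Gg C), used for the
#' activity ratio TST/stock.
#'
#' @return Stock in Gg C.
#' @export
nhld_total_stock <- function() 380050
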