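#' @keywords internal
"_PACKAGE"

## Controlled vocabularies --------------------------------------------------

#' Controlled vocabularies for flux networks
#'
#' `flux_processes()` lists the recognised process labels, `flux_orientations()`
#' the flow orientations, and `compartment_roles()` the compartment roles.
#' Self-flows (`source == target`) are permitted only for the storage
#' processes `accumulation` and `sediment`.
#'
#' @return A character vector of labels.
#' @export
flux_processes <- function() {
  c("GPP", "respiration", "precipitation", "DIC_runoff", "DOC_runoff",
    "litter", "CH4", "CO2_evasion", "sediment", "accumulation",
    "runoff_export", "other")
}

#' @rdname flux_processes
#' @export
flux_orientations <- function() c("lateral", "vertical", "internal")

#' @rdname flux_processes
#' @export
compartment_roles <- function() c("internal_ecosystem", "exterior", "storage")

# processes allowed to form self-flows
.self_flow_processes <- c("accumulation", "sediment")

## Constructors -------------------------------------------------------------

#' Build a compartment table
#'
#' Compartments are aspatial nodes: internal ecosystems, exterior pools
#' (e.g. the atmosphere), or storage. Areas, when given, are surface areas in
#' m^2; stocks are pool sizes in Gg C.
#'
#' @param id Character vector of unique compartment ids.
#' @param name Free-text names (defaults to `id`).
#' @param role One of `compartment_roles()`, recycled.
#' @param area Surface area in m^2 (`NA` if unknown); must be positive.
#' @param stock Carbon pool size in Gg C (`NA` if unknown).
#' @return A `data.frame` with columns `id`, `name`, `role`, `area`, `stock`.
#' @export
#' @examples
#' compartments(c("forest", "wetland"), role = "internal_ecosystem")
compartments <- function(id, name = id, role = "internal_ecosystem",
                         area = NA_real_, stock = NA_real_) {
  stopifnot(is.character(id))
  if (length(id) == 0)
    return(data.frame(id = character(), name = character(), role = character(),
                      area = numeric(), stock = numeric(),
                      stringsAsFactors = FALSE))
  role <- match.arg(role, compartment_roles(), several.ok = TRUE)
  df <- data.frame(id = id, name = name,
                   role = rep_len(role, length(id)),
                   area = rep_len(as.numeric(area), length(id)),
                   stock = rep_len(as.numeric(stock), length(id)),
                   stringsAsFactors = FALSE)
  df
}

#' Build a flow table
#'
#' Each row is one directed flux record between compartments, with a process
#' label, an orientation, a best-estimate magnitude and optional low/high
#' range bounds, all in Gg C yr-1. `best` may be negative only for
#' `accumulation` (a compartment drawing down its store).
#'
#' @param source,target Compartment ids.
#' @param process Process labels from `flux_processes()`.
#' @param orientation Orientation labels from `flux_orientations()`.
#' @param best Best-estimate magnitudes, Gg C yr-1.
#' @param low,high Optional range bounds (`low <= best <= high`; `low` may be
#'   negative, as for an uncertain net accumulation).
#' @param significance `"unset"`, `"significant"` or `"insignificant"`.
#' @return A `data.frame` of flow records.
#' @export
flows <- function(source, target, process, orientation, best,
                  low = NA_real_, high = NA_real_, significance = "unset") {
  n <- length(source)
  data.frame(source = as.character(source), target = as.character(target),
             process = rep_len(as.character(process), n),
             orientation = rep_len(as.character(orientation), n),
             best = as.numeric(best),
             low = rep_len(as.numeric(low), n),
             high = rep_len(as.numeric(high), n),
             significance = rep_len(as.character(significance), n),
             stringsAsFactors = FALSE)
}

#' Assemble and validate a flux network
#'
#' A flux network is a weighted directed multigraph: a compartment table and a
#' flow table plus units metadata. Validation enforces unique compartment ids,
#' declared endpoints for every flow, at most one flow per
#' (source, target, process) triple, finite magnitudes, ordered range bounds,
#' non-negative magnitudes except for accumulation, and self-flows only for
#' storage processes.
#'
#' @param compartments A compartment table from [compartments()].
#' @param flows A flow table from [flows()] (may have zero rows).
#' @param units Units label; the canonical internal unit is `"Gg C yr-1"`.
#' @param provenance Free-text metadata carried along unchanged.
#' @return An object of class `flux_network`.
#' @export
#' @examples
#' comp <- compartments(c("a", "b"))
#' fl <- flows("a", "b", "DOC_runoff", "lateral", 5)
#' net <- flux_network(comp, fl)
flux_network <- function(compartments, flows = NULL, units = "Gg C yr-1",
                         provenance = "") {
  if (is.null(flows)) {
    flows <- data.frame(source = character(), target = character(),
                        process = character(), orientation = character(),
                        best = numeric(), low = numeric(), high = numeric(),
                        significance = character(), stringsAsFactors = FALSE)
  }
  net <- structure(list(compartments = compartments, flows = flows,
                        units = units, provenance = provenance),
                   class = "flux_network")
  validate_flux_network(net)
}

#' @rdname flux_network
#' @param x A `flux_network`.
#' @export
validate_flux_network <- function(x) {
  comp <- x$compartments
  fl <- x$flows
  if (anyDuplicated(comp$id))
    stop("duplicate compartment ids: ",
         paste(unique(comp$id[duplicated(comp$id)]), collapse = ", "))
  if (!all(comp$role %in% compartment_roles()))
    stop("unknown compartment role(s): ",
         paste(setdiff(comp$role, compartment_roles()), collapse = ", "))
  bad_area <- !is.na(comp$area) & comp$area <= 0
  if (any(bad_area))
    stop("non-positive area for compartment(s): ",
         paste(comp$id[bad_area], collapse = ", "))
  if (nrow(fl) > 0) {
    dangling <- setdiff(c(fl$source, fl$target), comp$id)
    if (length(dangling) > 0) {
      i <- which(fl$source %in% dangling | fl$target %in% dangling)[1]
      stop("flow references undeclared compartment(s) [",
           paste(dangling, collapse = ", "), "]; first offending flow: ",
           fl$source[i], " -> ", fl$target[i], " (", fl$process[i], ")")
    }
    key <- paste(fl$source, fl$target, fl$process, sep = "\r")
    if (anyDuplicated(key)) {
      d <- fl[duplicated(key), , drop = FALSE][1, ]
      stop("duplicate flow for (source, target, process) = (",
           d$source, ", ", d$target, ", ", d$process, ")")
    }
    if (!all(fl$process %in% flux_processes()))
      stop("unknown process label(s): ",
           paste(setdiff(fl$process, flux_processes()), collapse = ", "))
    if (!all(fl$orientation %in% flux_orientations()))
      stop("unknown orientation(s): ",
           paste(setdiff(fl$orientation, flux_orientations()), collapse = ", "))
    if (!all(is.finite(fl$best)))
      stop("non-finite best magnitude in flow(s) ",
           paste(which(!is.finite(fl$best)), collapse = ", "))
    neg <- fl$best < 0 & fl$process != "accumulation"
    if (any(neg))
      stop("negative best magnitude allowed only for accumulation; flow(s) ",
           paste(which(neg), collapse = ", "))
    bad_rng <- (!is.na(fl$low) & fl$low > fl$best) |
      (!is.na(fl$high) & fl$high < fl$best)
    if (any(bad_rng))
      stop("range bounds must satisfy low <= best <= high; flow(s) ",
           paste(which(bad_rng), collapse = ", "))
    self <- fl$source == fl$target
    bad_self <- self & !(fl$process %in% .self_flow_processes)
    if (any(bad_self))
      stop("self-flows permitted only for accumulation/sediment; flow(s) ",
           paste(which(bad_self), collapse = ", "))
    if (!all(fl$significance %in% c("unset", "significant", "insignificant")))
      stop("significance must be unset/significant/insignificant")
  }
  x
}

#' @export
print.flux_network <- function(x, ...) {
  n_int <- sum(x$compartments$role == "internal_ecosystem")
  cat("<flux_network> ", nrow(x$compartments), " compartments (",
      n_int, " internal), ", nrow(x$flows), " flows [", x$units, "]\n",
      sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  flagged <- x$flows$significance != "unset"
  if (nrow(x$flows) > 0 && any(flagged))
    cat("  significance: ", sum(x$flows$significance == "significant"),
        " significant / ", sum(x$flows$significance == "insignificant"),
        " insignificant\n", sep = "")
  invisible(x)
}

## Accessors ----------------------------------------------------------------

#' Internal ecosystem ids of a network
#' @param network A `flux_network`.
#' @return Character vector of compartment ids with role `internal_ecosystem`.
#' @export
internal_ids <- function(network) {
  network$compartments$id[network$compartments$role == "internal_ecosystem"]
}

# logical vector marking self-flows
.is_self <- function(flows) flows$source == flows$target

.check_id <- function(network, id) {
  if (length(id) != 1 || !id %in% network$compartments$id)
    stop("unknown compartment id: ", paste(id, collapse = ", "))
  invisible(id)
}

## Throughput and balance ---------------------------------------------------

#' Per-compartment throughput
#'
#' Sum of the best magnitudes of every flow entering or leaving a compartment.
#' Self-flows (accumulation, sediment) are excluded by default: a store does
#' not exchange with neighbours. Magnitudes enter as absolute values, so a
#' negative accumulation contributes its size when self-flows are included.
#'
#' @param network A `flux_network`.
#' @param id Compartment id.
#' @param include_self_flows Include accumulation/sediment self-flows?
#' @return Throughput in Gg C yr-1.
#' @export
#' @examples
#' net <- nhld_network()
#' compartment_throughput(net, "forest") # 5503.5
compartment_throughput <- function(network, id, include_self_flows = FALSE) {
  .check_id(network, id)
  fl <- network$flows
  if (nrow(fl) == 0) return(0)
  self <- .is_self(fl)
  touch <- (fl$source == id | fl$target == id)
  keep <- touch & (include_self_flows | !self)
  # self-flows touch twice but count once
  sum(abs(fl$best[keep]))
}

#' Per-compartment net balance
#'
#' Inflow sum minus outflow sum, self-flows excluded: the empirical analogue
#' of a compartment's local growth rate in the absence of spatial flows.
#'
#' @inheritParams compartment_throughput
#' @return Net balance in Gg C yr-1 (positive = net gain).
#' @export
net_balance <- function(network, id) {
  .check_id(network, id)
  fl <- network$flows
  if (nrow(fl) == 0) return(0)
  fl <- fl[!.is_self(fl), , drop = FALSE]
  sum(fl$best[fl$target == id]) - sum(fl$best[fl$source == id])
}
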