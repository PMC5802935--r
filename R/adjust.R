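## Protocol step 3: adjust a fragmental landscape system to a meta-ecosystem

#' Exterior-compartment specification for meta-ecosystem adjustment
#'
#' Describes how boundary-crossing flows are simplified to a limited number of
#' exterior, inexhaustible compartments (no stock tracking, no balance
#' requirement), and how accumulation sign conventions are resolved.
#'
#' @param exterior_map Named character vector mapping flow orientations to
#'   exterior compartment ids, e.g. `c(vertical = "atmosphere",
#'   lateral = "downstream")`. Every boundary-crossing orientation must be
#'   covered.
#' @param process_map Optional named character vector mapping specific process
#'   labels to exterior ids, overriding `exterior_map`.
#' @param drop_insignificant Drop flows flagged insignificant (default TRUE).
#' @param negative_accumulation Policy for a negative accumulation of
#'   magnitude m: `"release_inflow"` (a release of +m back into the
#'   compartment, stored as a positive self-loop), `"signed_self_loop"`
#'   (retained as signed), or `"exclude"` (omitted).
#' @param self_loops_in_tst Should accumulation/sediment self-loops enter the
#'   total system throughput and the ENA marginals (default TRUE)?
#' @return An object of class `exterior_spec`.
#' @export
exterior_spec <- function(exterior_map = c(vertical = "atmosphere",
                                           lateral = "downstream"),
                          process_map = NULL,
                          drop_insignificant = TRUE,
                          negative_accumulation = c("release_inflow",
                                                    "signed_self_loop",
                                                    "exclude"),
                          self_loops_in_tst = TRUE) {
  negative_accumulation <- match.arg(negative_accumulation)
  stopifnot(is.character(exterior_map), !is.null(names(exterior_map)),
            all(names(exterior_map) %in% flux_orientations()))
  structure(list(exterior_map = exterior_map, process_map = process_map,
                 drop_insignificant = drop_insignificant,
                 negative_accumulation = negative_accumulation,
                 self_loops_in_tst = self_loops_in_tst),
            class = "exterior_spec")
}

#' Adjust a flagged landscape system to a closed meta-ecosystem
#'
#' Re-points every boundary-crossing flow (a flow with an exterior-role
#' endpoint) at its mapped exterior compartment, optionally drops insignificant
#' flows, and resolves accumulation sign conventions. The result is closed:
#' every endpoint is a declared member compartment, so classifying it with
#' exteriors treated as members yields `systemic`. Adjusting an
#' already-adjusted network is a no-op.
#'
#' @param network A significance-flagged `flux_network` (fragmental or
#'   systemic).
#' @param spec An [exterior_spec()].
#' @return A closed `flux_network`; the spec used is recorded in `$meta`.
#' @export
#' @examples
#' meta <- to_meta_ecosystem(flag_significance(nhld_network()))
#' sort(meta$compartments$id[meta$compartments$role == "exterior"])
to_meta_ecosystem <- function(network, spec = exterior_spec()) {
  stopifnot(inherits(spec, "exterior_spec"))
  fl <- network$flows
  if (nrow(fl) > 0 && any(fl$significance == "unset"))
    stop("significance flags not set; run flag_significance() first")
  if (spec$drop_insignificant)
    fl <- fl[fl$significance != "insignificant", , drop = FALSE]

  comp <- network$compartments
  ext_ids <- comp$id[comp$role == "exterior"]
  is_boundary <- fl$source %in% ext_ids | fl$target %in% ext_ids
  mapped_to <- character(nrow(fl))
  for (i in which(is_boundary)) {
    target_id <- spec$process_map[fl$process[i]]
    if (is.null(spec$process_map) || is.na(target_id))
      target_id <- spec$exterior_map[fl$orientation[i]]
    mapped_to[i] <- target_id
  }
  uncovered <- is_boundary & (is.na(mapped_to) | mapped_to == "")
  if (any(uncovered)) {
    u <- fl[uncovered, , drop = FALSE]
    stop("no exterior compartment mapped for boundary flow(s): ",
         paste(sprintf("%s->%s (%s, %s)", u$source, u$target, u$process,
                       u$orientation), collapse = "; "))
  }
  for (i in which(is_boundary)) {
    if (fl$source[i] %in% ext_ids) fl$source[i] <- mapped_to[i]
    if (fl$target[i] %in% ext_ids) fl$target[i] <- mapped_to[i]
  }

  # accumulation sign policy
  neg <- fl$process == "accumulation" & fl$best < 0
  if (any(neg)) {
    if (spec$negative_accumulation == "release_inflow") {
      fl$best[neg] <- abs(fl$best[neg])
      fl$low[neg] <- NA_real_
      fl$high[neg] <- NA_real_
    } else if (spec$negative_accumulation == "exclude") {
      fl <- fl[!neg, , drop = FALSE]
    } # signed_self_loop: keep as printed
  }
  fl$significance <- "significant"

  new_ext <- setdiff(unique(c(spec$exterior_map, spec$process_map)), NA)
  used <- unique(c(fl$source, fl$target))
  keep <- comp[comp$role != "exterior" | comp$id %in% used, , drop = FALSE]
  add <- setdiff(intersect(new_ext, used), keep$id)
  if (length(add) > 0)
    keep <- rbind(keep, compartments(add, role = "exterior"))
  out <- flux_network(keep, fl, units = network$units,
                      provenance = network$provenance)
  out$meta <- spec
  out
}

#' Source-sink residual of a closed network
#'
#' Sum over internal compartments of the net balance (inflow minus outflow,
#' self-flows excluded) after adjustment. In an exactly mass-conserving
#' meta-ecosystem the residual is zero; in an empirical budget it reports the
#' carbon retained in (or drawn from) storage plus estimation error.
#'
#' @param network A `flux_network`, typically from [to_meta_ecosystem()].
#' @return Residual in Gg C yr-1.
#' @export
source_sink_residual <- function(network) {
  ids <- internal_ids(network)
  if (length(ids) == 0) return(0)
  sum(vapply(ids, function(id) net_balance(network, id), numeric(1)))
}
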