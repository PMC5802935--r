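## Full protocol pipeline (also driven by the exec/metaflux CLI script)

#' Run the full landscape-to-meta-ecosystem protocol
#'
#' Executes the four protocol steps on a flux network: (1) the delineated
#' network is read or taken as given; (2) fluxes are significance-flagged and
#' the landscape system is classified; (3) the system is adjusted to a closed
#' meta-ecosystem with exterior compartments; (4) the ENA holistic indices are
#' computed, optionally alongside spatial budgets and scenario comparisons.
#'
#' @param input A `flux_network`, or a path to a flow-table CSV / network
#'   JSON.
#' @param ratio Significance threshold fraction (default 0.01).
#' @param spec An [exterior_spec()] controlling the adjustment.
#' @param total_stock Optional total stock (Gg C) for the activity ratio.
#' @param scenarios Optional list of [scenario()] objects compared on the
#'   adjusted network.
#' @param output Optional path; the report is written there as JSON.
#' @param exterior_ids Exterior ids used when `input` is a CSV path.
#' @param verbose Log each protocol step to the console.
#' @return A list with elements `flagged` (network), `landscape_class`,
#'   `meta` (adjusted network), `residual`, `report` (an `ena_report`), and
#'   `comparison` (data frame, when scenarios are given).
#' @export
#' @examples
#' res <- run_pipeline(nhld_network(), total_stock = nhld_total_stock())
#' res$landscape_class # "fragmental"
run_pipeline <- function(input, ratio = 0.01, spec = exterior_spec(),
                         total_stock = NULL, scenarios = list(),
                         output = NULL, exterior_ids = "external",
                         verbose = FALSE) {
  say <- function(...) if (verbose) message("[metaflux] ", ...)
  net <- if (inherits(input, "flux_network")) input
  else if (grepl("\\.json$", input)) read_network(input)
  else read_flow_table(input, exterior_ids = exterior_ids)
  say("step 1: network with ", nrow(net$compartments), " compartments, ",
      nrow(net$flows), " flows")

  flagged <- flag_significance(net, ratio = ratio)
  cls <- classify_landscape_system(flagged)
  say("step 2: ", sum(flagged$flows$significance == "insignificant"),
      " insignificant flows; landscape system is ", cls)
  if (cls %in% c("omnidirectionally_discrete"))
    stop("an omnidirectionally discrete landscape system cannot be adjusted ",
         "to a meta-ecosystem")

  meta <- to_meta_ecosystem(flagged, spec)
  residual <- source_sink_residual(meta)
  say("step 3: closed meta-ecosystem with exteriors ",
      paste(meta$compartments$id[meta$compartments$role == "exterior"],
            collapse = ", "))

  report <- ena_report(meta, total_stock = total_stock,
                       include_self_loops = spec$self_loops_in_tst)
  say(sprintf("step 4: TST %.2f, AMI %.6f, A %.2f, C %.2f, R %.2f",
              report$tst, report$ami, report$ascendency, report$capacity,
              report$redundancy))
  comparison <- if (length(scenarios) > 0)
    compare_scenarios(meta, scenarios, total_stock = total_stock,
                      include_self_loops = spec$self_loops_in_tst)

  out <- list(flagged = flagged, landscape_class = cls, meta = meta,
              residual = residual, report = report, comparison = comparison)
  if (!is.null(output)) {
    doc <- list(landscape_class = cls, residual = residual,
                report = unclass(report)[c("tst", "ami", "ascendency",
                                           "capacity", "redundancy",
                                           "ascendency_ratio",
                                           "resilience_ratio",
                                           "activity_ratio")],
                insignificant = flagged$flows[
                  flagged$flows$significance == "insignificant",
                  c("source", "target", "process", "best")],
                comparison = comparison)
    jsonlite::write_json(doc, output, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
    say("report written to ", output)
  }
  invisible(out)
}
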