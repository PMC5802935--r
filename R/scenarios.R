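## Scenario construction and comparison

#' Define a flux-substitution scenario
#'
#' A scenario is a named set of substitutions: replacement best-estimate
#' magnitudes for existing (source, target, process) flow records. Scenarios
#' are applied without mutating the base network.
#'
#' @param name Scenario label.
#' @param substitutions Data frame with columns `source`, `target`, `process`,
#'   `value`.
#' @return An object of class `flux_scenario`.
#' @export
#' @examples
#' sc <- scenario("wetter", data.frame(source = "forest", target = "surface_waters",
#'                process = "DOC_runoff", value = 23))
scenario <- function(name, substitutions) {
  stopifnot(is.character(name), length(name) == 1, is.data.frame(substitutions),
            all(c("source", "target", "process", "value") %in%
                  names(substitutions)))
  structure(list(name = name, substitutions = substitutions),
            class = "flux_scenario")
}

#' Read a scenario from a plain-text substitution file
#'
#' One substitution per line: `source,target,process,value`. Lines starting
#' with `#` are comments.
#'
#' @param path File path.
#' @param name Scenario label (defaults to the file name).
#' @return A `flux_scenario`.
#' @export
read_scenario <- function(path, name = basename(path)) {
  df <- utils::read.csv(path, header = FALSE, comment.char = "#",
                        col.names = c("source", "target", "process", "value"),
                        stringsAsFactors = FALSE)
  scenario(name, df)
}

#' Apply a scenario to a flux network
#'
#' Returns a copy of the network with substituted magnitudes; range bounds of
#' substituted flows are cleared, all other records untouched.
#'
#' @param network A `flux_network`.
#' @param scenario A [scenario()].
#' @return A new `flux_network`.
#' @export
apply_scenario <- function(network, scenario) {
  stopifnot(inherits(scenario, "flux_scenario"))
  fl <- network$flows
  key <- paste(fl$source, fl$target, fl$process, sep = "\r")
  sub <- scenario$substitutions
  skey <- paste(sub$source, sub$target, sub$process, sep = "\r")
  missing <- !(skey %in% key)
  if (any(missing))
    stop("scenario '", scenario$name, "' substitutes unknown flow(s): ",
         paste(sprintf("%s->%s (%s)", sub$source[missing], sub$target[missing],
                       sub$process[missing]), collapse = "; "))
  i <- match(skey, key)
  fl$best[i] <- sub$value
  fl$low[i] <- NA_real_
  fl$high[i] <- NA_real_
  network$flows <- fl
  validate_flux_network(network)
}

#' Compare ENA reports across scenarios
#'
#' One report row per scenario plus the base network, with per-index deltas
#' relative to the base. All networks must already be adjusted/closed.
#'
#' @param base A closed `flux_network`.
#' @param scenarios A list of [scenario()] objects (may be empty).
#' @param ... Passed to [ena_report()].
#' @return A data frame, one row per network, ordered base first.
#' @export
compare_scenarios <- function(base, scenarios = list(), ...) {
  nets <- c(list(base), lapply(scenarios, apply_scenario, network = base))
  labels <- c("base", vapply(scenarios, `[[`, character(1), "name"))
  rows <- lapply(nets, function(n) as.data.frame(ena_report(n, ...)))
  out <- do.call(rbind, rows)
  out <- cbind(scenario = labels, out, stringsAsFactors = FALSE)
  for (col in c("tst", "ami", "ascendency", "capacity", "redundancy"))
    out[[paste0("d_", col)]] <- out[[col]] - out[[col]][1]
  rownames(out) <- NULL
  out
}
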