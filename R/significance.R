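## Protocol step 2: significance filtering and landscape-system classification

#' Flag flux significance by the throughput-ratio rule
#'
#' A flux crossing ecosystem boundaries is insignificant when it is two orders
#' of magnitude smaller than the fluxes within the ecosystems it touches. The
#' rule implemented: a non-self flow is significant iff
#' `|best| >= ratio * throughput(e)` for at least one internal-ecosystem
#' endpoint `e`, with throughputs computed once on the unfiltered network
#' (self-flows excluded). Self-flows are always significant. Ties count as
#' significant. Re-flagging is idempotent.
#'
#' @param network A `flux_network` with at least one internal ecosystem.
#' @param ratio Threshold fraction of ecosystem throughput (default 0.01,
#'   i.e. two orders of magnitude).
#' @return The network with the `significance` column filled in.
#' @export
#' @examples
#' net <- flag_significance(nhld_network())
#' subset(net$flows, significance == "insignificant")
flag_significance <- function(network, ratio = 0.01) {
  stopifnot(is.numeric(ratio), length(ratio) == 1, ratio > 0, ratio < 1)
  internals <- internal_ids(network)
  if (length(internals) == 0)
    stop("network has no internal ecosystems to compare against")
  fl <- network$flows
  if (nrow(fl) == 0) return(network)
  thr <- vapply(internals, function(id)
    compartment_throughput(network, id, include_self_flows = FALSE), numeric(1))
  self <- .is_self(fl)
  if (sum(thr) == 0 && any(!self)) {
    warning("zero total throughput: all non-self flows flagged insignificant")
  }
  sig <- logical(nrow(fl))
  for (i in seq_len(nrow(fl))) {
    if (self[i]) { sig[i] <- TRUE; next }
    ends <- intersect(c(fl$source[i], fl$target[i]), internals)
    sig[i] <- length(ends) > 0 &&
      any(abs(fl$best[i]) >= ratio * thr[ends] & thr[ends] > 0)
  }
  fl$significance <- ifelse(sig, "significant", "insignificant")
  network$flows <- fl
  network
}

#' Classify a landscape system
#'
#' Decision-tree classification of a significance-flagged network:
#' * `systemic` — internal ecosystems are significantly interconnected and no
#'   significant flow crosses the system boundary;
#' * `fragmental` — internal ecosystems are significantly interconnected but
#'   significant flows cross the boundary (an exterior endpoint);
#' * `laterally_discrete` — no significant flows connect internal ecosystems,
#'   but two or more of them retain significant vertical flows (connected
#'   through the overlying medium);
#' * `omnidirectionally_discrete` — internal ecosystems share no significant
#'   flows in any orientation.
#'
#' @param network A flagged `flux_network` (see [flag_significance()]).
#' @param treat_exterior_as_internal Treat exterior compartments as members
#'   when judging interconnection; used to verify closure of an adjusted
#'   meta-ecosystem.
#' @return A single string, one of the four class labels.
#' @export
#' @examples
#' classify_landscape_system(flag_significance(nhld_network())) # "fragmental"
classify_landscape_system <- function(network,
                                      treat_exterior_as_internal = FALSE) {
  fl <- network$flows
  if (nrow(fl) > 0 && any(fl$significance == "unset"))
    stop("significance flags not set; run flag_significance() first")
  members <- internal_ids(network)
  if (treat_exterior_as_internal) {
    ext <- network$compartments$id[network$compartments$role == "exterior"]
    members <- c(members, ext)
  }
  sig <- fl[fl$significance == "significant" & !.is_self(fl), , drop = FALSE]
  between <- sig$source %in% members & sig$target %in% members &
    sig$source != sig$target
  crossing <- xor(sig$source %in% members, sig$target %in% members)
  interconnected <- any(between)
  if (interconnected) {
    if (any(crossing)) return("fragmental")
    return("systemic")
  }
  # internals not significantly interconnected: discrete system
  vert <- sig[sig$orientation == "vertical", , drop = FALSE]
  vertically_active <- unique(c(
    vert$source[vert$source %in% members],
    vert$target[vert$target %in% members]))
  if (length(vertically_active) >= 2) return("laterally_discrete")
  "omnidirectionally_discrete"
}
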