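## Ecological Network Analysis: the holistic flow-network indices

#' Aggregate a flux network into a square flow matrix
#'
#' Entry (i, j) is the total best-estimate flow from compartment i to
#' compartment j, parallel process records summed. Magnitudes enter as
#' absolute values (a signed self-loop retained under the
#' `signed_self_loop` policy contributes its size).
#'
#' @param network A `flux_network`.
#' @param include_self_loops Keep accumulation/sediment self-loops (default
#'   TRUE; they then enter the marginals and TST).
#' @return A numeric matrix with compartment ids as dimnames.
#' @export
as_flow_matrix <- function(network, include_self_loops = TRUE) {
  ids <- network$compartments$id
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  fl <- network$flows
  if (nrow(fl) == 0) return(m)
  if (!include_self_loops) fl <- fl[!.is_self(fl), , drop = FALSE]
  for (i in seq_len(nrow(fl)))
    m[fl$source[i], fl$target[i]] <- m[fl$source[i], fl$target[i]] +
      abs(fl$best[i])
  m
}

#' Total system throughput
#'
#' The sum of all flows in the network: the size and overall activity of the
#' meta-ecosystem.
#'
#' @inheritParams as_flow_matrix
#' @return TST in the network's flow units (Gg C yr-1).
#' @export
tst <- function(network, include_self_loops = TRUE) {
  sum(as_flow_matrix(network, include_self_loops))
}

# shared kernel: returns list(T, ami, ascendency, capacity) from a flow matrix
.ena_indices <- function(m, log_base = 2, k = 1) {
  T_ <- sum(m)
  if (T_ <= 0) stop("total system throughput is zero; indices undefined")
  Ti <- rowSums(m) # total outflow of each compartment
  Tj <- colSums(m) # total inflow of each compartment
  idx <- which(m > 0, arr.ind = TRUE)
  v <- m[idx]
  lg <- function(x) log(x, base = log_base)
  a_terms <- v * lg(v * T_ / (Ti[idx[, 1]] * Tj[idx[, 2]]))
  list(tst = T_,
       ami = k * sum(a_terms) / T_,
       ascendency = sum(a_terms),
       capacity = -sum(v * lg(v / T_)))
}

#' Average mutual information of a flow network
#'
#' `AMI = k * sum_ij (T_ij / T) log( T_ij T / (T_i T_j) )` with `T_i` the
#' total outflow of compartment i, `T_j` the total inflow of j, `T` the total
#' system throughput, and the convention `0 log 0 = 0` (zero flows are
#' skipped). With base-2 logarithms the result is in bits: the average number
#' of binary decisions needed to identify where a unit of flow goes next.
#'
#' @inheritParams as_flow_matrix
#' @param log_base Logarithm base (2 for bits).
#' @param k Scalar multiplier (default 1).
#' @return AMI in `log_base` units.
#' @export
#' @examples
#' ring <- generate_ring(4)
#' ami(ring) # log2(4) = 2 bits
ami <- function(network, log_base = 2, k = 1, include_self_loops = TRUE) {
  .ena_indices(as_flow_matrix(network, include_self_loops), log_base, k)$ami
}

#' Ascendency of a flow network
#'
#' `A = sum_ij T_ij log( T_ij T / (T_i T_j) )`, equal to `TST * AMI` when
#' `k = 1`: joint measure of system activity and organization.
#'
#' @inheritParams ami
#' @return Ascendency in flow units times `log_base` units
#'   (Gg C bits yr-1 for base 2).
#' @export
ascendency <- function(network, log_base = 2, include_self_loops = TRUE) {
  .ena_indices(as_flow_matrix(network, include_self_loops),
               log_base)$ascendency
}

#' Development capacity of a flow network
#'
#' `C = -sum_ij T_ij log(T_ij / T)`: the diversity of the flows scaled by the
#' total system throughput, an upper bound on ascendency.
#'
#' @inheritParams ami
#' @return Capacity in the same units as [ascendency()].
#' @export
capacity <- function(network, log_base = 2, include_self_loops = TRUE) {
  .ena_indices(as_flow_matrix(network, include_self_loops), log_base)$capacity
}

#' Redundancy (resilience) of a flow network
#'
#' `R = C - A`: the degree to which pathways parallel each other, read as
#' resilience, complementary to ascendency.
#'
#' @inheritParams ami
#' @return Redundancy in the same units as [ascendency()].
#' @export
redundancy <- function(network, log_base = 2, include_self_loops = TRUE) {
  z <- .ena_indices(as_flow_matrix(network, include_self_loops), log_base)
  z$capacity - z$ascendency
}

#' Full ENA report
#'
#' Computes the five holistic indices plus derived ratios: the ascendency
#' ratio A/C, the resilience ratio R/C, and (when a total stock is supplied)
#' the activity ratio TST/stock.
#'
#' @inheritParams ami
#' @param total_stock Optional total carbon pool size in the same mass units
#'   as the flows (Gg C), for the activity ratio.
#' @return An object of class `ena_report`: a list with elements `tst`, `ami`,
#'   `ascendency`, `capacity`, `redundancy`, `ascendency_ratio`,
#'   `resilience_ratio`, `activity_ratio`, `n_compartments`, `n_flows`.
#' @export
#' @examples
#' meta <- to_meta_ecosystem(flag_significance(nhld_network()))
#' ena_report(meta, total_stock = 380050)
ena_report <- function(network, total_stock = NULL, log_base = 2, k = 1,
                       include_self_loops = TRUE) {
  m <- as_flow_matrix(network, include_self_loops)
  z <- .ena_indices(m, log_base, k)
  red <- z$capacity - z$ascendency
  structure(list(
    tst = z$tst, ami = z$ami, ascendency = z$ascendency,
    capacity = z$capacity, redundancy = red,
    ascendency_ratio = if (z$capacity > 0) z$ascendency / z$capacity else NA_real_,
    resilience_ratio = if (z$capacity > 0) red / z$capacity else NA_real_,
    activity_ratio = if (!is.null(total_stock)) z$tst / total_stock else NA_real_,
    n_compartments = nrow(network$compartments),
    n_flows = nrow(network$flows),
    units = network$units, log_base = log_base
  ), class = "ena_report")
}

#' @export
print.ena_report <- function(x, ...) {
  unit_bits <- if (x$log_base == 2) "bits" else sprintf("log%g units", x$log_base)
  cat("<ena_report> ", x$n_compartments, " compartments, ", x$n_flows,
      " flows\n", sep = "")
  cat(sprintf("  TST         %12.2f %s\n", x$tst, x$units))
  cat(sprintf("  AMI         %12.6f %s\n", x$ami, unit_bits))
  cat(sprintf("  Ascendency  %12.2f flow-%s\n", x$ascendency, unit_bits))
  cat(sprintf("  Capacity    %12.2f flow-%s\n", x$capacity, unit_bits))
  cat(sprintf("  Redundancy  %12.2f flow-%s\n", x$redundancy, unit_bits))
  cat(sprintf("  A/C = %.4f   R/C = %.4f", x$ascendency_ratio,
              x$resilience_ratio))
  if (!is.na(x$activity_ratio))
    cat(sprintf("   TST/stock = %.4f%%", 100 * x$activity_ratio))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.ena_report <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(tst = x$tst, ami = x$ami, ascendency = x$ascendency,
             capacity = x$capacity, redundancy = x$redundancy,
             ascendency_ratio = x$ascendency_ratio,
             resilience_ratio = x$resilience_ratio,
             activity_ratio = x$activity_ratio,
             n_compartments = x$n_compartments, n_flows = x$n_flows,
             row.names = row.names, stringsAsFactors = FALSE)
}
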