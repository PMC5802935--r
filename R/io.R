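## Reading, writing and generating flux networks

# convert a magnitude column to Gg C yr-1
.to_gg <- function(x, units) {
  u <- unique(units)
  if (length(u) > 1)
    stop("mixed units in flow table: ", paste(u, collapse = ", "))
  if (grepl("^Gg", u)) return(x)
  if (grepl("^g ", u) || grepl("^g$", u)) return(x / 1e9)
  stop("unsupported units: ", u, " (expected 'Gg C yr-1' or 'g C yr-1')")
}

#' Read a flow table into a flux network
#'
#' Reads a CSV with columns `source`, `target`, `process`, `orientation`,
#' `best`, `low`, `high`, `units`. Compartments are inferred from flow
#' endpoints; ids listed in `exterior_ids` get the `exterior` role, all others
#' `internal_ecosystem`. Magnitudes are converted to Gg C yr-1 (tables mixing
#' units are rejected). Lines starting with `#` are comments.
#'
#' @param path CSV file path.
#' @param exterior_ids Compartment ids to mark as exterior pools.
#' @param provenance Free-text metadata attached to the network.
#' @return A `flux_network`.
#' @export
read_flow_table <- function(path, exterior_ids = "external",
                            provenance = path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         colClasses = "character")
  need <- c("source", "target", "process", "orientation", "best")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("flow table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(raw) == 0) {
    return(flux_network(compartments(character(0)), provenance = provenance))
  }
  num <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(x) & !is.na(raw[[col]]) & nzchar(trimws(raw[[col]]))
    if (any(bad))
      stop("non-numeric '", col, "' at data line(s) ",
           paste(which(bad), collapse = ", "), " of ", path)
    x
  }
  best <- num("best"); low <- num("low"); high <- num("high")
  if (any(is.na(best)))
    stop("missing 'best' at data line(s) ",
         paste(which(is.na(best)), collapse = ", "), " of ", path)
  units <- if ("units" %in% names(raw)) raw$units else "Gg C yr-1"
  best <- .to_gg(best, units); low <- .to_gg(low, units)
  high <- .to_gg(high, units)
  ids <- unique(c(raw$source, raw$target))
  comp <- compartments(ids, role = ifelse(ids %in% exterior_ids, "exterior",
                                          "internal_ecosystem"))
  flux_network(comp,
               flows(raw$source, raw$target, raw$process, raw$orientation,
                     best, low, high),
               provenance = provenance)
}

#' Write a flux network to disk
#'
#' `format = "csv"` writes the flow table (compartment roles are re-inferred
#' on read via `exterior_ids`); `format = "json"` writes the full network
#' document (compartments with roles/areas/stocks, flows, units, provenance),
#' which [read_network()] round-trips exactly.
#'
#' @param network A `flux_network`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    fl <- network$flows
    fl$units <- rep(network$units, nrow(fl))
    fl$significance <- NULL
    utils::write.csv(fl, path, row.names = FALSE, quote = FALSE)
  } else {
    doc <- list(units = network$units, provenance = network$provenance,
                compartments = network$compartments, flows = network$flows)
    jsonlite::write_json(doc, path, dataframe = "columns", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a network JSON document written by [write_network()]
#'
#' @param path JSON file path.
#' @return A `flux_network`.
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- as.data.frame(doc$compartments, stringsAsFactors = FALSE)
  comp$area <- as.numeric(comp$area)
  comp$stock <- as.numeric(comp$stock)
  fl <- as.data.frame(doc$flows, stringsAsFactors = FALSE)
  if (nrow(fl) > 0) {
    fl$best <- as.numeric(fl$best)
    fl$low <- as.numeric(fl$low)
    fl$high <- as.numeric(fl$high)
  } else {
    fl <- NULL
  }
  flux_network(comp, fl, units = doc$units, provenance = doc$provenance)
}

#' Export the square flow matrix (legacy interchange layout)
#'
#' Writes the pair-aggregated flow matrix as CSV for interoperability with
#' classic network-ecology software. Export-only convenience: process labels
#' and range bounds are not representable in this layout, so there is no
#' matching reader.
#'
#' @inheritParams as_flow_matrix
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flow_matrix <- function(network, path, include_self_loops = TRUE) {
  m <- as_flow_matrix(network, include_self_loops)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

## Synthetic networks --------------------------------------------------------

# run code under a local RNG seed without clobbering the caller's stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded random flux network
#'
#' Directed Erdos-Renyi style generator for property testing: each ordered
#' pair of distinct compartments carries a flow with probability
#' `connectance`, magnitudes log-normal(`mu`, `sigma`). A ring backbone keeps
#' the network strongly connected. With `balanced = TRUE`, per-compartment
#' outflows are iteratively rescaled (matrix-balancing passes) until every
#' compartment's inflow equals its outflow to within `tol` — a synthetic
#' closed meta-ecosystem.
#'
#' @param n Number of compartments (>= 2).
#' @param connectance Probability an ordered pair carries a flow (0, 1].
#' @param mu,sigma Log-normal magnitude parameters.
#' @param seed Integer seed; the same seed reproduces the same network.
#' @param balanced Force per-compartment inflow = outflow?
#' @param tol Relative balance tolerance.
#' @return A `flux_network` of internal ecosystems.
#' @export
#' @examples
#' net <- generate_network(5, 0.5, seed = 42)
generate_network <- function(n, connectance = 0.5, mu = 0, sigma = 1,
                             seed = 1, balanced = FALSE, tol = 1e-10) {
  if (n < 2) stop("n must be >= 2")
  stopifnot(connectance > 0, connectance <= 1)
  .with_seed(seed, {
    ids <- sprintf("c%02d", seq_len(n))
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    pick <- matrix(stats::runif(n * n) < connectance, n, n)
    diag(pick) <- FALSE
    # ring backbone: guarantees strong connectivity (and balancing convergence)
    for (i in seq_len(n)) pick[i, i %% n + 1] <- TRUE
    m[pick] <- stats::rlnorm(sum(pick), meanlog = mu, sdlog = sigma)
    if (balanced) {
      for (it in seq_len(10000)) {
        out <- rowSums(m); inn <- colSums(m)
        if (max(abs(out - inn)) <= tol * sum(m)) break
        m <- m * sqrt(inn / out) # rescale each compartment's outflows
      }
    }
    idx <- which(m > 0, arr.ind = TRUE)
    flux_network(
      compartments(ids),
      flows(ids[idx[, 1]], ids[idx[, 2]], "other", "lateral", m[idx]),
      provenance = sprintf("generate_network(n=%d, connectance=%g, seed=%d)",
                           n, connectance, seed))
  })
}

#' Toy networks with closed-form indices
#'
#' `generate_ring(n)` builds a unidirectional ring of `n` compartments with
#' equal flows: a single maximally constrained pathway with
#' `AMI = log2(n)` bits and zero redundancy. `generate_uniform(n)` builds the
#' complete network (self-loops included) with equal flows: fully independent
#' routing with `AMI = 0`.
#'
#' @param n Number of compartments (>= 2).
#' @param flow Magnitude of every flow.
#' @return A `flux_network`.
#' @export
generate_ring <- function(n, flow = 1) {
  if (n < 2) stop("n must be >= 2")
  ids <- sprintf("c%02d", seq_len(n))
  flux_network(compartments(ids),
               flows(ids, ids[c(2:n, 1)], "other", "lateral", flow),
               provenance = sprintf("ring(n=%d)", n))
}

#' @rdname generate_ring
#' @export
generate_uniform <- function(n, flow = 1) {
  if (n < 2) stop("n must be >= 2")
  ids <- sprintf("c%02d", seq_len(n))
  g <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  self <- g$source == g$target
  flux_network(compartments(ids),
               flows(g$source, g$target,
                     ifelse(self, "accumulation", "other"),
                     ifelse(self, "internal", "lateral"), flow),
               provenance = sprintf("uniform(n=%d)", n))
}
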