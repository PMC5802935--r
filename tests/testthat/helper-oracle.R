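# Independent brute-force evaluation of the flow-network information indices.
# Deliberately written against the flow records directly (explicit double
# loops over compartment pairs, scalar accumulation), sharing no code with the
# production matrix path.
ena_oracle <- function(network, log_base = 2, k = 1,
                       include_self_loops = TRUE) {
  ids <- network$compartments$id
  fl <- network$flows
  pair_flow <- function(i, j) {
    sel <- fl$source == i & fl$target == j
    if (i == j && !include_self_loops) return(0)
    sum(abs(fl$best[sel]))
  }
  T_ <- 0
  for (i in ids) for (j in ids) T_ <- T_ + pair_flow(i, j)
  t_out <- function(i) { s <- 0; for (j in ids) s <- s + pair_flow(i, j); s }
  t_in <- function(j) { s <- 0; for (i in ids) s <- s + pair_flow(i, j); s }
  ami_ <- 0; asc <- 0; cap <- 0
  for (i in ids) for (j in ids) {
    tij <- pair_flow(i, j)
    if (tij > 0) {
      term <- log(tij * T_ / (t_out(i) * t_in(j)), base = log_base)
      ami_ <- ami_ + (tij / T_) * term
      asc <- asc + tij * term
      cap <- cap - tij * log(tij / T_, base = log_base)
    }
  }
  list(tst = T_, ami = k * ami_, ascendency = asc, capacity = cap,
       redundancy = cap - asc)
}
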