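test_that("closed forms: ring and uniform networks", {
  for (n in 2:8) {
    ring <- generate_ring(n)
    expect_equal(ami(ring), log2(n))
    expect_equal(ascendency(ring), n * log2(n))
    expect_equal(capacity(ring), n * log2(n))
    expect_equal(redundancy(ring), 0)
    expect_equal(ami(generate_uniform(n)), 0)
  }
  # single flow: one pathway, zero information either way
  single <- flux_network(compartments(c("a", "b")),
                         flows("a", "b", "DOC_runoff", "lateral", 5))
  expect_equal(tst(single), 5)
  expect_equal(ascendency(single), 0)
  expect_equal(capacity(single), 0)
  # 2-compartment uniform network: A = 0, so R equals its capacity
  u2 <- generate_uniform(2)
  expect_equal(redundancy(u2), capacity(u2))
})

test_that("tst sums magnitudes, with self-loops configurable", {
  expect_equal(tst(generate_ring(4)), 4)
  empty <- flux_network(compartments(c("a", "b")))
  expect_equal(tst(empty), 0)
  expect_error(ami(empty), "zero")
  meta <- nhld_meta()
  expect_equal(tst(meta) - tst(meta, include_self_loops = FALSE),
               968 + 89 + 17 + 15)
})

test_that("indices match the brute-force oracle on seeded networks", {
  for (seed in 1:25) {
    net <- generate_network(n = 3 + seed %% 5, connectance = 0.5,
                            sigma = 1.5, seed = seed)
    got <- ena_report(net)
    want <- ena_oracle(net)
    expect_equal(got$tst, want$tst, tolerance = 1e-9)
    expect_equal(got$ami, want$ami, tolerance = 1e-9)
    expect_equal(got$ascendency, want$ascendency, tolerance = 1e-9)
    expect_equal(got$capacity, want$capacity, tolerance = 1e-9)
    expect_equal(got$redundancy, want$redundancy, tolerance = 1e-9)
  }
  # parallel processes aggregate per compartment pair before the formulas
  par2 <- flux_network(
    compartments(c("a", "b")),
    flows(c("a", "a"), c("b", "b"), c("DIC_runoff", "DOC_runoff"),
          "lateral", c(2, 3)))
  expect_equal(ami(par2), ena_oracle(par2)$ami)
  expect_equal(ascendency(par2), 0) # still a single pathway once aggregated
  # and on the NHLD meta-ecosystem itself
  meta <- nhld_meta()
  want <- ena_oracle(meta)
  expect_equal(ami(meta), want$ami, tolerance = 1e-12)
  expect_equal(capacity(meta), want$capacity, tolerance = 1e-12)
})

test_that("scale equivariance and permutation invariance", {
  net <- generate_network(6, 0.4, seed = 8)
  scaled <- net
  scaled$flows$best <- scaled$flows$best * 2.75
  expect_equal(tst(scaled), 2.75 * tst(net))
  expect_equal(ami(scaled), ami(net))
  expect_equal(ascendency(scaled), 2.75 * ascendency(net))
  expect_equal(capacity(scaled), 2.75 * capacity(net))
  # relabel compartments: indices unchanged
  perm <- net
  map <- c(c01 = "z9", c02 = "z3", c03 = "z7", c04 = "z1", c05 = "z5",
           c06 = "z2")
  perm$compartments$id <- unname(map[perm$compartments$id])
  perm$flows$source <- unname(map[perm$flows$source])
  perm$flows$target <- unname(map[perm$flows$target])
  perm <- validate_flux_network(perm)
  expect_equal(ami(perm), ami(net))
  expect_equal(capacity(perm), capacity(net))
})

test_that("ascendency is bounded by capacity across random networks", {
  for (seed in 1:60) {
    net <- generate_network(n = 2 + seed %% 7, connectance = 0.6,
                            sigma = 2, seed = 1000 + seed)
    a <- ascendency(net); c_ <- capacity(net)
    expect_gte(a, 0)
    expect_lte(a, c_ + 1e-9)
  }
})

test_that("the report carries consistent indices and ratios", {
  meta <- nhld_meta()
  rep <- ena_report(meta, total_stock = nhld_total_stock())
  expect_equal(rep$ascendency, rep$tst * rep$ami, tolerance = 1e-12)
  expect_equal(rep$redundancy, rep$capacity - rep$ascendency)
  expect_equal(rep$ascendency_ratio + rep$resilience_ratio, 1,
               tolerance = 1e-12)
  expect_equal(rep$activity_ratio, rep$tst / 380050)
  expect_equal(rep$n_flows, 16)
  # ring: maximally constrained, zero resilience
  expect_equal(ena_report(generate_ring(5))$resilience_ratio, 0)
})
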