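test_that("network validation enforces the data-model invariants", {
  comp <- compartments(c("a", "b"))
  expect_s3_class(flux_network(comp), "flux_network")
  expect_equal(nrow(flux_network(comp)$flows), 0)

  # dangling endpoint names the offending flow
  expect_error(
    flux_network(comp, flows("a", "zz", "DOC_runoff", "lateral", 1)),
    "undeclared.*zz", ignore.case = TRUE)
  # duplicate (source, target, process)
  expect_error(
    flux_network(comp, flows(c("a", "a"), c("b", "b"), "DOC_runoff",
                             "lateral", c(1, 2))),
    "duplicate flow")
  # duplicate compartment ids
  expect_error(flux_network(compartments(c("a", "a"))), "duplicate compartment")
  # negative magnitude only for accumulation
  expect_error(
    flux_network(comp, flows("a", "b", "DOC_runoff", "lateral", -1)),
    "accumulation")
  expect_silent(
    flux_network(comp, flows("a", "a", "accumulation", "internal", -1)))
  # self-flows only for storage processes
  expect_error(
    flux_network(comp, flows("a", "a", "GPP", "vertical", 1)),
    "self-flows", ignore.case = TRUE)
  # range bounds ordered around best (negative lows are legal)
  expect_error(
    flux_network(comp, flows("a", "b", "DOC_runoff", "lateral", 1,
                             low = 2, high = 3)),
    "low <= best <= high")
  expect_silent(
    flux_network(comp, flows("a", "b", "DOC_runoff", "lateral", 1,
                             low = -2.2, high = 4.2)))
  # non-positive areas rejected
  expect_error(flux_network(compartments("a", area = 0)), "area")
})

test_that("the NHLD budget encodes as 3 internal compartments and 21 flows", {
  net <- nhld_network()
  expect_equal(length(internal_ids(net)), 3)
  expect_equal(nrow(net$flows), 21)
  expect_setequal(internal_ids(net), c("forest", "wetland", "surface_waters"))
})

test_that("compartment throughput reproduces the per-ecosystem totals", {
  net <- nhld_network()
  expect_equal(compartment_throughput(net, "forest"), 5503.5)
  expect_equal(compartment_throughput(net, "wetland"), 1669.9)
  expect_equal(compartment_throughput(net, "surface_waters"), 113.7)
  # self-flows enter only on request, as absolute magnitudes
  expect_equal(compartment_throughput(net, "surface_waters",
                                      include_self_flows = TRUE),
               113.7 + 17 + 15)
  expect_error(compartment_throughput(net, "nope"), "unknown compartment")
  # compartment with no incident flows
  lonely <- flux_network(compartments(c("a", "b")),
                         flows("a", "a", "accumulation", "internal", 5))
  expect_equal(compartment_throughput(lonely, "b"), 0)
})

test_that("net balance is inflow minus outflow with self-flows excluded", {
  net <- nhld_network()
  # (3233 + 6.2) - (2238 + 10 + 14 + 2.3); the printed accumulation 968
  # instead matches the balance without precipitation (968.7)
  expect_equal(net_balance(net, "forest"), 974.9)
  expect_equal(net_balance(net, "wetland"), 881.2 - 788.7)
  expect_equal(net_balance(net, "surface_waters"), 49.5 - 64.2)
  sym <- flux_network(compartments(c("a", "b")),
                      flows(c("a", "b"), c("b", "a"), "DOC_runoff", "lateral",
                            c(7, 7)))
  expect_equal(net_balance(sym, "a"), 0)
  expect_error(net_balance(net, "nope"), "unknown compartment")
})

test_that("throughput is invariant to relabeling other compartments", {
  net <- nhld_network()
  ref <- compartment_throughput(net, "forest")
  net$compartments$id[net$compartments$id == "wetland"] <- "bog"
  net$flows$source[net$flows$source == "wetland"] <- "bog"
  net$flows$target[net$flows$target == "wetland"] <- "bog"
  expect_equal(compartment_throughput(validate_flux_network(net), "forest"),
               ref)
})

test_that("throughput and balance scale linearly with the flows", {
  for (seed in c(3, 11)) {
    net <- generate_network(5, 0.6, seed = seed)
    scaled <- net
    scaled$flows$best <- scaled$flows$best * 3.5
    for (id in internal_ids(net)) {
      expect_equal(compartment_throughput(scaled, id),
                   3.5 * compartment_throughput(net, id))
      expect_equal(net_balance(scaled, id), 3.5 * net_balance(net, id))
    }
  }
})

test_that("summed internal balances equal net boundary exchange", {
  # conservation bookkeeping: sum of internal net balances = total inflow from
  # exteriors minus total outflow to exteriors
  net <- nhld_network()
  fl <- net$flows[net$flows$source != net$flows$target, ]
  boundary_in <- sum(fl$best[fl$source == "external"])
  boundary_out <- sum(fl$best[fl$target == "external"])
  total <- sum(vapply(internal_ids(net), function(id) net_balance(net, id),
                      numeric(1)))
  expect_equal(total, boundary_in - boundary_out)
})
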