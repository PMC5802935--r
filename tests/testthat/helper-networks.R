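# Toy flagged networks for classification and adjustment tests.

# three internal ecosystems exchanging significant flows, nothing crossing
# the boundary
toy_systemic <- function() {
  net <- flux_network(
    compartments(c("a", "b", "c")),
    flows(c("a", "b", "c"), c("b", "c", "a"), "DOC_runoff", "lateral",
          c(50, 60, 70)))
  flag_significance(net)
}

# three ecosystems with only vertical exchange against an exterior pool
toy_laterally_discrete <- function() {
  net <- flux_network(
    compartments(c("a", "b", "c", "sky"),
                 role = c(rep("internal_ecosystem", 3), "exterior")),
    flows(c("sky", "a", "sky", "b", "sky", "c"),
          c("a", "sky", "b", "sky", "c", "sky"),
          c("GPP", "respiration", "GPP", "respiration", "GPP", "respiration"),
          "vertical", c(100, 80, 90, 70, 60, 50)))
  flag_significance(net)
}

# three isolated ecosystems: storage terms only, no exchange at all
toy_omnidirectional <- function() {
  net <- flux_network(
    compartments(c("a", "b", "c")),
    flows(c("a", "b", "c"), c("a", "b", "c"), "accumulation", "internal",
          c(100, 100, 100)))
  flag_significance(net)
}

# the NHLD pipeline up to each stage, computed once per test file
nhld_flagged <- function() flag_significance(nhld_network())
nhld_meta <- function(spec = exterior_spec()) to_meta_ecosystem(nhld_flagged(),
                                                                spec)
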