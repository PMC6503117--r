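# Shared fixtures: the bundled networks, small toy networks built in code,
# and a closed-form mass-balanced flux generator for the TCA example.

tcaNet <- function() loadFixture("tca")
xylNet <- function() loadFixture("xylose")

# TCA steady state has one net degree of freedom (the AKG split toward
# glutamate) plus the fumarate/oxaloacetate exchange:
#   v1 = v2 = 1, v3 = x, v4 = v5 = 1 - x, v7 = x, v6f = (1 - x) + e, v6b = e
tcaFluxes <- function(x = 0.4, e = 0.2) {
  c(v1 = 1, v2 = 1, v3 = x, v4 = 1 - x, v5 = 1 - x,
    v6f = 1 - x + e, v6b = e, v7 = x)
}

# linear chain A -> B -> C -> D (A is the substrate)
chainNet <- function() parseModel(c(
  "v1: A (a) -> B (a)",
  "v2: B (a) -> C (a)",
  "v3: C (a) -> D (a)"))

# toy condensation: C = A + B, then C -> D export
condNet <- function() parseModel(c(
  "v1: A (ab) + B (cd) -> C (abcd)",
  "v2: C (abcd) -> D (abcd)"))

fullDecompose <- function(net, targets)
  combineEquivalents(reduceUnimolecular(decomposeEMU(net, targets)))

acReadouts <- c("AC_1", "AC_2", "AC_12")
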