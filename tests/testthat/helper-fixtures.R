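# Shared fixtures built in code.

# Fermenter broth at the state-of-the-art digester outlet conditions:
# 20 g/L biomass feed digested at 45 wt% to 9 g/L glucose, fully fermented
# at 0.432 g/g.
reference_broth <- function(flow_L_h = 208.59) {
  stream(flow_L_h, bdo = 9 * 0.432, biomass = 20 * 0.55)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
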