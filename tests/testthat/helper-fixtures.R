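# Shared fixtures built in code.

# Six-sequence POA graph whose fifth backbone base (a C supported by five
# sequences) competes with a parallel A carried by one variant subread that
# also skips the following T: the canonical worked example for the
# topological-cut count [A = 1, C = 5].
worked_example_graph <- function() {
  buildPoa("TAGGCTA",
           c("TAGGCTA", "TAGGCTA", "TAGGCTA", "TAGGCTA", "TAGGAA"))
}

worked_example_calling_node <- function(g) backbone(g)[5]

# small deterministic molecule for io tests
tiny_cohort <- function(n = 2, seed = 5, ...) {
  simulateCohort(n, refLength = 40L, nPasses = 4L, germlineRate = 0.05,
                 seed = seed, ...)
}
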