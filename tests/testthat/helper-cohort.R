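# Small shared fixtures for cohort-level tests. Everything is generated in
# code; nothing is read from disk.

tinyConfig <- function(...) {
  cohortConfig(nPerGroup = c(NC = 6L, TPD = 5L, NTPD = 4L),
               nRois = 24L, nModules = 3L, nVolumes = 80L,
               affectedNodes = 1:4, cerebellumNodes = 21:24,
               seed = 7L, ...)
}

# Cache expensive shared computations across test files within one run.
.fixtureEnv <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureEnv))
    assign(name, force(expr), envir = .fixtureEnv)
  get(name, envir = .fixtureEnv)
}
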