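# Shared fixtures: the bundled base case, loaded once per test run.

base_params <- function() {
  if (is.null(.fixture_env$p)) {
    .fixture_env$p <- load_parameters(
      system.file("extdata", "base_case.yaml", package = "rrmsce"),
      quiet = TRUE
    )
  }
  .fixture_env$p
}

base_case_results <- function() {
  if (is.null(.fixture_env$bc)) {
    .fixture_env$bc <- run_base_case(base_params())
  }
  .fixture_env$bc
}

.fixture_env <- new.env(parent = emptyenv())

# A parameter set with frozen dynamics: no deaths, no EDSS movement, no SPMS
# conversion. Useful for conservation/limit tests.
frozen_params <- function(p = base_params()) {
  p$mortality$female[] <- 0
  p$mortality$male[] <- 0
  support0 <- as.numeric(p$shift$support == 0)
  p$shift$esc <- support0
  p$shift$swi <- support0
  p$shift$off_treatment <- support0
  p$shift$esc_raw <- support0
  p$spms$conversion[] <- 0
  p$spms$progression <- support0
  p
}
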