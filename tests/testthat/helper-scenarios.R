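# Shared scaled-down scenario fixtures, computed once per test run.
# Configurations are fixed study conditions (see the methods vignette):
#  - s1_small: scenario 1 with 64 hippocampal cells, 400 grid cells, 600 s
#    training, 400 s test, with per-cell precession measurement.
#  - s1_hundred: scenario 1 with the full 100-cell hippocampal population,
#    400 grid cells, 2400 s training.
#  - s23: scenario 2 (100 cells, 400 grid + 400 weakly spatial, 1800 s
#    training) and the scenario-3 inactivation derived from it.
.fixture_cache <- new.env(parent = emptyenv())

.fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

get_s1_small <- function() {
  .fixture("s1_small", function() {
    cfg <- scenario_config(1, n_hippocampal = 64, n_grid = 400,
                           train_duration = 600, test_duration = 400,
                           master_seed = 42)
    run_scenario(cfg, measure_precession = TRUE)
  })
}

get_s1_hundred <- function() {
  .fixture("s1_hundred", function() {
    cfg <- scenario_config(1, n_hippocampal = 100, n_grid = 400,
                           train_duration = 2400, test_duration = 400,
                           master_seed = 7)
    run_scenario(cfg)
  })
}

get_s23 <- function() {
  .fixture("s23", function() {
    cfg2 <- scenario_config(2, n_hippocampal = 100, n_grid = 400,
                            n_weak = 400, train_duration = 1800,
                            test_duration = 400, master_seed = 7)
    rep2 <- run_scenario(cfg2)
    cfg3 <- cfg2
    cfg3$scenario <- 3
    rep3 <- run_scenario(cfg3, base = rep2)
    list(rep2 = rep2, rep3 = rep3)
  })
}
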