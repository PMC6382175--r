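# Shared scenario runs: several tests interrogate the same chronograms, so
# each preset is simulated once per test session.
.scenario_cache <- new.env(parent = emptyenv())

cachedScenario <- function(name, overrides = NULL, key = name) {
  if (!exists(key, envir = .scenario_cache)) {
    assign(key, runScenario(name, overrides), envir = .scenario_cache)
  }
  get(key, envir = .scenario_cache)
}

# small fixed mature domain run used by several solver tests
cachedTuringRun <- function() {
  if (!exists("turing_small", envir = .scenario_cache)) {
    cfg <- modelConfig(list(
      growth = list(L0 = 2.6, growth_speed = 0),
      numerics = list(t_end = 200, dt = 0.005, output_stride = 400),
      init = list(mode = "two_bump", all_mature = TRUE),
      mesenchyme = list(enabled = FALSE)
    ))
    assign("turing_small", simulate(cfg, maturation = FALSE),
           envir = .scenario_cache)
  }
  get("turing_small", envir = .scenario_cache)
}
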