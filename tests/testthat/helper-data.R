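# Shared fixtures. Expensive simulated datasets and pipeline runs are
# computed once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# compact dataset for module-level tests
small_cfg <- function(seed = 11L, ...) {
  defaults <- list(seed = seed, genome_length = 20000L,
                   n_planted_hairpins = 6L, depth_per_library = 2e4,
                   n_decoy_tags = 4L, n_decoy_refs = 2L,
                   n_decoy_transcripts = 2L, transcript_length = 600L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_sim <- function() cached("small_sim", simulate_dataset(small_cfg()))

# study-condition datasets for the acceptance suite (default SimConfig with
# the known fraction at the two ends)
accept_sim_frac0 <- function()
  cached("accept_sim_frac0",
         simulate_dataset(sim_config(seed = 42L, n_known_fraction = 0)))

accept_run_frac0 <- function()
  cached("accept_run_frac0",
         run_pipeline(pipeline_config(seed = 42L,
                                      sim = sim_config(seed = 42L,
                                                       n_known_fraction = 0)),
                      data = accept_sim_frac0()))

accept_sim_frac1 <- function()
  cached("accept_sim_frac1",
         simulate_dataset(sim_config(seed = 42L, n_known_fraction = 1)))
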