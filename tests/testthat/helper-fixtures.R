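# Shared fixtures. Ideal-observer runs are the slowest primitive used by
# many tests, so trajectories are cached per schedule seed.
.traj_cache <- new.env(parent = emptyenv())

short_schedule <- function(seed) build_schedule(schedule_config("short", seed = seed))

cached_traj <- function(schedule) {
  key <- paste0("s", schedule$config$seed)
  if (is.null(.traj_cache[[key]])) {
    .traj_cache[[key]] <- run_observer(schedule)
  }
  .traj_cache[[key]]
}

# a played short schedule from a delta-rule agent
played_schedule <- function(seed = 3, alpha = 0.3, beta = 8) {
  s <- short_schedule(seed)
  simulate_agent(agent_spec("delta_rule", alpha = alpha, beta = beta,
                            seed = seed + 1000L), s)
}

# minimal hand-built trials data frame (valid magnitudes)
toy_trials <- function(rewarded, mag_a, choice = NA_character_,
                       condition = "stable") {
  n <- length(rewarded)
  data.frame(
    trial = seq_len(n), rewarded = rewarded, mag_a = mag_a,
    mag_b = 100 - mag_a,
    condition = rep(condition, length.out = n),
    block = 1L, choice = rep(choice, length.out = n),
    stringsAsFactors = FALSE
  )
}
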