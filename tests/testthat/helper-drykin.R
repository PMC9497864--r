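# Shared fixtures, all generated in code.

# A noiseless synthetic run for one study condition.
noiseless_run <- function(temperature = 60, thickness_mm = 4) {
  generate_run(synthetic_config(temperature, thickness_mm, noise_sd = 0))
}

# A small hand-built run: linear water loss, easy to reason about.
toy_run <- function() {
  m0 <- 4
  dry <- 0.2
  mt <- c(4, 3, 2.2, 1.6, 1.2)
  drying_run(
    run_id = "toy", temperature = 60, thickness = 0.004, air_velocity = 1.5,
    initial_load = dry * (1 + m0), dry_mass = dry,
    times = c(0, 30, 60, 90, 120), weights = dry * (1 + mt),
    initial_moisture_db = m0
  )
}
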