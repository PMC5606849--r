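# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_env)) assign(key, build(), .fixture_env)
  get(key, envir = .fixture_env)
}

noiseless_phantom <- function() {
  fixture("phantom0", function() generate_spine_phantom(phantom_spec(noise_sd = 0)))
}

noisy_phantom <- function() {
  fixture("phantom_noisy", function() generate_spine_phantom(phantom_spec()))
}

segmented_phantom <- function() {
  fixture("segmented0", function() {
    ph <- noiseless_phantom()
    run_pipeline(ph$volume, ph$seeds)
  })
}

wt_cohort16 <- function() {
  fixture("wt16", function() simulate_phenome_cohort(16, seed = 101))
}

# two touching cubes joined by a thin bridge, plus the seed that cuts it
bridged_cubes <- function(bridge_half_width = 1) {
  dims <- c(24, 24, 25)
  m <- array(FALSE, dims)
  m[8:17, 8:17, 3:12] <- TRUE    # anterior cube (1000 voxels)
  m[8:17, 8:17, 15:24] <- TRUE   # posterior cube
  ml <- 12 + seq(-bridge_half_width, bridge_half_width)
  m[12, ml, 13:14] <- TRUE       # bridge
  m
}
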