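# Shared fixtures.  The two reference Monte Carlo traces (acute/chronic at
# 1e6 photons) are expensive, so they are computed once per test run on
# first use and cached for every test that needs them.

.fixture_cache <- new.env(parent = emptyenv())

reference_trace <- function(scene, n_photons = 1e6,
                            seed = c(acute = 7, chronic = 8)[[scene]]) {
  key <- paste(scene, n_photons, seed, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- trace_photons(build_scene(scene),
                                           n_photons = n_photons, seed = seed)
  .fixture_cache[[key]]
}

# pure-absorber slab stack for transmission checks (index-matched, so the
# only attenuation is Beer-Lambert absorption)
absorber_stack <- function(mu_a = 2, thickness = 1,
                           emission = "collimated") {
  med <- c(optics_media(),
           list(absorber = optical_medium("absorber", 0, mu_a, 0, 1)))
  build_scene("custom",
              layers = data.frame(medium = "absorber",
                                  thickness = thickness),
              emission = emission, media = med)
}

# hand-built trial-count tensor (unit x trial x 180) for classifier tests
make_counts <- function(counts_array, irradiance = NULL) {
  d <- dim(counts_array)
  trials <- data.frame(trial_id = seq_len(d[2]),
                       onset_s = seq_len(d[2]) * 1.0)
  if (!is.null(irradiance)) trials$irradiance <- irradiance
  dimnames(counts_array) <- list(unit = sprintf("u%03d", seq_len(d[1])),
                                 trial = as.character(trials$trial_id),
                                 bin = NULL)
  structure(list(counts = counts_array, trials = trials,
                 units = dimnames(counts_array)$unit,
                 bin_w = 0.005, pre = 1:40, stim = 41:140, post = 141:180),
            class = "trial_counts")
}

# Poisson-null tensor: homogeneous rate, no stimulus locking
null_counts <- function(n_units, n_trials, rate_hz, seed) {
  withr::with_seed(seed, {
    arr <- array(stats::rpois(n_units * n_trials * 180, rate_hz * 0.005),
                 dim = c(n_units, n_trials, 180))
  })
  make_counts(arr)
}
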