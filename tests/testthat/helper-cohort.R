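# Shared, lazily built cohort fixtures. Building an aligned cohort is the
# expensive step, so tests that only read one reuse a single cached copy.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small noise-free cohort with a 3-latent outcome, fully aligned
small_cohort <- function() {
  cached_fixture("small_cohort", function() {
    truth <- ground_truth(noise_sd = 0)
    synth <- generate_cohort(K = 24, truth = truth, seed = 11,
                             n_theta = 36, n_phi = 48)
    coh <- build_cohort(synth$meshes, synth$outcomes, synth$covariates,
                        n_points = 1200, seed = 11)
    list(synth = synth, cohort = coh)
  })
}

# study-scale cohort for the acceptance suite: K = 66, N = 2000, outcome
# linear in three latents; built once, reused by several criteria
acceptance_cohort <- function(seed = 101) {
  cached_fixture("acceptance_cohort", function() {
    truth <- ground_truth(noise_sd = 0)
    synth <- generate_cohort(K = 66, truth = truth, seed = seed)
    coh <- build_cohort(synth$meshes, synth$outcomes, synth$covariates,
                        n_points = 2000, seed = seed)
    # noisy-outcome sibling: same shapes, noise at 30% of the signal SD
    set.seed(seed + 7)
    y_noisy <- synth$outcomes + rnorm(66, 0, 0.3 * sd(synth$outcomes))
    noisy <- coh
    noisy$outcomes <- y_noisy
    list(synth = synth, cohort = coh, cohort_noisy = noisy)
  })
}
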