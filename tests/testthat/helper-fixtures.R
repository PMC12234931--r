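# Shared fixtures, built once per test session and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a mid-sized uniform kidney phantom on the clinical grid
fixture_kidney <- function() {
  memo("kidney", make_kidney_phantom(100, 16, spacing = 4.42, C0 = 0.5,
                                     lambda = log(2) / 50, kidney_id = "fx"))
}

# noiseless ASCC preset
fixture_model <- function() memo("model", protocol_preset("ASCC"))

# emulated noiseless image series for the fixture kidney
fixture_images <- function() {
  memo("images", {
    ph <- fixture_kidney()
    m <- fixture_model()
    lapply(c(24, 48, 168), function(t) acquire(activity_at(ph, t), m))
  })
}

# small cohort for structural tests
fixture_small_cohort <- function() {
  memo("small_cohort", make_cohort(cohort_spec(n_patients = 3, seed = 11)))
}

# The default-conditions experiment: 18-patient cohort, ASCC with Poisson
# noise, post-filter sigmas 0 and 4 mm. Shared by the acceptance tests;
# computed once.
acceptance_sweep <- function() {
  memo("acceptance_sweep", {
    cohort <- make_cohort(cohort_spec(seed = 1))
    run_sweep(cohort, model = protocol_preset("ASCC", noise = TRUE),
              sv_volumes = c(4, 2, 0.6), n_svs = 1:5, sigmas = c(0, 4),
              seed = 1)
  })
}
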