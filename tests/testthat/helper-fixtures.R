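# Shared fixtures, built once per test run. The effect cohort plants a
# delta = 0.4 multiplicative alteration on 4 cerebellum (down) and
# 3 sensorimotor + 2 occipital (up) nodes of a 30-node atlas.

.fixture_cache <- new.env(parent = emptyenv())

# seeded evaluation that restores the caller's RNG stream
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_atlas <- function() cached_fixture("atlas", atlas_spec(30))

fixture_effect_cohort <- function() {
  cached_fixture("coh_eff", {
    atl <- fixture_atlas()
    # low noise: module tests probe mechanics, so keep the signal strong
    sample_cohort(atl, effect_plan(atl, delta = 0.4),
                  n_group1 = 16, n_group0 = 16, n_timepoints = 120,
                  seed = 42, noise_sd_range = c(0.3, 0.6))
  })
}

fixture_effect_features <- function() {
  cached_fixture("ft_eff", {
    coh <- fixture_effect_cohort()
    panel <- compute_metric_panel(coh, n_random = 8, seed = 42)
    assemble_features(panel, coh$covariates$group)
  })
}

fixture_null_features <- function() {
  cached_fixture("ft_null", {
    atl <- fixture_atlas()
    coh <- sample_cohort(atl, effect_plan(atl, delta = 0),
                         n_group1 = 16, n_group0 = 16, n_timepoints = 120,
                         seed = 43, noise_sd_range = c(0.3, 0.6))
    panel <- compute_metric_panel(coh, n_random = 8, seed = 43)
    assemble_features(panel, coh$covariates$group)
  })
}
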