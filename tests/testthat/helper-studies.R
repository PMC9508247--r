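# Monte-Carlo study runs shared by the acceptance-style tests. Each study
# is computed once per test session and cached; every block then asserts
# against the same runs. Seeds are fixed so the suite is reproducible.

study_env <- new.env(parent = emptyenv())

study_cache <- function(name, fn) {
  if (is.null(study_env[[name]])) study_env[[name]] <- fn()
  study_env[[name]]
}

study_seed <- 20260922L

study_scenario1 <- function() study_cache("s1", function() {
  run_scenario(scenario_config(1), n_sims = 200, n_boot = 1000,
               levels = c(0.95, 0.99), seed = study_seed)
})

study_scenario2 <- function() study_cache("s2", function() {
  run_scenario(scenario_config(2), n_sims = 200, n_boot = 200,
               levels = 0.95, seed = study_seed + 1L)
})

study_scenario3 <- function() study_cache("s3", function() {
  run_scenario(scenario_config(3), n_sims = 200, n_boot = 200,
               levels = 0.95, seed = study_seed + 2L)
})

study_scenario4 <- function() study_cache("s4", function() {
  run_scenario(scenario_config(4), n_sims = 200, n_boot = 0,
               levels = 0.95, seed = study_seed + 3L)
})

study_scenario6 <- function() study_cache("s6", function() {
  run_scenario(scenario_config(6), n_sims = 200, n_boot = 200,
               levels = 0.95, seed = study_seed + 4L)
})

study_misspec2 <- function() study_cache("mis2", function() {
  misspecification_study(scenario_config(2), "leroux", n_sims = 200,
                         n_boot = 200, levels = 0.95, seed = study_seed + 5L)
})

study_selection_areal <- function() study_cache("sel_areal", function() {
  # negative binomial outcomes under the strong CAR copula, matching the
  # model-choice study design
  cfg <- scenario_config(1)
  copula_selection_study(
    cfg$copula,
    candidates = list(copula_spec("car", cfg$domain),
                      copula_spec("leroux", cfg$domain)),
    mspec = marginal_spec("negative_binomial", theta = 3),
    X = cfg$X, beta = cfg$beta,
    n_sims = 200, seed = study_seed + 6L, residual_source = "residuals"
  )
})

study_selection_gp <- function() study_cache("sel_gp", function() {
  cfg <- scenario_config(5)    # Matern nu = 1, phi = 0.1 truth
  copula_selection_study(
    cfg$copula,
    candidates = list(copula_spec("matern", cfg$domain),
                      copula_spec("powered_exponential", cfg$domain)),
    mspec = cfg$mspec, X = cfg$X, beta = cfg$beta,
    n_sims = 200, seed = study_seed + 7L, residual_source = "latent_z"
  )
})

# Monte-Carlo tolerance, in percentage points, for an empirical rate
rate_tol <- function(p_pct, n_sims = 200) {
  p <- p_pct / 100
  100 * 3 * sqrt(p * (1 - p) / n_sims)
}
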