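# Shared fixtures, built in code at test time.

fx_env <- new.env(parent = emptyenv())

# Full-scale study-condition cohorts (40 observers x 2 cultures x 3,600
# trials) with fitted models; computed once and reused across tests.
study_fixture <- function(seed = 20180814L) {
  if (is.null(fx_env$study)) {
    west <- simulate_cohort(40, "western", 3600, seed = seed)
    east <- simulate_cohort(40, "east_asian", 3600, seed = seed + 1L)
    fx_env$study <- list(
      west = west, east = east,
      models_w = fit_cohort(west), models_e = fit_cohort(east))
  }
  fx_env$study
}

# One observer with single-AU templates and no noise: responses are a
# deterministic function of the stimulus AU set.
deterministic_log <- function(n_trials = 3600L, seed = 99L) {
  tmpl <- make_template("western",
                        base_templates = list(pain = 4L, orgasm = 12L),
                        add_prob = 0, drop_prob = 0, lapse_rate = 0,
                        intensity_noise = 0, observer_id = "det",
                        seed = seed)
  withr::with_seed(seed + 1L, simulate_observer(tmpl, n_trials))
}

# Minimal hand-built observer log: one always-active AU whose temporal
# parameters can be planted against the response / intensity.
planted_log <- function(n = 200L, au = 4L, seed = 7L,
                        amplitude = NULL, response = NULL,
                        intensity = NULL) {
  withr::with_seed(seed, {
    catalog <- build_catalog()
    if (is.null(response))
      response <- sample(c("pain", "orgasm"), n, replace = TRUE)
    prof <- facerevcorr:::sample_profiles(n)
    if (!is.null(amplitude)) prof$amplitude <- amplitude
    if (is.null(intensity))
      intensity <- ifelse(response == "other", NA_integer_,
                          sample(1:5, n, replace = TRUE))
    au_matrix <- matrix(0L, n, nrow(catalog),
                        dimnames = list(NULL, au_columns_pub(catalog)))
    au_matrix[, paste0("AU", au)] <- 1L
    structure(list(observer_id = "planted", culture = "western",
                   template = NULL,
                   trials = data.frame(trial_id = seq_len(n),
                                       response = response,
                                       intensity = as.integer(intensity)),
                   au_matrix = au_matrix,
                   profiles = cbind(trial_id = seq_len(n), au_id = au,
                                    prof),
                   catalog = catalog, duration = 2.25),
              class = "observer_log")
  })
}

au_columns_pub <- function(catalog) paste0("AU", catalog$au_id)

# Quick fake expression models carrying only what downstream code needs.
fake_model <- function(id, affect, aus, culture = "western") {
  list(model_id = id, observer_id = id, culture = culture,
       affect = affect, significant_aus = as.integer(aus),
       au_vector = au_set_to_vector(aus))
}
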