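# End-to-end pipeline orchestration -----------------------------------------

#' Build and validate a pipeline configuration
#'
#' One structured object holds every tunable of the simulate -> fit ->
#' analyze chain. Defaults reproduce the study conditions: 40 observers
#' per culture, 3,600 categorization trials each, AU-count masses
#' 0.10/0.30/0.40/0.20 (median 3), match threshold 0.5, lapse 0.05,
#' intensity noise 0.5, per-AU alpha 0.05, 1,000 classifier splits and
#' 1,000 permutation iterations, 10 validation identities.
#'
#' @param seed root seed; per-stage child seeds are derived from it.
#' @param n_observers observers per culture.
#' @param n_trials categorization trials per observer.
#' @param count_probs AU-count distribution over 1..4.
#' @param add_prob,drop_prob template variability, see [make_template()].
#' @param match_threshold,lapse_rate,intensity_noise observer model
#'   parameters.
#' @param alpha per-AU two-tailed significance level.
#' @param n_splits split-half classifier repetitions.
#' @param n_iter permutation / Monte Carlo iterations.
#' @param n_identities validation-task face-identity repetitions.
#' @param n_validation_observers validating observers per culture.
#' @param production_patterns path to a production-pattern JSON, or `NULL`
#'   for the bundled synthetic fixture.
#' @return object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(seed = 1L, n_observers = 40L,
                            n_trials = 3600L,
                            count_probs = c(0.10, 0.30, 0.40, 0.20),
                            add_prob = 0.02, drop_prob = 0.05,
                            match_threshold = 0.5, lapse_rate = 0.05,
                            intensity_noise = 0.5, alpha = 0.05,
                            n_splits = 1000L, n_iter = 1000L,
                            n_identities = 10L,
                            n_validation_observers = 52L,
                            production_patterns = NULL) {
  cfg <- list(seed = as.integer(seed), n_observers = as.integer(n_observers),
              n_trials = as.integer(n_trials),
              count_probs = as.numeric(count_probs),
              add_prob = add_prob, drop_prob = drop_prob,
              match_threshold = match_threshold, lapse_rate = lapse_rate,
              intensity_noise = intensity_noise, alpha = alpha,
              n_splits = as.integer(n_splits), n_iter = as.integer(n_iter),
              n_identities = as.integer(n_identities),
              n_validation_observers = as.integer(n_validation_observers),
              production_patterns = production_patterns)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  for (nm in c("add_prob", "drop_prob", "lapse_rate"))
    stop_if_not_prob(cfg[[nm]], nm)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("`alpha` must lie strictly between 0 and 1")
  if (cfg$match_threshold <= 0 || cfg$match_threshold > 1)
    stop("`match_threshold` must lie in (0, 1]")
  if (length(cfg$count_probs) != 4L || any(cfg$count_probs < 0) ||
      sum(cfg$count_probs) <= 0)
    stop("`count_probs` must be 4 non-negative masses")
  for (nm in c("n_observers", "n_trials", "n_splits", "n_iter",
               "n_identities", "n_validation_observers"))
    if (cfg[[nm]] < 1L) stop(sprintf("`%s` must be at least 1", nm))
  if (cfg$intensity_noise < 0) stop("`intensity_noise` must be >= 0")
  invisible(cfg)
}

#' Write / read a pipeline configuration as JSON (lossless round trip)
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  drop <- vapply(raw, function(x)
    is.null(x) || (is.list(x) && !length(x)), logical(1))
  do.call(pipeline_config, raw[!drop])
}

#' Run the full reverse-correlation analysis chain on synthetic cohorts
#'
#' Stages, in order: simulate both cohorts; fit all expression models;
#' highly-frequent AU detection per culture and affect; split-half
#' Bayesian classification per culture; validation task simulation and
#' per-model d-prime; within-culture pain-vs-orgasm MI with
#' specific/common partition; cross-cultural MI per affect; Hamming
#' nearest-pattern classification against the production patterns with a
#' chi-square test. Every stage draws its seed deterministically from the
#' root seed, and all artifacts (CSV/JSON) are written under `out_dir`
#' together with a JSON run report of the recovery metrics.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param quiet suppress stage messages.
#' @return invisible list with all stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage_seeds <- seed_stream(config$seed, 8L)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  cultures <- c("western", "east_asian")

  say("[simulate] %d observers x %d trials per culture",
      config$n_observers, config$n_trials)
  cohorts <- stats::setNames(lapply(seq_along(cultures), function(i)
    simulate_cohort(config$n_observers, cultures[i],
                    n_trials = config$n_trials,
                    seed = stage_seeds[1] + i,
                    count_probs = config$count_probs,
                    add_prob = config$add_prob,
                    drop_prob = config$drop_prob,
                    match_threshold = config$match_threshold,
                    lapse_rate = config$lapse_rate,
                    intensity_noise = config$intensity_noise)),
    cultures)

  say("[fit] reverse-correlation models, alpha = %g", config$alpha)
  models <- lapply(cohorts, fit_cohort, alpha = config$alpha)
  recovery <- lapply(cultures, function(cu)
    recovery_summary(cohorts[[cu]], models[[cu]]))
  names(recovery) <- cultures

  mats <- lapply(cultures, function(cu) {
    info <- models_info(models[[cu]])
    list(pain = models_matrix(models[[cu]][info$affect == "pain"]),
         orgasm = models_matrix(models[[cu]][info$affect == "orgasm"]))
  })
  names(mats) <- cultures

  say("[frequent] Monte Carlo highly frequent AUs (%d iterations)",
      config$n_iter)
  frequent <- with_seed_if(stage_seeds[2],
    lapply(mats, lapply, highly_frequent, n_iter = config$n_iter))

  say("[bayes] split-half classification (%d splits)", config$n_splits)
  bayes <- with_seed_if(stage_seeds[3], lapply(cultures, function(cu) {
    info <- models_info(models[[cu]])
    split_half_classify(models_matrix(models[[cu]]), info$affect,
                        n_splits = config$n_splits)
  }))
  names(bayes) <- cultures

  say("[dprime] validation task (%d observers, %d identities per culture)",
      config$n_validation_observers, config$n_identities)
  dpr <- with_seed_if(stage_seeds[4], lapply(cultures, function(cu) {
    templates <- lapply(seq_len(config$n_validation_observers), function(i)
      make_template(cu, add_prob = config$add_prob,
                    drop_prob = config$drop_prob,
                    match_threshold = config$match_threshold,
                    lapse_rate = config$lapse_rate,
                    intensity_noise = config$intensity_noise,
                    observer_id = sprintf("val_%s_%02d", cu, i)))
    val <- simulate_validation(models[[cu]], templates,
                               n_identities = config$n_identities)
    validation_dprime(val)
  }))
  names(dpr) <- cultures

  say("[mi] pain vs orgasm MI with max-statistic null")
  mi_within <- with_seed_if(stage_seeds[5], lapply(cultures, function(cu) {
    fa <- frequent[[cu]]$pain$significant_aus
    fb <- frequent[[cu]]$orgasm$significant_aus
    tested <- sort(union(fa, fb))
    if (!length(tested)) {
      say("[mi] %s: no highly frequent AUs at this scale; stage skipped",
          cu)
      return(list(mi = NULL, partition = NULL,
                  note = "no highly frequent AUs"))
    }
    info <- models_info(models[[cu]])
    mi <- maxT_mi_test(models_matrix(models[[cu]]), info$affect, tested,
                       n_iter = config$n_iter)
    list(mi = mi,
         partition = specific_common_partition(mi, fa, fb))
  }))
  names(mi_within) <- cultures

  say("[crossculture] MI over culture labels per affect")
  mi_across <- with_seed_if(stage_seeds[6], lapply(
    c(pain = "pain", orgasm = "orgasm"), function(a)
      tryCatch(
        cross_culture_test(mats$western[[a]], mats$east_asian[[a]],
                           n_iter = config$n_iter,
                           freq_n_iter = config$n_iter),
        error = function(e) {
          say("[crossculture] %s: %s", a, conditionMessage(e))
          NULL
        })))

  say("[production] Hamming nearest-pattern classification")
  patterns <- read_production_patterns(config$production_patterns)
  west_models <- models$western
  production <- nearest_pattern_classify(west_models, patterns)
  prod_chi <- chi_square_2x2(production$confusion)

  info_w <- models_info(west_models)
  venn <- venn_partition(
    majority_set(west_models[info_w$affect == "pain"]),
    majority_set(west_models[info_w$affect == "orgasm"]),
    majority_set(patterns[vapply(patterns, `[[`, character(1),
                                 "affect") == "pain"]),
    majority_set(patterns[vapply(patterns, `[[`, character(1),
                                 "affect") == "orgasm"]))

  report <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_models = vapply(models, length, integer(1)),
    mean_sensitivity = vapply(recovery, function(r)
      mean(r$sensitivity), numeric(1)),
    mean_false_positives = vapply(recovery, function(r)
      mean(r$false_positives), numeric(1)),
    diagonal_posterior = vapply(bayes, function(b)
      mean(diag(b$posterior_matrix)), numeric(1)),
    prop_discriminated = vapply(dpr, function(d)
      mean(d$quadrant == "discriminated"), numeric(1)),
    production_chi_square = prod_chi$statistic,
    production_chi_p = prod_chi$p_value)

  if (!is.null(out_dir)) {
    fp <- function(...) file.path(out_dir, sprintf(...))
    write_config(config, fp("config.json"))
    for (cu in cultures) {
      write_models(models[[cu]], fp("models_%s.json", cu))
      utils::write.csv(recovery[[cu]], fp("recovery_%s.csv", cu),
                       row.names = FALSE)
      utils::write.csv(dpr[[cu]], fp("dprime_%s.csv", cu),
                       row.names = FALSE)
      if (!is.null(mi_within[[cu]]$partition))
        utils::write.csv(mi_within[[cu]]$partition,
                         fp("mi_partition_%s.csv", cu), row.names = FALSE)
    }
    utils::write.csv(production$assignments,
                     fp("production_assignments.csv"), row.names = FALSE)
    jsonlite::write_json(report, fp("run_report.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(list(config = config, cohorts = cohorts, models = models,
                 recovery = recovery, frequent = frequent, bayes = bayes,
                 dprime = dpr, mi_within = mi_within,
                 mi_across = mi_across, production = production,
                 production_chi = prod_chi, venn = venn, report = report))
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        null = "null")
  # small rolling hash; avoids a digest dependency
  sum(utf8ToInt(as.character(s)) *
        (seq_len(nchar(as.character(s))) %% 97 + 1)) %% 1e9
}
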