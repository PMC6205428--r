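# Synthetic observers -------------------------------------------------------

#' Group-level default AU templates per culture
#'
#' Pain is represented by the same face movements in both cultures (brow
#' lowerer AU4, cheek raiser AU6, nose wrinkler AU9, upper lip raiser AU10,
#' lip stretcher AU20). Orgasm differs: Western templates add upper lid
#' raiser (AU5), jaw drop (AU26) and mouth stretch (AU27) to the shared
#' brow raisers (AU1, AU2) and eyes closed (AU43); East Asian templates add
#' lip corner puller (AU12) instead.
#'
#' @param culture `"western"` or `"east_asian"`.
#' @return list with integer elements `pain` and `orgasm`.
#' @export
default_templates <- function(culture = c("western", "east_asian")) {
  culture <- match.arg(culture)
  pain <- c(4L, 6L, 9L, 10L, 20L)
  orgasm <- if (culture == "western") c(1L, 2L, 5L, 26L, 27L, 43L)
            else c(1L, 2L, 12L, 43L)
  list(pain = pain, orgasm = orgasm)
}

#' Create one synthetic observer template
#'
#' Starting from the group-level AU sets for the culture, each base AU is
#' dropped with probability `drop_prob` and each eligible non-template AU is
#' added with probability `add_prob`, modeling idiosyncratic variation
#' around the group representation. At least one AU is always retained per
#' affect, and additions are drawn outside both affects' sets so an
#' observer's pain and orgasm templates never overlap.
#'
#' @param culture `"western"` or `"east_asian"`.
#' @param base_templates list with elements `pain` and `orgasm` (AU ids).
#' @param add_prob probability of adding each eligible non-template AU.
#' @param drop_prob probability of dropping each base AU.
#' @param match_threshold minimum overlap fraction for an affect match.
#' @param lapse_rate probability of a uniformly random response.
#' @param intensity_noise Gaussian SD added to the intensity rating.
#' @param catalog an `au_catalog`.
#' @param observer_id identifier string.
#' @param seed optional integer seed (local to this call).
#' @return an object of class `observer_template`.
#' @export
make_template <- function(culture = c("western", "east_asian"),
                          base_templates = default_templates(culture),
                          add_prob = 0.02, drop_prob = 0.05,
                          match_threshold = 0.5, lapse_rate = 0.05,
                          intensity_noise = 0.5,
                          catalog = build_catalog(),
                          observer_id = "obs1", seed = NULL) {
  culture <- match.arg(culture)
  stop_if_not_prob(add_prob, "add_prob")
  stop_if_not_prob(drop_prob, "drop_prob")
  stop_if_not_prob(lapse_rate, "lapse_rate")
  if (match_threshold <= 0 || match_threshold > 1)
    stop("`match_threshold` must lie in (0, 1]")
  base_p <- as.integer(base_templates$pain)
  base_o <- as.integer(base_templates$orgasm)
  if (!length(base_p) || !length(base_o))
    stop("base templates must be non-empty")
  bad <- setdiff(c(base_p, base_o), catalog$au_id)
  if (length(bad)) stop("base template AUs outside catalog: ",
                        paste(bad, collapse = ", "))
  with_seed_if(seed, {
    noised <- function(base, forbidden) {
      kept <- base[stats::runif(length(base)) >= drop_prob]
      if (!length(kept)) kept <- base[sample.int(length(base), 1L)]
      pool <- setdiff(catalog$au_id, forbidden)
      added <- pool[stats::runif(length(pool)) < add_prob]
      sort(c(kept, added))
    }
    pain_aus <- noised(base_p, union(base_p, base_o))
    orgasm_aus <- noised(base_o, union(union(base_p, base_o), pain_aus))
    structure(list(observer_id = observer_id, culture = culture,
                   pain_aus = pain_aus, orgasm_aus = orgasm_aus,
                   match_threshold = match_threshold,
                   lapse_rate = lapse_rate,
                   intensity_noise = intensity_noise),
              class = "observer_template")
  })
}

#' @export
print.observer_template <- function(x, ...) {
  cat(sprintf("Synthetic observer %s (%s)\n", x$observer_id, x$culture))
  cat("  pain AUs:   ", paste0("AU", x$pain_aus, collapse = " "), "\n")
  cat("  orgasm AUs: ", paste0("AU", x$orgasm_aus, collapse = " "), "\n")
  cat(sprintf("  threshold %.2f, lapse %.2f, intensity noise %.2f\n",
              x$match_threshold, x$lapse_rate, x$intensity_noise))
  invisible(x)
}

# overlap between an active AU set and a template AU set, normalized by the
# smaller of the two set sizes so that a small stimulus fully inside a large
# template (or vice versa) counts as a complete match
overlap_fraction <- function(active, template) {
  if (!length(active) || !length(template)) return(0)
  length(intersect(active, template)) / min(length(active), length(template))
}

#' Simulate one categorization response
#'
#' The observer compares the active AU set with each affect template using
#' the overlap fraction |active n template| / min(|active|, |template|).
#' With probability `lapse_rate` the response is uniform over
#' pain/orgasm/other; otherwise the best-matching affect is chosen if its
#' overlap reaches the match threshold and strictly exceeds the other
#' affect's (ties go to "other"). Intensity is
#' `clamp(round(1 + 4 * mean peak amplitude of matched AUs + noise), 1, 5)`
#' and is absent (`NA`) for "other" responses.
#'
#' @param template an `observer_template`.
#' @param stimulus a `stimulus_spec`.
#' @param seed optional integer seed (local to this call).
#' @return list with elements `response` ("pain", "orgasm" or "other") and
#'   `intensity` (integer 1-5, `NA` for "other").
#' @export
respond <- function(template, stimulus, seed = NULL) {
  with_seed_if(seed, {
    active <- stimulus$au_ids
    o_p <- overlap_fraction(active, template$pain_aus)
    o_o <- overlap_fraction(active, template$orgasm_aus)
    thr <- template$match_threshold
    if (stats::runif(1) < template$lapse_rate) {
      response <- sample(c("pain", "orgasm", "other"), 1L)
    } else if (o_p >= thr && o_p > o_o) {
      response <- "pain"
    } else if (o_o >= thr && o_o > o_p) {
      response <- "orgasm"
    } else {
      response <- "other"
    }
    if (response == "other") {
      list(response = response, intensity = NA_integer_)
    } else {
      tset <- if (response == "pain") template$pain_aus else
        template$orgasm_aus
      m <- stimulus$profiles$au_id %in% tset
      amp <- if (any(m)) mean(stimulus$profiles$amplitude[m]) else
        mean(stimulus$profiles$amplitude)
      val <- 1 + 4 * amp + stats::rnorm(1, 0, template$intensity_noise)
      list(response = response,
           intensity = as.integer(clamp(round(val), 1, 5)))
    }
  })
}

#' Simulate one observer's categorization session
#'
#' Vectorized simulation of `n_trials` reverse-correlation trials for a
#' single observer template; draws from the current RNG stream (wrap in
#' [withr::with_seed()] or use [simulate_cohort()] for reproducibility).
#'
#' @param template an `observer_template`.
#' @param n_trials number of trials.
#' @param catalog an `au_catalog`.
#' @param count_probs AU-count distribution over 1..4.
#' @param duration stimulus duration in seconds.
#' @param ranges temporal parameter ranges.
#' @return an `observer_log`: list with the trial table (`trial_id`,
#'   `response`, `intensity`), the binary trial-by-AU presence matrix, the
#'   long temporal-parameter table and the generating template.
#' @export
simulate_observer <- function(template, n_trials = 3600L,
                              catalog = build_catalog(),
                              count_probs = c(0.10, 0.30, 0.40, 0.20),
                              duration = 2.25,
                              ranges = default_param_ranges(duration)) {
  stopifnot(n_trials >= 1L)
  n_au <- nrow(catalog)
  counts <- sample.int(4L, n_trials, replace = TRUE, prob = count_probs)
  au_idx <- unlist(lapply(counts, function(k) sample.int(n_au, k)),
                   use.names = FALSE)
  trial <- rep.int(seq_len(n_trials), counts)
  prof <- sample_profiles(length(au_idx), ranges)

  pain_pos <- match(template$pain_aus, catalog$au_id)
  org_pos <- match(template$orgasm_aus, catalog$au_id)
  tab_by_trial <- function(mask) tabulate(trial[mask], nbins = n_trials)
  hits_p <- tab_by_trial(au_idx %in% pain_pos)
  hits_o <- tab_by_trial(au_idx %in% org_pos)
  o_p <- hits_p / pmin(counts, length(pain_pos))
  o_o <- hits_o / pmin(counts, length(org_pos))

  thr <- template$match_threshold
  response <- rep("other", n_trials)
  response[o_p >= thr & o_p > o_o] <- "pain"
  response[o_o >= thr & o_o > o_p] <- "orgasm"
  lapse <- stats::runif(n_trials) < template$lapse_rate
  if (any(lapse))
    response[lapse] <- sample(c("pain", "orgasm", "other"), sum(lapse),
                              replace = TRUE)

  # mean peak amplitude of template-matched active AUs (all actives if the
  # match set is empty, which can happen on lapse trials)
  sum_by_trial <- function(mask) {
    s <- numeric(n_trials)
    if (any(mask)) {
      agg <- rowsum(prof$amplitude[mask], trial[mask])
      s[as.integer(rownames(agg))] <- agg[, 1]
    }
    s
  }
  s_p <- sum_by_trial(au_idx %in% pain_pos)
  s_o <- sum_by_trial(au_idx %in% org_pos)
  s_all <- sum_by_trial(rep(TRUE, length(au_idx)))
  mean_amp <- s_all / counts
  ip <- response == "pain" & hits_p > 0
  io <- response == "orgasm" & hits_o > 0
  mean_amp[ip] <- s_p[ip] / hits_p[ip]
  mean_amp[io] <- s_o[io] / hits_o[io]

  intensity <- rep(NA_integer_, n_trials)
  aff <- response != "other"
  if (any(aff)) {
    val <- 1 + 4 * mean_amp[aff] +
      stats::rnorm(sum(aff), 0, template$intensity_noise)
    intensity[aff] <- as.integer(clamp(round(val), 1, 5))
  }

  au_matrix <- matrix(0L, n_trials, n_au,
                      dimnames = list(NULL, au_columns(catalog)))
  au_matrix[cbind(trial, au_idx)] <- 1L

  profiles <- cbind(trial_id = trial, au_id = catalog$au_id[au_idx], prof)
  structure(list(observer_id = template$observer_id,
                 culture = template$culture,
                 template = template,
                 trials = data.frame(trial_id = seq_len(n_trials),
                                     response = response,
                                     intensity = intensity,
                                     stringsAsFactors = FALSE),
                 au_matrix = au_matrix,
                 profiles = profiles,
                 catalog = catalog,
                 duration = duration),
            class = "observer_log")
}

#' @export
print.observer_log <- function(x, ...) {
  tab <- table(factor(x$trials$response,
                      levels = c("pain", "orgasm", "other")))
  cat(sprintf("Observer log %s (%s): %d trials (pain %d, orgasm %d, other %d)\n",
              x$observer_id, x$culture, nrow(x$trials),
              tab["pain"], tab["orgasm"], tab["other"]))
  invisible(x)
}

#' Simulate a cohort of synthetic observers
#'
#' Each observer receives an independent noised template
#' (see [make_template()]) and completes `n_trials` categorization trials
#' of freshly sampled random AU stimuli. Fully reproducible from `seed`.
#'
#' @param n_observers number of observers.
#' @param culture `"western"` or `"east_asian"`.
#' @param n_trials trials per observer.
#' @param seed optional integer seed (local to this call).
#' @param base_templates group-level AU sets, see [default_templates()].
#' @param catalog an `au_catalog`.
#' @param count_probs AU-count distribution over 1..4.
#' @param ... further arguments passed to [make_template()]
#'   (`add_prob`, `drop_prob`, `match_threshold`, `lapse_rate`,
#'   `intensity_noise`).
#' @return list of `observer_log` objects.
#' @export
simulate_cohort <- function(n_observers = 40L,
                            culture = c("western", "east_asian"),
                            n_trials = 3600L, seed = NULL,
                            base_templates = default_templates(culture),
                            catalog = build_catalog(),
                            count_probs = c(0.10, 0.30, 0.40, 0.20), ...) {
  culture <- match.arg(culture)
  if (n_observers < 1L) stop("`n_observers` must be at least 1")
  if (n_trials < 1L) stop("`n_trials` must be at least 1")
  with_seed_if(seed, {
    lapply(seq_len(n_observers), function(i) {
      tmpl <- make_template(culture, base_templates = base_templates,
                            catalog = catalog,
                            observer_id = sprintf("%s_%02d",
                                                  substr(culture, 1, 4), i),
                            ...)
      simulate_observer(tmpl, n_trials = n_trials, catalog = catalog,
                        count_probs = count_probs)
    })
  })
}

#' Simulate the word-matching validation task
#'
#' Each validating observer sees every model displayed on `n_identities`
#' face identities (identity replication is i.i.d. repetition; no identity
#' effect is modeled), once preceded by the matching affect word and once by
#' the mismatching word, so exactly half of the trials are matched. The
#' yes/no answer applies the same overlap rule as the categorization task:
#' yes when the model's AU set overlaps the observer's own template for the
#' cued word at or above the observer's match threshold; with probability
#' `lapse_rate` the answer is uniform.
#'
#' @param models list of fitted `expression_model` objects (or any lists
#'   with elements `model_id`/`observer_id`, `affect` and
#'   `significant_aus`); at least one model per affect.
#' @param observer_templates list of `observer_template` objects for the
#'   validating observers.
#' @param n_identities number of face-identity repetitions per model.
#' @param seed optional integer seed (local to this call).
#' @return data frame with columns `observer_id`, `trial_id`, `word`,
#'   `model_id`, `matched`, `answer`.
#' @export
simulate_validation <- function(models, observer_templates,
                                n_identities = 10L, seed = NULL) {
  if (!length(models)) stop("empty model list")
  affects <- vapply(models, function(m) m$affect, character(1))
  if (!all(c("pain", "orgasm") %in% affects))
    stop("need at least one model per affect")
  ids <- vapply(models, function(m)
    if (!is.null(m$model_id)) m$model_id else
      paste(m$observer_id, m$affect, sep = "_"), character(1))
  sets <- lapply(models, function(m) m$significant_aus)
  with_seed_if(seed, {
    out <- lapply(observer_templates, function(tmpl) {
      stim_model <- rep(seq_along(models), each = n_identities)
      base <- data.frame(model = rep(stim_model, 2L),
                         matched = rep(c(TRUE, FALSE),
                                       each = length(stim_model)))
      base$word <- ifelse(base$matched, affects[base$model],
                          ifelse(affects[base$model] == "pain",
                                 "orgasm", "pain"))
      base <- base[sample.int(nrow(base)), ]
      o <- mapply(function(m, w) {
        tset <- if (w == "pain") tmpl$pain_aus else tmpl$orgasm_aus
        overlap_fraction(sets[[m]], tset)
      }, base$model, base$word)
      answer <- o >= tmpl$match_threshold
      lapse <- stats::runif(nrow(base)) < tmpl$lapse_rate
      answer[lapse] <- stats::runif(sum(lapse)) < 0.5
      data.frame(observer_id = tmpl$observer_id,
                 trial_id = seq_len(nrow(base)),
                 word = base$word,
                 model_id = ids[base$model],
                 matched = base$matched,
                 answer = answer,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
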