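# File dialects: observer logs, models, config ------------------------------

#' Write an observer log to CSV
#'
#' Two files: a wide trials table (`observer_id`, `culture`, `trial_id`,
#' `response`, `intensity`, one `AU<k>` presence column per catalog AU) and
#' a long temporal-parameter companion (`observer_id`, `trial_id`, `au_id`,
#' `onset`, `acceleration`, `amplitude`, `peak`, `sustain`,
#' `deceleration`, `offset`).
#'
#' @param log an `observer_log`.
#' @param trials_path,profiles_path output CSV paths.
#' @export
write_observer_log <- function(log, trials_path, profiles_path) {
  trials <- cbind(observer_id = log$observer_id, culture = log$culture,
                  log$trials, as.data.frame(log$au_matrix))
  utils::write.csv(trials, trials_path, row.names = FALSE)
  prof <- cbind(observer_id = log$observer_id, log$profiles)
  utils::write.csv(prof, profiles_path, row.names = FALSE)
  invisible(trials_path)
}

#' Read an observer log from CSV
#'
#' Inverse of [write_observer_log()]; validates the trial invariants
#' (intensity present exactly on pain/orgasm trials) and reports offending
#' row numbers.
#'
#' @param trials_path,profiles_path CSV paths written by
#'   [write_observer_log()].
#' @param catalog an `au_catalog`.
#' @param duration stimulus duration in seconds.
#' @return an `observer_log` (without a ground-truth template).
#' @export
read_observer_log <- function(trials_path, profiles_path,
                              catalog = build_catalog(),
                              duration = 2.25) {
  trials <- tryCatch(utils::read.csv(trials_path,
                                     stringsAsFactors = FALSE),
                     error = function(e)
                       stop("empty or malformed trials file: ",
                            trials_path, call. = FALSE))
  if (!nrow(trials)) stop("empty trials file: ", trials_path)
  need <- c("observer_id", "culture", "trial_id", "response", "intensity")
  if (!all(need %in% names(trials)))
    stop("trials file misses columns: ",
         paste(setdiff(need, names(trials)), collapse = ", "))
  bad_resp <- which(!trials$response %in% c("pain", "orgasm", "other"))
  if (length(bad_resp))
    stop("invalid response at rows: ",
         paste(utils::head(bad_resp), collapse = ", "))
  bad_int <- which((trials$response == "other" & !is.na(trials$intensity)) |
                     (trials$response != "other" & is.na(trials$intensity)))
  if (length(bad_int))
    stop("intensity must be present exactly on pain/orgasm trials; ",
         "offending rows: ", paste(utils::head(bad_int), collapse = ", "))
  au_cols <- au_columns(catalog)
  if (!all(au_cols %in% names(trials)))
    stop("trials file misses AU presence columns")
  prof <- utils::read.csv(profiles_path, stringsAsFactors = FALSE)
  if (!nrow(prof)) stop("empty profiles file: ", profiles_path)
  pneed <- c("trial_id", "au_id", profile_columns())
  if (!all(pneed %in% names(prof)))
    stop("profiles file misses columns: ",
         paste(setdiff(pneed, names(prof)), collapse = ", "))
  au_matrix <- as.matrix(trials[, au_cols])
  storage.mode(au_matrix) <- "integer"
  rownames(au_matrix) <- NULL
  structure(list(observer_id = as.character(trials$observer_id[1]),
                 culture = as.character(trials$culture[1]),
                 template = NULL,
                 trials = data.frame(trial_id = trials$trial_id,
                                     response = trials$response,
                                     intensity = as.integer(trials$intensity),
                                     stringsAsFactors = FALSE),
                 au_matrix = au_matrix,
                 profiles = prof[, c("trial_id", "au_id",
                                     profile_columns())],
                 catalog = catalog,
                 duration = duration),
            class = "observer_log")
}

#' Export / import expression models as JSON
#'
#' One JSON object per model with the significant AUs, per-AU correlation
#' table, regression coefficients and the high-intensity profile.
#'
#' @param models list of `expression_model` objects.
#' @param path JSON file path.
#' @export
write_models <- function(models, path) {
  out <- lapply(models, function(m) {
    list(model_id = m$model_id, observer_id = m$observer_id,
         culture = m$culture, affect = m$affect,
         significant_aus = m$significant_aus,
         r = m$au_correlations$r, p = m$au_correlations$p,
         au_ids = m$au_correlations$au_id,
         temporal_coefficients = m$temporal_coefficients,
         intensity_gradient = m$intensity_gradient,
         high_intensity_profile = m$high_intensity_profile,
         alpha = m$alpha, temporal_regression = m$temporal_regression,
         notes = m$notes)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_models
#' @param catalog an `au_catalog`.
#' @return `read_models` returns a list of `expression_model` objects.
#' @export
read_models <- function(path, catalog = build_catalog()) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(m) {
    aus <- as.integer(unlist(m$significant_aus))
    as_mat <- function(x) {
      if (is.null(x) || !length(x))
        return(matrix(NA_real_, 0L, 7L,
                      dimnames = list(NULL, profile_columns())))
      rows <- lapply(x, function(r)
        vapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
               numeric(1)))
      mat <- do.call(rbind, rows)
      dimnames(mat) <- list(paste0("AU", aus), profile_columns())
      mat
    }
    structure(list(observer_id = m$observer_id, model_id = m$model_id,
                   culture = m$culture, affect = m$affect,
                   significant_aus = aus,
                   au_vector = au_set_to_vector(aus, catalog),
                   au_correlations = data.frame(
                     au_id = as.integer(unlist(m$au_ids)),
                     r = vapply(m$r, function(v)
                       if (is.null(v)) NA_real_ else as.numeric(v),
                       numeric(1)),
                     p = vapply(m$p, function(v)
                       if (is.null(v)) NA_real_ else as.numeric(v),
                       numeric(1))),
                   temporal_coefficients = as_mat(m$temporal_coefficients),
                   intensity_gradient = as_mat(m$intensity_gradient),
                   high_intensity_profile = as_mat(m$high_intensity_profile),
                   alpha = m$alpha,
                   temporal_regression = m$temporal_regression,
                   notes = as.character(unlist(m$notes))),
              class = "expression_model")
  })
}
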