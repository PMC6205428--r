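# Reverse-correlation model fitting -----------------------------------------

#' Phi (Pearson) correlation between two binary vectors
#'
#' The phi coefficient equals the Pearson correlation of two 0/1 vectors.
#' The two-sided p-value uses the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom; for
#' the trial counts used here this is numerically indistinguishable from
#' exact methods.
#'
#' @param x,y binary (0/1 or logical) vectors of equal length >= 3; both
#'   must be non-constant.
#' @return list with elements `r` and `p`.
#' @examples
#' phi_correlation(c(1, 1, 0, 0), c(1, 1, 0, 0))$r  # 1
#' @export
phi_correlation <- function(x, y) {
  x <- as_binary01(x, "x")
  y <- as_binary01(y, "y")
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant input vector: phi correlation is undefined")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p)
}

# vectorized phi + p over the columns of a binary matrix; constant columns
# give NA
phi_columns <- function(m, y) {
  n <- length(y)
  r <- suppressWarnings(as.vector(stats::cor(m, y)))
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  r1 <- ok & abs(r) >= 1
  p[r1] <- 0
  mid <- ok & !r1
  tval <- r[mid] * sqrt((n - 2) / (1 - r[mid]^2))
  p[mid] <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(r = r, p = p)
}

# OLS slopes of y on the seven temporal parameters; NULL on rank deficiency
ols_slopes <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  q <- qr(X1)
  if (q$rank < ncol(X1)) return(NULL)
  stats::setNames(qr.coef(q, y)[-1], colnames(X))
}

# rows of log$profiles for AU `au_id` restricted to trials in `trial_set`
profile_rows <- function(log, au_id, trial_set) {
  which(log$profiles$au_id == au_id & log$profiles$trial_id %in% trial_set)
}

#' Temporal-dynamics regression for one AU
#'
#' Ordinary least squares of the binary response (pain = 0, orgasm = 1) on
#' the seven temporal parameters, over the retained (pain/orgasm) trials on
#' which the AU was active.
#'
#' @param log an `observer_log`.
#' @param au_id FACS AU id.
#' @param min_trials minimum number of usable trials (default 9, i.e. the
#'   seven parameters plus two).
#' @return named numeric vector of 7 slopes.
#' @export
fit_temporal <- function(log, au_id, min_trials = 9L) {
  keep <- log$trials$trial_id[log$trials$response %in% c("pain", "orgasm")]
  rows <- profile_rows(log, au_id, keep)
  if (length(rows) < min_trials)
    stop(sprintf("AU%d active on only %d retained trials (need >= %d)",
                 au_id, length(rows), min_trials))
  y <- as.integer(log$trials$response[log$profiles$trial_id[rows]] ==
                    "orgasm")
  b <- ols_slopes(log$profiles[rows, profile_columns()], y)
  if (is.null(b)) stop(sprintf("rank-deficient design for AU%d", au_id))
  b
}

#' Intensity-gradient regression for one AU
#'
#' Ordinary least squares of the 1-5 intensity rating on the seven temporal
#' parameters, over trials with the matching affect response on which the
#' AU was active.
#'
#' @inheritParams fit_temporal
#' @param affect `"pain"` or `"orgasm"`.
#' @return named numeric vector of 7 slopes.
#' @export
fit_intensity_gradient <- function(log, au_id,
                                   affect = c("pain", "orgasm"),
                                   min_trials = 9L) {
  affect <- match.arg(affect)
  keep <- log$trials$trial_id[log$trials$response == affect]
  if (!length(keep)) stop("no trials with a ", affect, " response")
  rows <- profile_rows(log, au_id, keep)
  if (length(rows) < min_trials)
    stop(sprintf("AU%d active on only %d %s trials (need >= %d)",
                 au_id, length(rows), affect, min_trials))
  y <- log$trials$intensity[log$profiles$trial_id[rows]]
  b <- ols_slopes(log$profiles[rows, profile_columns()], y)
  if (is.null(b)) stop(sprintf("rank-deficient design for AU%d", au_id))
  b
}

#' High-intensity temporal profile for one AU
#'
#' Element-wise mean of the seven temporal parameters over matching-affect
#' trials rated in the high-intensity band (default ratings 4-5) on which
#' the AU was active. Because every per-trial profile satisfies the timing
#' invariants, so does their mean; a defensive clamp to the stimulus
#' duration is applied anyway.
#'
#' @inheritParams fit_intensity_gradient
#' @param band intensity ratings counted as high intensity.
#' @return named numeric vector of 7 mean parameters.
#' @export
high_intensity_profile <- function(log, au_id,
                                   affect = c("pain", "orgasm"),
                                   band = c(4L, 5L)) {
  affect <- match.arg(affect)
  keep <- log$trials$trial_id[log$trials$response == affect &
                                log$trials$intensity %in% band]
  rows <- profile_rows(log, au_id, keep)
  if (!length(rows))
    stop(sprintf(paste("no high-intensity %s trials with AU%d active;",
                       "consider widening `band`"), affect, au_id))
  prof <- colMeans(log$profiles[rows, profile_columns(), drop = FALSE])
  prof["offset"] <- min(prof["offset"], log$duration)
  prof
}

#' Fit per-observer expression models from a trial log
#'
#' Trials answered "other" are excluded; responses are coded pain = 0,
#' orgasm = 1, and each AU's presence is phi-correlated with the response.
#' AUs with a significant (two-tailed `p < alpha`) negative correlation
#' enter the pain model; significant positive correlations enter the
#' orgasm model, so the two models of one observer never share an AU.
#' For each significant AU the temporal regression (on all retained trials
#' where the AU was active), the intensity-gradient regression and the
#' high-intensity mean profile are then computed; AUs with too few usable
#' trials get `NA` coefficients and are listed in the model's `notes`.
#'
#' @param log an `observer_log`.
#' @param alpha per-AU two-tailed significance level (unadjusted).
#' @param min_trials minimum trials for the per-AU regressions.
#' @param band high-intensity rating band.
#' @return list with elements `pain` and `orgasm`, each an
#'   `expression_model`.
#' @export
fit_models <- function(log, alpha = 0.05, min_trials = 9L,
                       band = c(4L, 5L)) {
  resp <- log$trials$response
  retained <- which(resp %in% c("pain", "orgasm"))
  if (sum(resp == "pain") < 1L) stop("log contains no pain responses")
  if (sum(resp == "orgasm") < 1L) stop("log contains no orgasm responses")
  if (length(retained) < 3L) stop("fewer than 3 usable (pain/orgasm) trials")
  y <- as.integer(resp[retained] == "orgasm")
  M <- log$au_matrix[retained, , drop = FALSE]
  phi <- phi_columns(M, y)
  cat_ids <- log$catalog$au_id
  cors <- data.frame(au_id = cat_ids, r = phi$r, p = phi$p)
  sig <- !is.na(phi$p) & phi$p < alpha
  one_model <- function(affect) {
    keep <- if (affect == "pain") sig & phi$r < 0 else sig & phi$r > 0
    aus <- cat_ids[keep]
    rn <- if (length(aus)) paste0("AU", aus) else NULL
    coefs <- matrix(NA_real_, length(aus), 7L,
                    dimnames = list(rn, profile_columns()))
    grads <- coefs
    hip <- coefs
    notes <- character(0)
    for (i in seq_along(aus)) {
      a <- aus[i]
      tc <- tryCatch(fit_temporal(log, a, min_trials),
                     error = function(e) conditionMessage(e))
      if (is.character(tc)) notes <- c(notes, paste0("temporal: ", tc))
      else coefs[i, ] <- tc
      g <- tryCatch(fit_intensity_gradient(log, a, affect, min_trials),
                    error = function(e) conditionMessage(e))
      if (is.character(g)) notes <- c(notes, paste0("intensity: ", g))
      else grads[i, ] <- g
      h <- tryCatch(high_intensity_profile(log, a, affect, band),
                    error = function(e) conditionMessage(e))
      if (is.character(h)) notes <- c(notes, paste0("profile: ", h))
      else hip[i, ] <- h
    }
    au_vec <- integer(length(cat_ids))
    names(au_vec) <- paste0("AU", cat_ids)
    au_vec[keep] <- 1L
    structure(list(observer_id = log$observer_id,
                   model_id = paste(log$observer_id, affect, sep = "_"),
                   culture = log$culture,
                   affect = affect,
                   significant_aus = aus,
                   au_vector = au_vec,
                   au_correlations = cors,
                   temporal_coefficients = coefs,
                   intensity_gradient = grads,
                   high_intensity_profile = hip,
                   alpha = alpha,
                   temporal_regression = "retained trials with AU active",
                   notes = notes),
              class = "expression_model")
  }
  list(pain = one_model("pain"), orgasm = one_model("orgasm"))
}

#' @export
print.expression_model <- function(x, ...) {
  cat(sprintf("Expression model %s [%s, %s]: %d significant AU(s)\n",
              x$model_id, x$culture, x$affect, length(x$significant_aus)))
  if (length(x$significant_aus))
    cat("  ", paste0("AU", x$significant_aus, collapse = " "), "\n")
  invisible(x)
}

#' Fit expression models for every observer in a cohort
#'
#' @param logs list of `observer_log` objects.
#' @param ... passed to [fit_models()].
#' @return flat list of `expression_model` objects (pain and orgasm model
#'   per observer).
#' @export
fit_cohort <- function(logs, ...) {
  out <- lapply(logs, function(l) {
    m <- fit_models(l, ...)
    list(m$pain, m$orgasm)
  })
  unlist(out, recursive = FALSE)
}

#' Stack expression models into a binary AU matrix
#'
#' @param models list of `expression_model` objects.
#' @return integer matrix (models x AUs) with `AU<k>` column names and
#'   model ids as row names.
#' @export
models_matrix <- function(models) {
  if (!length(models)) stop("empty model list")
  m <- do.call(rbind, lapply(models, function(x) x$au_vector))
  rownames(m) <- vapply(models, function(x) x$model_id, character(1))
  m
}

#' Metadata table for a list of expression models
#'
#' @param models list of `expression_model` objects.
#' @return data frame with columns `model_id`, `observer_id`, `culture`,
#'   `affect`, `n_aus`.
#' @export
models_info <- function(models) {
  data.frame(model_id = vapply(models, `[[`, character(1), "model_id"),
             observer_id = vapply(models, `[[`, character(1),
                                  "observer_id"),
             culture = vapply(models, `[[`, character(1), "culture"),
             affect = vapply(models, `[[`, character(1), "affect"),
             n_aus = vapply(models, function(m)
               length(m$significant_aus), integer(1)),
             stringsAsFactors = FALSE)
}

#' Parameter-recovery summary for a simulated cohort
#'
#' Compares each fitted model's significant AUs with the simulated
#' observer's ground-truth template: sensitivity is the fraction of
#' template AUs recovered, false positives are significant AUs outside the
#' template.
#'
#' @param logs list of `observer_log` objects carrying templates.
#' @param models list of `expression_model` objects fitted from them.
#' @return data frame with one row per model: `model_id`, `affect`,
#'   `n_template`, `n_recovered`, `sensitivity`, `false_positives`.
#' @export
recovery_summary <- function(logs, models) {
  tmpl <- list()
  for (l in logs) {
    tmpl[[paste(l$observer_id, "pain", sep = "_")]] <- l$template$pain_aus
    tmpl[[paste(l$observer_id, "orgasm", sep = "_")]] <-
      l$template$orgasm_aus
  }
  rows <- lapply(models, function(m) {
    truth <- tmpl[[m$model_id]]
    if (is.null(truth)) stop("no template found for model ", m$model_id)
    rec <- intersect(m$significant_aus, truth)
    data.frame(model_id = m$model_id, affect = m$affect,
               n_template = length(truth), n_recovered = length(rec),
               sensitivity = length(rec) / length(truth),
               false_positives = length(setdiff(m$significant_aus, truth)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
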