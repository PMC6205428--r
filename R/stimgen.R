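# Random dynamic AU stimulus generation -------------------------------------

#' Default sampling ranges for the seven temporal parameters
#'
#' Units are seconds except for the dimensionless shape exponents
#' (`acceleration`, `deceleration`) and `amplitude` (activation fraction).
#' `rise` is the sampled gap between onset and peak latency; `min_fall` is
#' the minimum gap between the end of the plateau and the offset. The ranges
#' guarantee that every sampled profile respects
#' 0 <= onset < peak, peak + sustain <= offset <= duration.
#'
#' @param duration stimulus duration in seconds.
#' @return named list of ranges.
#' @export
default_param_ranges <- function(duration = 2.25) {
  list(onset        = c(0, 0.6),
       rise         = c(0.2, 0.8),
       acceleration = c(0.5, 3),
       amplitude    = c(0.2, 1),
       sustain      = c(0, 0.4),
       min_fall     = 0.2,
       deceleration = c(0.5, 3),
       duration     = duration)
}

# vectorized draw of n valid temporal profiles; returns a data.frame with
# the seven canonical columns
sample_profiles <- function(n, ranges = default_param_ranges()) {
  runif2 <- function(r) stats::runif(n, r[1], r[2])
  onset <- runif2(ranges$onset)
  peak <- onset + runif2(ranges$rise)
  sustain <- runif2(ranges$sustain)
  plateau_end <- peak + sustain
  max_fall <- ranges$duration - plateau_end
  if (any(max_fall < ranges$min_fall))
    stop("temporal parameter ranges allow profiles longer than the stimulus")
  offset <- plateau_end + ranges$min_fall +
    stats::runif(n) * (max_fall - ranges$min_fall)
  data.frame(onset = onset,
             acceleration = runif2(ranges$acceleration),
             amplitude = runif2(ranges$amplitude),
             peak = peak,
             sustain = sustain,
             deceleration = runif2(ranges$deceleration),
             offset = offset)
}

profile_columns <- function() {
  c("onset", "acceleration", "amplitude", "peak", "sustain",
    "deceleration", "offset")
}

#' Sample one random dynamic AU stimulus
#'
#' Draws the number of active AUs from `count_probs` over 1..4 (default
#' masses 0.10/0.30/0.40/0.20, median 3), selects that many AUs uniformly
#' without replacement from the catalog, and assigns each an independently
#' sampled temporal activation profile. An optional list of mutually
#' incompatible AU pairs can be supplied to enforce biologically feasible
#' combinations; incompatible draws are rejected and redrawn.
#'
#' @param catalog an `au_catalog`.
#' @param count_probs probabilities of drawing 1, 2, 3 or 4 AUs.
#' @param duration stimulus duration in seconds.
#' @param ranges temporal parameter ranges, see [default_param_ranges()].
#' @param exclusions optional list of length-2 integer vectors of AU ids
#'   that may not co-occur.
#' @param seed optional integer seed (local to this call).
#' @return an object of class `stimulus_spec`: a list with elements
#'   `au_ids` (active AUs, sorted), `au_vector` (named 0/1 vector over the
#'   catalog), `profiles` (data frame, one row per active AU) and
#'   `duration`.
#' @export
sample_stimulus <- function(catalog = build_catalog(),
                            count_probs = c(0.10, 0.30, 0.40, 0.20),
                            duration = 2.25,
                            ranges = default_param_ranges(duration),
                            exclusions = list(),
                            seed = NULL) {
  stopifnot(length(count_probs) == 4L, all(count_probs >= 0),
            sum(count_probs) > 0)
  with_seed_if(seed, {
    k <- sample.int(4L, 1L, prob = count_probs)
    repeat {
      idx <- sort(sample.int(nrow(catalog), k))
      ids <- catalog$au_id[idx]
      ok <- !any(vapply(exclusions,
                        function(p) all(p %in% ids), logical(1)))
      if (ok) break
    }
    prof <- sample_profiles(k, ranges)
    prof <- cbind(au_id = ids, prof)
    structure(list(au_ids = ids,
                   au_vector = au_set_to_vector(ids, catalog),
                   profiles = prof,
                   duration = duration),
              class = "stimulus_spec")
  })
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("Random AU stimulus: %d active AU(s) [%s], duration %.2f s\n",
              length(x$au_ids),
              paste0("AU", x$au_ids, collapse = ", "), x$duration))
  invisible(x)
}

#' Evaluate an AU activation time course
#'
#' The activation rises from zero at `onset` to `amplitude` at `peak` as a
#' power law with exponent `acceleration`, holds the peak for `sustain`
#' seconds, and decays back to zero at the absolute time `offset` as a
#' power law with exponent `deceleration`:
#' \deqn{a(t) = A ((t - t_{on}) / (t_{pk} - t_{on}))^{acc}} on the rise and
#' \deqn{a(t) = A (1 - ((t - t_{pe}) / (t_{off} - t_{pe}))^{dec})} on the
#' decay, where \eqn{t_{pe} = t_{pk} + sustain}.
#'
#' @param profile a named list / one-row data frame with elements `onset`,
#'   `acceleration`, `amplitude`, `peak`, `sustain`, `deceleration`,
#'   `offset`.
#' @param times numeric vector of times in `[0, duration]` seconds.
#' @param duration stimulus duration in seconds.
#' @return numeric vector of activation fractions in `[0, amplitude]`.
#' @export
activation_curve <- function(profile, times, duration = 2.25) {
  p <- as.list(profile)
  if (any(times < 0 | times > duration))
    stop("`times` must lie within [0, duration]")
  if (!(p$onset >= 0 && p$onset < p$peak))
    stop("invalid profile: need 0 <= onset < peak")
  plateau_end <- p$peak + p$sustain
  if (!(plateau_end <= p$offset && p$offset <= duration))
    stop("invalid profile: need peak + sustain <= offset <= duration")
  if (p$acceleration <= 0 || p$deceleration <= 0)
    stop("invalid profile: shape exponents must be positive")
  a <- numeric(length(times))
  rise <- times >= p$onset & times < p$peak
  hold <- times >= p$peak & times <= plateau_end
  fall <- times > plateau_end & times < p$offset
  a[rise] <- p$amplitude *
    ((times[rise] - p$onset) / (p$peak - p$onset))^p$acceleration
  a[hold] <- p$amplitude
  a[fall] <- p$amplitude *
    (1 - ((times[fall] - plateau_end) /
            (p$offset - plateau_end))^p$deceleration)
  a
}

#' Per-frame activation matrix for one stimulus
#'
#' @param stimulus a `stimulus_spec`.
#' @param fps frames per second.
#' @return matrix with one row per frame and one column per active AU;
#'   row names give frame times in seconds.
#' @export
stimulus_timecourse <- function(stimulus, fps = 30) {
  times <- seq(0, stimulus$duration, by = 1 / fps)
  out <- vapply(seq_along(stimulus$au_ids), function(i)
    activation_curve(stimulus$profiles[i, profile_columns()], times,
                     stimulus$duration),
    numeric(length(times)))
  out <- matrix(out, nrow = length(times))
  dimnames(out) <- list(format(times, digits = 4),
                        paste0("AU", stimulus$au_ids))
  out
}

#' Export per-frame activation time courses as CSV
#'
#' Long format: one row per (trial, frame, active AU) with the activation
#' fraction at that frame.
#'
#' @param stimuli list of `stimulus_spec` objects.
#' @param path output CSV path.
#' @param fps frames per second.
#' @export
write_timecourse <- function(stimuli, path, fps = 30) {
  rows <- do.call(rbind, lapply(seq_along(stimuli), function(i) {
    tc <- stimulus_timecourse(stimuli[[i]], fps)
    times <- seq(0, stimuli[[i]]$duration, by = 1 / fps)
    data.frame(trial_id = i,
               time = rep(times, ncol(tc)),
               au_id = rep(stimuli[[i]]$au_ids, each = nrow(tc)),
               activation = as.vector(tc))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Export stimuli as a long CSV (one row per trial x active AU)
#'
#' @param stimuli list of `stimulus_spec` objects.
#' @param path output CSV path.
#' @export
write_stimuli <- function(stimuli, path) {
  rows <- do.call(rbind, lapply(seq_along(stimuli), function(i) {
    pr <- stimuli[[i]]$profiles
    cbind(trial_id = i, pr)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
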