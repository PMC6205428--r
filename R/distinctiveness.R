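# Distinctiveness: Bayesian classification, d-prime, chi-square -------------

#' Train a Bernoulli naive Bayes classifier on binary AU vectors
#'
#' Class-conditional AU presence probabilities use Laplace smoothing:
#' `P(AU = 1 | class) = (count + alpha) / (n_class + 2 * alpha)`; class
#' priors are proportional to class sizes. With `alpha = 0` a probability
#' of exactly 0 or 1 is possible (permitting -Inf log-likelihoods); this is
#' flagged with a warning.
#'
#' @param x binary matrix (items x AUs).
#' @param labels class labels (two or more classes, each non-empty).
#' @param alpha Laplace smoothing constant.
#' @return list with elements `classes`, `theta` (classes x AUs presence
#'   probabilities), `priors` and `alpha`, of class `bernoulli_nb`.
#' @export
train_bernoulli_nb <- function(x, labels, alpha = 1) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (length(labels) != nrow(x))
    stop("`labels` must have one entry per row of `x`")
  if (any(table(labels) == 0L)) stop("empty class in `labels`")
  if (alpha < 0) stop("`alpha` must be non-negative")
  counts <- rowsum(x, labels)
  n_class <- as.vector(table(labels))
  theta <- (counts + alpha) / (n_class + 2 * alpha)
  if (alpha == 0 && any(theta == 0 | theta == 1))
    warning("alpha = 0 with boundary class-conditionals: ",
            "-Inf log-likelihoods are possible")
  structure(list(classes = levels(labels), theta = theta,
                 priors = n_class / length(labels), alpha = alpha),
            class = "bernoulli_nb")
}

#' Posterior class probabilities under a Bernoulli naive Bayes model
#'
#' Bayes' rule with independent Bernoulli likelihoods across AUs, computed
#' in log space and normalized by log-sum-exp.
#'
#' @param fit a `bernoulli_nb` object.
#' @param x binary vector or matrix (items x AUs).
#' @return matrix (items x classes) of posterior probabilities; each row
#'   sums to 1.
#' @export
nb_posterior <- function(fit, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != ncol(fit$theta))
    stop("`x` has a different number of AUs than the trained model")
  loglik <- x %*% t(log(fit$theta)) + (1 - x) %*% t(log(1 - fit$theta))
  loglik <- sweep(loglik, 2L, log(fit$priors), `+`)
  mx <- apply(loglik, 1L, max)
  w <- exp(loglik - mx)
  post <- w / rowSums(w)
  colnames(post) <- fit$classes
  post
}

#' Split-half Bayesian classification of expression models
#'
#' On each of `n_splits` repetitions every class is split into two random
#' halves; the classifier is trained on one half per class and the mean
#' posterior is evaluated on the held-out halves. The posterior matrix and
#' its standard deviation aggregate over repetitions; the SD of per-model
#' mean posteriors across models is reported alongside.
#'
#' @param x binary matrix (models x AUs).
#' @param labels class labels, at least 2 models per class.
#' @param n_splits number of random split repetitions.
#' @param alpha Laplace smoothing constant.
#' @param seed optional integer seed (local to this call).
#' @return object of class `classification_result`: list with
#'   `posterior_matrix` (rows = true class, columns = predicted),
#'   `posterior_sd` (across splits), `posterior_sd_models` (across models),
#'   and `n_splits`.
#' @export
split_half_classify <- function(x, labels, n_splits = 1000L, alpha = 1,
                                seed = NULL) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  cls <- levels(labels)
  idx <- split(seq_len(nrow(x)), labels)
  if (any(vapply(idx, length, integer(1)) < 2L))
    stop("each class needs at least 2 models for a split-half analysis")
  k <- length(cls)
  with_seed_if(seed, {
    sums <- matrix(0, k, k, dimnames = list(cls, cls))
    sq <- sums
    model_sum <- matrix(0, nrow(x), k)
    model_n <- numeric(nrow(x))
    for (s in seq_len(n_splits)) {
      train <- unlist(lapply(idx, function(ii)
        ii[sample.int(length(ii), floor(length(ii) / 2))]),
        use.names = FALSE)
      test <- setdiff(seq_len(nrow(x)), train)
      fit <- train_bernoulli_nb(x[train, , drop = FALSE], labels[train],
                                alpha)
      post <- nb_posterior(fit, x[test, , drop = FALSE])
      post <- post[, cls, drop = FALSE]
      m <- rowsum(post, labels[test]) /
        as.vector(table(labels[test]))
      m <- m[cls, cls, drop = FALSE]
      sums <- sums + m
      sq <- sq + m^2
      model_sum[test, ] <- model_sum[test, ] + post
      model_n[test] <- model_n[test] + 1
    }
    mean_mat <- sums / n_splits
    sd_mat <- sqrt(pmax(sq / n_splits - mean_mat^2, 0) *
                     n_splits / max(n_splits - 1, 1))
    per_model <- model_sum / model_n
    own <- per_model[cbind(seq_len(nrow(x)), match(labels, cls))]
    sd_models <- stats::setNames(
      vapply(cls, function(cl) stats::sd(own[labels == cl]), numeric(1)),
      cls)
    structure(list(posterior_matrix = mean_mat, posterior_sd = sd_mat,
                   posterior_sd_models = sd_models, n_splits = n_splits,
                   alpha = alpha),
              class = "classification_result")
  })
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Split-half Bayesian classification (%d splits)\n",
              x$n_splits))
  cat("Mean posterior (rows = true, cols = predicted):\n")
  print(round(x$posterior_matrix, 4))
  invisible(x)
}

#' Signal-detection sensitivity (d-prime) from a 2x2 response table
#'
#' With the default log-linear correction, 0.5 is added to each cell and 1
#' to each denominator before computing the hit and false-alarm rates, so
#' extreme (0 or 1) rates never occur; `correction = "none"` uses the raw
#' rates. `d' = qnorm(H) - qnorm(F)`. The response quadrant follows the
#' 0.5/0.5 boundaries (high hit & low false alarm = "discriminated"; high &
#' high = "ambiguous"; low & high = "confused"; low & low = "missed");
#' exact ties at 0.5 are assigned to the non-discriminated side.
#'
#' @param hits,misses,false_alarms,correct_rejections non-negative counts.
#' @param correction `"loglinear"` (default) or `"none"`.
#' @return list with `dprime`, `hit_rate`, `fa_rate`, `quadrant` and the
#'   input counts.
#' @examples
#' dprime(10, 10, 10, 10, correction = "none")$dprime  # 0
#' @export
dprime <- function(hits, misses, false_alarms, correct_rejections,
                   correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (hits + misses <= 0 || false_alarms + correct_rejections <= 0)
    stop("zero denominator: need signal and noise trials")
  if (correction == "loglinear") {
    H <- (hits + 0.5) / (hits + misses + 1)
    F <- (false_alarms + 0.5) / (false_alarms + correct_rejections + 1)
  } else {
    H <- hits / (hits + misses)
    F <- false_alarms / (false_alarms + correct_rejections)
  }
  d <- stats::qnorm(H) - stats::qnorm(F)
  quadrant <- if (H > 0.5 && F < 0.5) "discriminated"
  else if (H > 0.5) "ambiguous"
  else if (F >= 0.5) "confused"
  else "missed"
  list(dprime = d, hit_rate = H, fa_rate = F, quadrant = quadrant,
       hits = hits, misses = misses, false_alarms = false_alarms,
       correct_rejections = correct_rejections, correction = correction)
}

#' Per-model d-prime from validation-task responses
#'
#' Pools the yes/no answers of all validating observers per model: hits
#' and misses come from matched trials, false alarms and correct
#' rejections from mismatched trials.
#'
#' @param validation data frame as returned by [simulate_validation()].
#' @param correction passed to [dprime()].
#' @return data frame with one row per model: counts, corrected rates,
#'   `dprime` and `quadrant`, sorted by decreasing `dprime`.
#' @export
validation_dprime <- function(validation, correction = "loglinear") {
  sp <- split(validation, validation$model_id)
  rows <- lapply(sp, function(v) {
    h <- sum(v$matched & v$answer)
    m <- sum(v$matched & !v$answer)
    fa <- sum(!v$matched & v$answer)
    cr <- sum(!v$matched & !v$answer)
    d <- dprime(h, m, fa, cr, correction)
    data.frame(model_id = v$model_id[1], hits = h, misses = m,
               false_alarms = fa, correct_rejections = cr,
               hit_rate = d$hit_rate, fa_rate = d$fa_rate,
               dprime = d$dprime, quadrant = d$quadrant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$dprime), ]
  rownames(out) <- NULL
  out
}

#' Uncorrected Pearson chi-square test on a 2x2 confusion matrix
#'
#' `X^2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 degree of
#' freedom and no continuity correction.
#'
#' @param confusion 2x2 matrix of non-negative counts with all margins
#'   positive.
#' @return list with `statistic`, `df` (1) and `p_value`.
#' @examples
#' chi_square_2x2(matrix(c(35, 5, 5, 35), 2, byrow = TRUE))$statistic # 45
#' @export
chi_square_2x2 <- function(confusion) {
  m <- as.matrix(confusion)
  if (!all(dim(m) == c(2L, 2L))) stop("`confusion` must be 2x2")
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin in confusion matrix")
  n <- sum(m)
  stat <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    prod(rowSums(m), colSums(m))
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, 1L, lower.tail = FALSE))
}
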