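# Frequent-AU detection and mutual-information analyses ---------------------

#' Per-AU frequency across expression models
#'
#' @param x binary matrix (models x AUs) as from [models_matrix()].
#' @return named integer vector of counts (maximum = number of models).
#' @export
au_frequencies <- function(x) {
  x <- as.matrix(x)
  if (!nrow(x)) stop("empty model list")
  counts <- colSums(x)
  storage.mode(counts) <- "integer"
  counts
}

# nearest-rank 95th percentile of a null sample
nearest_rank_95 <- function(v) sort(v)[ceiling(0.95 * length(v))]

#' Detect highly frequent AUs by Monte Carlo simulation
#'
#' The null preserves each model's AU count and redraws its AU positions
#' uniformly at random (`null = "within_model"`, the default, equivalent to
#' permuting AU identity within each model); `null = "marginal"` instead
#' resamples each model's AU count from the empirical count distribution
#' before drawing positions. Each iteration records the maximum per-AU
#' count across all AUs; an AU is flagged (one-tailed p < 0.05,
#' familywise) when its observed count strictly exceeds the nearest-rank
#' 95th percentile of the null maxima.
#'
#' @param x binary matrix (models x AUs).
#' @param n_iter number of Monte Carlo iterations.
#' @param seed optional integer seed (local to this call).
#' @param null null model, see above.
#' @return object of class `freq_result`: list with `counts`,
#'   `null_max`, `threshold_95`, `significant_aus` (AU ids) and metadata.
#' @export
highly_frequent <- function(x, n_iter = 1000L, seed = NULL,
                            null = c("within_model", "marginal")) {
  null <- match.arg(null)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 models")
  if (n_iter < 1L) stop("`n_iter` must be at least 1")
  counts <- au_frequencies(x)
  k <- rowSums(x)
  p <- ncol(x)
  with_seed_if(seed, {
    null_max <- vapply(seq_len(n_iter), function(i) {
      kk <- if (null == "within_model") k else
        k[sample.int(length(k), length(k), replace = TRUE)]
      idx <- unlist(lapply(kk, function(m) sample.int(p, m)),
                    use.names = FALSE)
      max(tabulate(idx, nbins = p))
    }, numeric(1))
    thr <- nearest_rank_95(null_max)
    flagged <- which(counts > thr)
    structure(list(counts = counts, null_max = null_max,
                   threshold_95 = thr,
                   significant_aus = au_ids_from_names(names(counts)[flagged]),
                   n_iter = n_iter, null = null),
              class = "freq_result")
  })
}

au_ids_from_names <- function(nm) as.integer(sub("^AU", "", nm))

#' @export
print.freq_result <- function(x, ...) {
  cat(sprintf("Highly frequent AUs (Monte Carlo, %d iterations, %s null)\n",
              x$n_iter, x$null))
  cat(sprintf("  threshold (null max, 95th pct): %g\n", x$threshold_95))
  cat("  flagged:", if (length(x$significant_aus))
    paste0("AU", x$significant_aus, collapse = " ") else "none", "\n")
  invisible(x)
}

# vectorized plug-in MI (bits) for 2x2 tables given n11 and the margins;
# empty cells contribute 0
mi_from_counts <- function(n11, nx, ny, n) {
  len <- length(n11)
  nx <- rep_len(nx, len)
  ny <- rep_len(ny, len)
  n10 <- nx - n11
  n01 <- ny - n11
  n00 <- n - nx - ny + n11
  term <- function(cell, rx, ry) {
    out <- numeric(len)
    pos <- cell > 0
    out[pos] <- cell[pos] / n * log2(cell[pos] * n / (rx[pos] * ry[pos]))
    out
  }
  nx0 <- n - nx
  ny0 <- n - ny
  term(n11, nx, ny) + term(n10, nx, ny0) +
    term(n01, nx0, ny) + term(n00, nx0, ny0)
}

#' Plug-in mutual information between two binary variables
#'
#' `MI = sum p(x, y) log2( p(x, y) / (p(x) p(y)) )` over the 2x2 joint
#' histogram, with empty cells contributing 0. No bias correction is
#' applied; the estimator is used as an effect-size screen under a
#' permutation null, where the bias cancels. A constant vector gives 0.
#'
#' @param x,y binary (0/1 or logical) vectors of equal length.
#' @return mutual information in bits, in `[0, 1]`.
#' @examples
#' mi_binary(rep(0:1, each = 40), rep(0:1, each = 40))  # 1 bit
#' @export
mi_binary <- function(x, y) {
  x <- as_binary01(x, "x")
  y <- as_binary01(y, "y")
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  mi_from_counts(sum(x == 1 & y == 1), sum(x), sum(y), length(x))
}

# 0/1 label matrix with n_iter columns, each a random relabeling that
# preserves the number of positives
permuted_label_matrix <- function(n, n_pos, n_iter) {
  L <- matrix(0L, n, n_iter)
  pos <- unlist(lapply(seq_len(n_iter), function(i) sample.int(n, n_pos)),
                use.names = FALSE)
  L[cbind(pos, rep(seq_len(n_iter), each = n_pos))] <- 1L
  L
}

#' Max-statistic permutation test on per-AU mutual information
#'
#' Computes the observed MI between each tested AU's presence and the
#' binary label, then builds a familywise null by shuffling the labels
#' `n_iter` times, computing the MI of every tested AU at each iteration
#' and retaining the maximum. The significance threshold is the
#' nearest-rank 95th percentile of the null maxima; AUs whose observed MI
#' strictly exceeds it are flagged (P < 0.05, familywise).
#'
#' @param x binary matrix (models x AUs) with `AU<k>` column names.
#' @param labels two-class label vector (one per model).
#' @param restrict_to AU ids to test (typically the highly frequent AUs).
#' @param n_iter number of permutations.
#' @param seed optional integer seed (local to this call).
#' @return object of class `mi_result`: list with `tested_aus`, `mi_bits`,
#'   `null_max`, `threshold_95`, `significant_aus`, per-class presence
#'   counts and sizes, and metadata.
#' @export
maxT_mi_test <- function(x, labels, restrict_to, n_iter = 1000L,
                         seed = NULL) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (length(labels) != nrow(x))
    stop("`labels` must have one entry per model")
  if (nlevels(labels) != 2L) stop("`labels` must have exactly two classes")
  if (any(table(labels) < 2L)) stop("need at least 2 models per class")
  if (!length(restrict_to)) stop("`restrict_to` must be non-empty")
  if (n_iter < 1L) stop("`n_iter` must be at least 1")
  cols <- match(paste0("AU", restrict_to), colnames(x))
  if (anyNA(cols)) stop("`restrict_to` contains AUs outside the matrix")
  Xr <- x[, cols, drop = FALSE]
  n <- nrow(Xr)
  y <- as.integer(labels == levels(labels)[2L])
  nx <- colSums(Xr)
  ny <- sum(y)
  obs_n11 <- as.vector(crossprod(Xr, y))
  observed <- mi_from_counts(obs_n11, nx, ny, n)
  names(observed) <- paste0("AU", restrict_to)
  with_seed_if(seed, {
    L <- permuted_label_matrix(n, ny, n_iter)
    N11 <- crossprod(Xr, L)                       # tested AUs x n_iter
    MI <- matrix(mi_from_counts(as.vector(N11),
                                rep(nx, times = n_iter),
                                ny, n),
                 nrow = length(cols))
    null_max <- apply(MI, 2L, max)
    thr <- nearest_rank_95(null_max)
    sig <- restrict_to[observed > thr]
    presence <- rowsum(Xr, labels)
    structure(list(tested_aus = restrict_to, mi_bits = observed,
                   null_max = null_max, threshold_95 = thr,
                   significant_aus = sig,
                   presence = presence,
                   class_sizes = as.vector(table(labels)),
                   classes = levels(labels), n_iter = n_iter),
              class = "mi_result")
  })
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("Max-statistic MI permutation test (%s vs %s, %d iterations)\n",
              x$classes[1], x$classes[2], x$n_iter))
  cat(sprintf("  threshold (null max, 95th pct): %.4f bits\n",
              x$threshold_95))
  cat("  significant:", if (length(x$significant_aus))
    paste0("AU", x$significant_aus, collapse = " ") else "none", "\n")
  invisible(x)
}

#' Partition tested AUs into specific / common / unclassified
#'
#' An AU with significantly high MI that is highly frequent in exactly one
#' class is specific to the class with the higher presence rate; an AU with
#' non-significant MI that is highly frequent in both classes is common.
#' Remaining tested AUs are reported as unclassified rather than forced
#' into a category.
#'
#' @param mi an `mi_result` from [maxT_mi_test()].
#' @param freq_A,freq_B AU ids highly frequent in the first / second class.
#' @return data frame with columns `au_id`, `mi_bits`, `significant`,
#'   `role` (`"specific_<class>"`, `"common"` or `"unclassified"`).
#' @export
specific_common_partition <- function(mi, freq_A, freq_B) {
  rate <- sweep(mi$presence, 1L, mi$class_sizes, `/`)
  rows <- lapply(seq_along(mi$tested_aus), function(i) {
    au <- mi$tested_aus[i]
    sig <- au %in% mi$significant_aus
    inA <- au %in% freq_A
    inB <- au %in% freq_B
    col <- paste0("AU", au)
    richer <- mi$classes[which.max(rate[, col])]
    role <- if (sig && xor(inA, inB)) paste0("specific_", richer)
    else if (!sig && inA && inB) "common"
    else "unclassified"
    data.frame(au_id = au, mi_bits = unname(mi$mi_bits[i]),
               significant = sig, role = role, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-cultural MI comparison of expression models for one affect
#'
#' Runs the max-statistic MI permutation machinery with culture as the
#' label. Unless `restrict_to` is given, the tested set is the union of
#' the AUs highly frequent within each culture (each determined by its own
#' Monte Carlo run).
#'
#' @param x1,x2 binary model matrices for the two cultures (same affect).
#' @param cultures length-2 character vector of culture labels.
#' @param restrict_to optional AU ids to test.
#' @param n_iter permutations for the MI test.
#' @param freq_n_iter iterations for the within-culture frequent-AU runs.
#' @param seed optional integer seed (local to this call).
#' @return an `mi_result` (with the tested set recorded).
#' @export
cross_culture_test <- function(x1, x2,
                               cultures = c("western", "east_asian"),
                               restrict_to = NULL, n_iter = 1000L,
                               freq_n_iter = 1000L, seed = NULL) {
  x1 <- as.matrix(x1)
  x2 <- as.matrix(x2)
  if (!nrow(x1) || !nrow(x2))
    stop("both cultures must be represented by at least one model")
  with_seed_if(seed, {
    if (is.null(restrict_to)) {
      f1 <- highly_frequent(x1, n_iter = freq_n_iter)
      f2 <- highly_frequent(x2, n_iter = freq_n_iter)
      restrict_to <- sort(union(f1$significant_aus, f2$significant_aus))
      if (!length(restrict_to))
        stop("no highly frequent AUs in either culture")
    }
    x <- rbind(x1, x2)
    labels <- factor(rep(cultures, c(nrow(x1), nrow(x2))),
                     levels = cultures)
    maxT_mi_test(x, labels, restrict_to, n_iter = n_iter)
  })
}
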