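# Comparison with production-study AU patterns ------------------------------

#' Read production-study AU patterns from JSON
#'
#' The file format is a JSON array of objects
#' `{"study_id": str, "affect": "pain"|"orgasm", "aus": [int]}`. The
#' package ships a default fixture
#' (`inst/extdata/production_patterns_synthetic.json`) of 11 pain and 3
#' orgasm patterns. The fixture is synthetic: the original per-study tables
#' are not publicly deposited, so it was constructed to satisfy the
#' published set-level statements about the production literature (the
#' pain/orgasm majority sets and their intersections); supply your own file
#' to use real per-study patterns.
#'
#' @param path JSON file path; `NULL` loads the bundled synthetic fixture.
#' @param catalog an `au_catalog` used to validate AU ids.
#' @return object of class `production_patterns`: a list of entries with
#'   `study_id`, `affect`, `au_set` and `au_vector`.
#' @export
read_production_patterns <- function(path = NULL,
                                     catalog = build_catalog()) {
  if (is.null(path))
    path <- system.file("extdata", "production_patterns_synthetic.json",
                        package = "facerevcorr", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(raw)) stop("no patterns in ", path)
  pats <- lapply(raw, function(e) {
    if (is.null(e$study_id) || is.null(e$affect) || is.null(e$aus))
      stop("each pattern needs `study_id`, `affect` and `aus`")
    if (!e$affect %in% c("pain", "orgasm"))
      stop("unknown affect: ", e$affect)
    aus <- sort(as.integer(unlist(e$aus)))
    if (!length(aus)) stop("empty AU set in study ", e$study_id)
    list(study_id = e$study_id, affect = e$affect, au_set = aus,
         au_vector = au_set_to_vector(aus, catalog))
  })
  structure(pats, class = "production_patterns")
}

#' @export
print.production_patterns <- function(x, ...) {
  aff <- vapply(x, `[[`, character(1), "affect")
  cat(sprintf("Production AU patterns: %d studies (%d pain, %d orgasm)\n",
              length(x), sum(aff == "pain"), sum(aff == "orgasm")))
  invisible(x)
}

#' Hamming distance between two binary vectors
#'
#' The number of positions at which the two vectors differ.
#'
#' @param u,v binary vectors of equal length.
#' @return non-negative integer.
#' @export
hamming_distance <- function(u, v) {
  u <- as_binary01(u, "u")
  v <- as_binary01(v, "v")
  if (length(u) != length(v)) stop("`u` and `v` must have equal length")
  sum(u != v)
}

#' Classify expression models by nearest production pattern
#'
#' Each model is assigned the affect of its minimum-Hamming-distance
#' production pattern, with distances computed on the full binary AU
#' vectors (absences count). Ties across affects are broken by the
#' majority affect among all tied patterns, then by the smaller mean
#' distance to each affect's full pattern set, and finally (logged) by
#' assigning "pain".
#'
#' @param models list of `expression_model` objects, or a binary matrix
#'   with a matching `info` data frame.
#' @param patterns a `production_patterns` object.
#' @param info optional data frame with `model_id` and `affect` columns
#'   (required when `models` is a matrix).
#' @return list with `assignments` (data frame: `model_id`, `true_affect`,
#'   `assigned`, `min_distance`, `tie_broken`) and `confusion` (2x2 matrix,
#'   rows = true affect, columns = assigned).
#' @export
nearest_pattern_classify <- function(models, patterns, info = NULL) {
  if (!length(models)) stop("empty model list")
  if (!length(patterns)) stop("empty pattern list")
  if (is.matrix(models)) {
    X <- models
    if (is.null(info)) stop("`info` is required when `models` is a matrix")
  } else {
    X <- models_matrix(models)
    info <- models_info(models)
  }
  pat_aff <- vapply(patterns, `[[`, character(1), "affect")
  if (!all(c("pain", "orgasm") %in% pat_aff))
    stop("need at least one production pattern per affect")
  P <- do.call(rbind, lapply(patterns, `[[`, "au_vector"))
  if (ncol(P) != ncol(X))
    stop("models and patterns use different catalogs")
  # |x - p|_H = |x| + |p| - 2 x.p
  D <- outer(rowSums(X), rep(1, nrow(P))) +
    outer(rep(1, nrow(X)), rowSums(P)) - 2 * X %*% t(P)
  assigned <- character(nrow(X))
  tie_broken <- logical(nrow(X))
  mean_d <- cbind(pain = rowMeans(D[, pat_aff == "pain", drop = FALSE]),
                  orgasm = rowMeans(D[, pat_aff == "orgasm", drop = FALSE]))
  for (i in seq_len(nrow(X))) {
    tied <- which(D[i, ] == min(D[i, ]))
    affs <- pat_aff[tied]
    tab <- table(factor(affs, levels = c("pain", "orgasm")))
    if (tab["pain"] != tab["orgasm"]) {
      assigned[i] <- names(which.max(tab))
      tie_broken[i] <- length(unique(affs)) > 1L
    } else if (mean_d[i, "pain"] != mean_d[i, "orgasm"]) {
      assigned[i] <- colnames(mean_d)[which.min(mean_d[i, ])]
      tie_broken[i] <- TRUE
    } else {
      assigned[i] <- "pain"
      tie_broken[i] <- TRUE
      message("unresolvable affect tie for model ", info$model_id[i],
              "; assigned pain")
    }
  }
  assignments <- data.frame(model_id = info$model_id,
                            true_affect = info$affect,
                            assigned = assigned,
                            min_distance = apply(D, 1L, min),
                            tie_broken = tie_broken,
                            stringsAsFactors = FALSE)
  confusion <- table(factor(info$affect, levels = c("pain", "orgasm")),
                     factor(assigned, levels = c("pain", "orgasm")))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("true", "assigned")
  list(assignments = assignments, confusion = confusion)
}

#' Majority AU set of a collection of patterns or models
#'
#' AUs present in strictly more than half of the items.
#'
#' @param x binary matrix (items x AUs), a list of AU-id vectors, a list of
#'   `expression_model` objects, or a `production_patterns` object.
#' @return sorted integer vector of AU ids.
#' @export
majority_set <- function(x) {
  if (is.matrix(x)) {
    if (!nrow(x)) stop("empty collection")
    counts <- colSums(x)
    return(sort(au_ids_from_names(names(counts)[counts > nrow(x) / 2])))
  }
  if (!length(x)) stop("empty collection")
  sets <- lapply(x, function(e) {
    if (is.numeric(e)) as.integer(e)
    else if (!is.null(e$au_set)) e$au_set
    else if (!is.null(e$significant_aus)) e$significant_aus
    else stop("cannot extract an AU set from the collection")
  })
  all_aus <- sort(unique(unlist(sets)))
  counts <- vapply(all_aus, function(a)
    sum(vapply(sets, function(s) a %in% s, logical(1))), integer(1))
  all_aus[counts > length(sets) / 2]
}

venn_set_names <- c("model_pain", "model_orgasm", "prod_pain", "prod_orgasm")

#' Four-set Venn partition of AU sets
#'
#' Decomposes the union of the four AU sets (model/production x
#' pain/orgasm) into the 15 disjoint non-empty membership regions of a
#' four-set Venn diagram. Region names join the member sets with `&`,
#' e.g. `"model_pain&prod_pain"`.
#'
#' @param model_pain,model_orgasm,prod_pain,prod_orgasm AU-id vectors.
#' @return object of class `venn_partition`: list with `regions` (named
#'   list over all 15 membership keys, possibly empty) and `sets` (the
#'   inputs).
#' @export
venn_partition <- function(model_pain, model_orgasm, prod_pain,
                           prod_orgasm) {
  sets <- list(model_pain = sort(unique(as.integer(model_pain))),
               model_orgasm = sort(unique(as.integer(model_orgasm))),
               prod_pain = sort(unique(as.integer(prod_pain))),
               prod_orgasm = sort(unique(as.integer(prod_orgasm))))
  keys <- unlist(lapply(1:4, function(k)
    utils::combn(venn_set_names, k, paste, collapse = "&")))
  regions <- stats::setNames(rep(list(integer(0)), length(keys)), keys)
  for (au in sort(unique(unlist(sets)))) {
    members <- venn_set_names[vapply(sets, function(s) au %in% s,
                                     logical(1))]
    key <- paste(members, collapse = "&")
    regions[[key]] <- c(regions[[key]], au)
  }
  structure(list(regions = regions, sets = sets),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Four-set AU Venn partition (non-empty regions):\n")
  for (k in names(x$regions)) {
    if (length(x$regions[[k]]))
      cat(sprintf("  %-55s %s\n", k,
                  paste0("AU", x$regions[[k]], collapse = " ")))
  }
  invisible(x)
}

#' Query a Venn partition for AUs inside some sets and outside others
#'
#' Convenience accessor: `venn_overlap(vp, c("model_pain", "prod_pain"))`
#' gives the plain intersection of the two sets;
#' `venn_overlap(vp, "model_pain", setdiff(venn_set_names, "model_pain"))`
#' gives the AUs exclusive to the pain models.
#'
#' @param vp a `venn_partition`.
#' @param within set names the AUs must belong to.
#' @param without set names the AUs must not belong to (default none).
#' @return sorted integer vector of AU ids.
#' @export
venn_overlap <- function(vp, within, without = character(0)) {
  stopifnot(all(c(within, without) %in% venn_set_names))
  inside <- Reduce(intersect, vp$sets[within])
  if (length(without))
    inside <- setdiff(inside, unlist(vp$sets[without]))
  sort(inside)
}
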