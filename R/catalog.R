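# Action-unit catalog -------------------------------------------------------

# The default working set of 42 FACS action units. Codes follow the standard
# FACS numbering; names are the conventional descriptors.
.default_au_entries <- data.frame(
  au_id = c(1L, 2L, 4L, 5L, 6L, 7L, 9L, 10L, 11L, 12L,
            13L, 14L, 15L, 16L, 17L, 18L, 20L, 21L, 22L, 23L,
            24L, 25L, 26L, 27L, 28L, 29L, 30L, 31L, 32L, 33L,
            34L, 35L, 36L, 37L, 38L, 39L, 41L, 42L, 43L, 44L,
            45L, 46L),
  au_name = c("inner brow raiser", "outer brow raiser", "brow lowerer",
              "upper lid raiser", "cheek raiser", "lid tightener",
              "nose wrinkler", "upper lip raiser", "nasolabial deepener",
              "lip corner puller", "sharp lip puller", "dimpler",
              "lip corner depressor", "lower lip depressor", "chin raiser",
              "lip pucker", "lip stretcher", "neck tightener",
              "lip funneler", "lip tightener", "lip pressor", "lips part",
              "jaw drop", "mouth stretch", "lip suck", "jaw thrust",
              "jaw sideways", "jaw clencher", "lip bite", "cheek blow",
              "cheek puff", "cheek suck", "tongue bulge", "lip wipe",
              "nostril dilator", "nostril compressor", "lid droop", "slit",
              "eyes closed", "squint", "blink", "wink"),
  stringsAsFactors = FALSE
)

#' Build an action-unit catalog
#'
#' The catalog enumerates the facial action units (AUs) available to the
#' stimulus generator. The default is the core working set of 42 FACS AUs.
#' A custom catalog may be supplied as a data frame with columns `au_id`
#' (integer FACS codes, unique and sorted ascending) and `au_name`.
#'
#' @param entries optional data frame with columns `au_id` and `au_name`.
#'   When `NULL`, the default 42-AU catalog is returned.
#' @return an object of class `au_catalog`: a data frame with columns
#'   `au_id` and `au_name`.
#' @examples
#' cat42 <- build_catalog()
#' nrow(cat42)  # 42
#' @export
build_catalog <- function(entries = NULL) {
  if (is.null(entries)) {
    entries <- .default_au_entries
    if (nrow(entries) != 42L)
      stop("internal error: default catalog must have 42 entries")
  } else {
    entries <- as.data.frame(entries, stringsAsFactors = FALSE)
    if (!all(c("au_id", "au_name") %in% names(entries)))
      stop("custom catalog needs columns `au_id` and `au_name`")
    entries$au_id <- as.integer(entries$au_id)
    if (nrow(entries) < 1L) stop("catalog must contain at least one AU")
    if (anyDuplicated(entries$au_id))
      stop("duplicate AU ids in custom catalog")
    if (is.unsorted(entries$au_id, strictly = TRUE))
      stop("AU ids must be sorted in ascending order")
    entries <- entries[, c("au_id", "au_name")]
  }
  rownames(entries) <- NULL
  class(entries) <- c("au_catalog", "data.frame")
  entries
}

#' @export
print.au_catalog <- function(x, ...) {
  cat(sprintf("Action-unit catalog: %d AUs (AU%d..AU%d)\n",
              nrow(x), min(x$au_id), max(x$au_id)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more AUs\n", nrow(x) - 6L))
  invisible(x)
}

au_columns <- function(catalog) paste0("AU", catalog$au_id)

#' Convert a set of AU ids to a binary vector over a catalog
#'
#' @param aus integer vector of FACS AU ids.
#' @param catalog an `au_catalog`.
#' @return named integer 0/1 vector, one element per catalog AU.
#' @export
au_set_to_vector <- function(aus, catalog = build_catalog()) {
  aus <- as.integer(aus)
  bad <- setdiff(aus, catalog$au_id)
  if (length(bad))
    stop("unknown AU ids: ", paste(bad, collapse = ", "))
  v <- integer(nrow(catalog))
  names(v) <- au_columns(catalog)
  v[match(aus, catalog$au_id)] <- 1L
  v
}

#' Write / read a catalog as JSON
#'
#' @param catalog an `au_catalog`.
#' @param path file path.
#' @return `read_catalog` returns an `au_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  jsonlite::write_json(as.data.frame(catalog), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  build_catalog(jsonlite::fromJSON(path))
}
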