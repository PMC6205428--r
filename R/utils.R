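# internal helpers shared across modules

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression under a local random seed
#'
#' If `seed` is `NULL` the expression runs under the current RNG stream;
#' otherwise the global RNG state is saved, the seed set, and the state
#' restored afterwards.
#' @noRd
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Derive deterministic child seeds from a root seed
#'
#' Every pipeline stage draws its own seed from the root so that stages can
#' be re-run in isolation and the whole run is reproducible from one integer.
#'
#' @param root integer root seed.
#' @param n number of child seeds to draw.
#' @return integer vector of length `n`, all below 2^31.
#' @export
seed_stream <- function(root, n) {
  stopifnot(is.numeric(root), length(root) == 1L, n >= 1L)
  withr::with_seed(as.integer(root), sample.int(2147483646L, n))
}

stop_if_not_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

is_binary <- function(x) {
  is.numeric(x) || is.logical(x)
}

as_binary01 <- function(x, name = deparse(substitute(x))) {
  x <- as.numeric(x)
  if (anyNA(x) || any(x != 0 & x != 1))
    stop(sprintf("`%s` must be a binary (0/1) vector without NAs", name),
         call. = FALSE)
  x
}
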