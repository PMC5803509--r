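# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a locally-seeded RNG, restoring the caller's state.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Scale a vector to unit Euclidean norm.
#' @keywords internal
unit_norm <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot normalize a zero vector")
  x / nrm
}

#' Column z-scoring; columns with standard deviation below `eps` are zeroed.
#' Returns the scaled matrix with attributes `center`, `scale` and
#' `constant` (logical vector of zeroed columns).
#' @keywords internal
zscore_cols <- function(m, eps = 1e-12) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  const <- !is.finite(sd) | sd < eps
  sd_safe <- ifelse(const, 1, sd)
  out <- sweep(sweep(m, 2L, mu, "-"), 2L, sd_safe, "/")
  out[, const] <- 0
  attr(out, "center") <- mu
  attr(out, "scale") <- sd_safe
  attr(out, "constant") <- const
  out
}

#' @keywords internal
assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

#' Write a data frame as TSV with fixed conventions (no quoting, no rownames).
#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @keywords internal
read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "", ...)
}
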