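#' @keywords internal
#' @useDynLib beamconn, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Derive a reproducible sub-stream seed
#'
#' One master seed per simulation/experiment; every internal source of
#' randomness (source draw, noise draw, dipole selection, subsample draws)
#' gets its own deterministic sub-seed so that components can be re-run in
#' isolation. Kept below 2^31 - 1.
#'
#' @param master integer master seed
#' @param offset integer stream offset (distinct per consumer)
#' @return an integer seed
#' @export
derive_seed <- function(master, offset) {
  s <- (abs(as.double(master)) %% 1e9) * 131 + as.double(offset) * 7919 + 17
  as.integer(s %% 2147483629)
}

# run expr with a local RNG state seeded by `seed`, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# scalar numeric check
chk_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}

# Euclidean norms of matrix rows
row_norms <- function(m) sqrt(rowSums(m^2))

# pairwise Euclidean distance matrix between rows of a and rows of b
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# round half away from zero (0.5 -> 1), used for printed edge counts
round_half_up <- function(x) floor(x + 0.5)
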