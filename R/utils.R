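# internal helpers shared across modules

#' Run code with a fixed RNG seed, restoring the caller's RNG state
#'
#' All generators route their randomness through this so that the global RNG
#' stream of the session is never disturbed and fixed seeds give bit-identical
#' output.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, name) {
  if (!all(is.finite(x)))
    stop("'", name, "' contains non-finite values", call. = FALSE)
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Standard chance-corrected agreement between two partitions of the same
#' items; 1 for identical partitions, ~0 for independent ones. Unassigned
#' items (label 0 / NA) are treated as singleton classes of their own so that
#' leaving a planted singleton unclustered does not count against recovery.
#'
#' @param a,b integer or character label vectors of equal length
#' @return numeric scalar in [-1, 1]
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  a <- as.character(a); b <- as.character(b)
  a[is.na(a) | a == "0"] <- paste0(".sa", seq_along(a))[is.na(a) | a == "0"]
  b[is.na(b) | b == "0"] <- paste0(".sb", seq_along(b))[is.na(b) | b == "0"]
  tab <- table(a, b)
  comb2 <- function(x) sum(x * (x - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab)); sum_b <- comb2(colSums(tab))
  n <- length(a); total <- n * (n - 1) / 2
  expected <- sum_a * sum_b / total
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions all-singletons or identical trivially
  (sum_ij - expected) / (maxi - expected)
}
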