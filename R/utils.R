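#' @importFrom stats kmeans cor sd setNames
#' @importFrom utils head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a fixed RNG state
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic substream derivation: mixes a master seed with a unit index
# into a new seed below 2^31. Arithmetic stays within the exact double range.
derive_seed <- function(master_seed, index) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(master_seed) %% m) + 1
  i <- as.numeric(index) %% m
  v <- (s * 48271) %% m
  v <- (v + i * 16807) %% m
  v <- (v * 69621) %% m
  as.integer(v)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label names), about 0 for independent
#' ones.
#'
#' @param a,b Integer label vectors of equal length.
#' @return A single number, at most 1.
#' @export
#' @examples
#' ari(c(1, 1, 2, 2), c(2, 2, 1, 1))
ari <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

# Hostname for run logs; falls back to "localhost" on restricted systems.
host_name <- function() {
  h <- tryCatch(Sys.info()[["nodename"]], error = function(e) NULL)
  if (is.null(h) || !nzchar(h)) "localhost" else h
}
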