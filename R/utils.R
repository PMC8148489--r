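#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
# All seeded entry points funnel through here so no exported function
# perturbs (or depends on) the global random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Seeded k-fold partition: a shuffled 1..n chopped into k near-equal folds.
# Returns an integer vector of fold labels (1..k), one per sample.
make_folds <- function(n, k, seed = NULL) {
  stopifnot(k >= 2, k <= n)
  with_seed(seed, {
    idx <- sample.int(n)
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    folds <- integer(n)
    folds[idx] <- rep(seq_len(k), times = sizes)
    folds
  })
}

# Number of set bits in a non-negative integer < 2^31.
popcount32 <- function(x) {
  n <- 0L
  while (x > 0) {
    n <- n + (x %% 2L)
    x <- x %/% 2L
  }
  n
}

#' Two-level orthogonal array
#'
#' Builds a two-level orthogonal array with `2^ceiling(log2(n_factors + 1))`
#' runs and `n_factors` columns by the standard Hadamard parity
#' construction: entry (i, j) is the parity of `popcount((i-1) AND j)`.
#' Levels are coded 1 and 2; every column is balanced and every pair of
#' columns orthogonal. Row 1 is all level 1.
#'
#' @param n_factors number of factor columns (>= 1)
#' @return integer matrix of 1/2 levels, runs in rows
#' @export
oa_two_level <- function(n_factors) {
  stopifnot(n_factors >= 1)
  q <- ceiling(log2(n_factors + 1))
  n_runs <- 2L^q
  M <- matrix(1L, n_runs, n_factors)
  for (i in seq_len(n_runs)) {
    for (j in seq_len(n_factors)) {
      M[i, j] <- popcount32(bitwAnd(i - 1L, j)) %% 2L + 1L
    }
  }
  M
}

# Lexicographic fitness comparison used everywhere a "better" individual is
# needed: higher CC wins; ties broken by lower MAE; remaining ties by the
# caller's first-seen order.
fitness_better <- function(a, b) {
  if (a$cc != b$cc) return(a$cc > b$cc)
  a$mae_years < b$mae_years
}

# index of the best fitness in a list, first-seen order breaking ties
which_best <- function(fitnesses) {
  best <- 1L
  for (i in seq_along(fitnesses)[-1]) {
    if (fitness_better(fitnesses[[i]], fitnesses[[best]])) best <- i
  }
  best
}
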