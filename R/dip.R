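#' Dip statistic of unimodality
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical distribution function and any unimodal distribution function
#' (convex to the left of a mode, concave to its right, an atom at the mode
#' allowed).  It is computed by bisection over the distance d, checking at
#' each d whether the per-knot bands `[i/n - d, (i-1)/n + d]` admit a
#' convex-prefix/concave-suffix interpolant (greatest-convex-minorant
#' feasibility, in compiled code).  The dip is bounded below by 1/(2n) and
#' approaches 1/4 for two well-separated half point-masses.
#'
#' @param samples numeric vector, at least 4 values.
#' @return the dip statistic, a scalar between 1/(2n) and 1/4.
#' @seealso [dipTest()] for the calibrated test.
#' @export
dipStatistic <- function(samples) {
  if (length(samples) < 4L) stop("dip statistic needs >= 4 samples")
  if (any(!is.finite(samples))) stop("samples must be finite")
  .dipStatC(as.numeric(samples))
}

# null dip distributions are cached per (n, nBoot, seed): every 100-reading
# entry shares one reference table, so screening a long stream costs one
# bootstrap, not one per entry
.dipNullCache <- new.env(parent = emptyenv())

.dipNullTable <- function(n, nBoot, seed) {
  key <- paste(n, nBoot, seed, sep = "_")
  tab <- .dipNullCache[[key]]
  if (is.null(tab)) {
    tab <- withSeed(seed, .dipNullC(n, nBoot))
    .dipNullCache[[key]] <- tab
  }
  tab
}

#' Dip test of unimodality
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution.  The p-value is calibrated by parametric bootstrap against
#' the uniform(0, 1) null -- the classical conservative reference for the
#' dip -- using `nBoot` replicates of the same sample size.  Null tables
#' are cached per (n, nBoot, seed), so screening many same-sized data
#' entries reuses one bootstrap.
#'
#' @param samples at least 10 numeric values.
#' @param nBoot number of bootstrap null replicates (default 500).
#' @param seed integer seed for the null table (default 1); the caller's
#'   RNG state is left untouched.
#' @return list with elements `statistic` (the dip) and `p.value`.
#' @examples
#' dipTest(rnorm(200))$p.value                    # large: unimodal
#' dipTest(c(rnorm(100), rnorm(100, 100)))$p.value  # < 0.01: two modes
#' @export
dipTest <- function(samples, nBoot = 500L, seed = 1L) {
  if (length(samples) < 10L)
    stop("insufficient data: dip test needs >= 10 samples")
  d <- dipStatistic(samples)
  tab <- .dipNullTable(length(samples), as.integer(nBoot),
                       as.integer(seed))
  list(statistic = d,
       p.value = (1 + sum(tab >= d)) / (length(tab) + 1))
}

# evaluate expr under a temporary RNG seed, restoring the caller's state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
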