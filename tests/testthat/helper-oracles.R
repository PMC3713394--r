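# Independent oracles used across the suite.

# Dip statistic by the chord-minimum envelope characterization, written
# independently of the package's incremental-hull implementation: the
# convex envelope of the upper bounds is evaluated as the minimum over all
# chords spanning each knot, prefix feasibility is found by binary search,
# and the dip by bisection over the band half-width.
oracleDip <- function(x, iters = 40L) {
  x <- sort(x)
  n <- length(x)
  ux <- unique(x)
  m <- length(ux)
  first <- match(ux, x)
  last <- n + 1L - match(ux, rev(x))
  Llev <- last / n
  Ulev <- (first - 1) / n

  envAt <- function(xx, UU, i) {
    jmax <- length(xx)
    v <- UU[i]
    for (p in seq_len(i)) {
      qs <- seq(i, jmax)
      qs <- qs[qs > p]
      if (length(qs))
        v <- min(v, UU[p] + (UU[qs] - UU[p]) *
                   (xx[i] - xx[p]) / (xx[qs] - xx[p]))
    }
    v
  }
  convexFeasible <- function(xx, LL, UU) {
    if (any(LL > UU + 1e-12)) return(FALSE)
    for (i in seq_along(xx))
      if (envAt(xx, UU, i) < LL[i] - 1e-12) return(FALSE)
    TRUE
  }
  maxPrefix <- function(xx, LL, UU) {
    lo <- 0L; hi <- length(xx)
    while (lo < hi) {
      mid <- as.integer(ceiling((lo + hi) / 2))
      if (convexFeasible(xx[1:mid], LL[1:mid], UU[1:mid])) lo <- mid
      else hi <- mid - 1L
    }
    lo
  }
  feasible <- function(d) {
    L <- pmax(Llev - d, 0)
    U <- pmin(Ulev + d, 1)
    p <- maxPrefix(ux, L, U)
    if (p == m) return(TRUE)
    s <- maxPrefix(-rev(ux), -rev(U), -rev(L))
    p + s >= m
  }
  lo <- 0.5 / n; hi <- 0.5
  if (feasible(lo)) return(lo)
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  hi
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# C(n + m, n) group assignments, mirroring the two-sided doubling rule.
oracleRanksumP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  combos <- utils::combn(nx + ny, nx)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  wAll <- apply(combos, 2, function(idx)
    sum(rank(pooled)[idx]) - nx * (nx + 1) / 2)
  pLo <- mean(wAll <= wObs)
  pHi <- mean(wAll >= wObs)
  min(1, 2 * min(pLo, pHi))
}

# random 3D rotation matrix
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))))
}

# small session data.frame and file helpers
makeSessionDF <- function(n = 5, seed = 1) {
  set.seed(seed)
  data.frame(t = seq_len(n) - 1,
             x_maxdev = round(runif(n, 0, 3), 6),
             y_maxdev = round(runif(n, 0, 3), 6),
             z_maxdev = round(runif(n, 0, 3), 6))
}

writeSessionFile <- function(df, path, sep = ",") {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# magnitude series straight from values (bypassing session plumbing)
seriesFromValues <- function(values, id = "p1", day = 1L, session = 1L) {
  new("MagnitudeSeries", participantId = id, values = values,
      day = rep(as.integer(day), length.out = length(values)),
      session = rep(as.integer(session), length.out = length(values)))
}

# a data entry with a far second mode, emulating bimodal contamination
contaminatedEntry <- function(idx, n = 100, seed = 1) {
  set.seed(seed)
  x <- rgamma(n, shape = 2, scale = 1)
  far <- 10 * quantile(x, 0.99)
  x[seq_len(round(0.2 * n))] <- abs(rnorm(round(0.2 * n), far, far / 50))
  new("DataEntry", entryIndex = as.integer(idx), samples = x,
      participantId = "p1", day = 1L, session = 1L)
}

cleanEntry <- function(idx, n = 100, shape = 2, scale = 1, seed = 1) {
  set.seed(seed)
  new("DataEntry", entryIndex = as.integer(idx),
      samples = rgamma(n, shape = shape, scale = scale),
      participantId = "p1", day = 1L, session = 1L)
}
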