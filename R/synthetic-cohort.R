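#' Construct a synthetic participant specification
#'
#' @param personaId identifier.
#' @param label cohort label, "NC" or "PD".
#' @param age age in years (metadata for the cohort stage).
#' @param a0,b0 baseline Gamma shape and scale of the magnitude entries.
#' @param driftSd per-entry standard deviation of the random-walk step on
#'   (log shape, log scale).
#' @param jumpProb per-entry probability of a regime jump.
#' @param jumpScale jump magnitude; on a jump each parameter is multiplied
#'   by a factor drawn log-uniformly between 1/jumpScale and jumpScale.
#' @param contaminationProb per-entry probability that the entry is
#'   bimodal-contaminated (a far second mode at 10x the entry's 99th
#'   percentile replacing 20% of its samples).
#' @param days,sessionsPerDay,readingsPerSession stream layout;
#'   readingsPerSession must be >= 100.
#' @param seed persona RNG seed.
#' @return a [Persona-class].
#' @seealso [ncPersona()], [pdPersona()] for the cohort presets.
#' @export
persona <- function(personaId, label = "NC", age = 60, a0 = 3.5, b0 = 0.64,
                    driftSd = 0.05, jumpProb = 0.02, jumpScale = 5,
                    contaminationProb = 0.02, days = 14L,
                    sessionsPerDay = 4L, readingsPerSession = 300L,
                    seed = 1L) {
  new("Persona", personaId = as.character(personaId), label = label,
      age = age, a0 = a0, b0 = b0, driftSd = driftSd, jumpProb = jumpProb,
      jumpScale = jumpScale, contaminationProb = contaminationProb,
      days = as.integer(days), sessionsPerDay = as.integer(sessionsPerDay),
      readingsPerSession = as.integer(readingsPerSession),
      seed = as.integer(seed))
}

#' Normal-control-like persona preset
#'
#' Baseline (shape 3.5, scale 0.64) sits in the predictive right side of
#' the Gamma plane, near the oldest controls of the reference cohort, with
#' mild drift and rare moderate jumps.
#'
#' @param personaId,age,seed passed to [persona()].
#' @param ... overrides for any [persona()] argument.
#' @return a [Persona-class] labelled "NC".
#' @export
ncPersona <- function(personaId, age = 65, seed = 1L, ...) {
  args <- list(personaId = personaId, label = "NC", age = age,
               a0 = 3.5, b0 = 0.64, driftSd = 0.05, jumpProb = 0.02,
               jumpScale = 5, contaminationProb = 0.02, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(persona, args)
}

#' Late-stage-PD-like persona preset
#'
#' Baseline (shape 0.75, scale 13.4) sits in the random, high-dispersion
#' left side of the Gamma plane (the most affected patient of the reference
#' cohort), with stronger drift and frequent large regime jumps.
#'
#' @param personaId,age,seed passed to [persona()].
#' @param ... overrides for any [persona()] argument.
#' @return a [Persona-class] labelled "PD".
#' @export
pdPersona <- function(personaId, age = 65, seed = 1L, ...) {
  args <- list(personaId = personaId, label = "PD", age = age,
               a0 = 0.75, b0 = 13.4, driftSd = 0.1, jumpProb = 0.05,
               jumpScale = 10, contaminationProb = 0.02, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(persona, args)
}

#' Simulate one persona's accelerometer stream
#'
#' Generates the magnitude stream entry-block by entry-block (blocks of
#' `window` readings, the downstream estimation unit).  The block's true
#' (shape, scale) follows a reflected random walk on the log parameters
#' within (a0/10, 10 a0) x (b0/10, 10 b0); with probability `jumpProb` the
#' walk takes a persistent multiplicative regime jump; block magnitudes are
#' i.i.d. Gamma draws; with probability `contaminationProb` 20% of the
#' block's samples are replaced by a far second mode centred at 10x the
#' block's 99th percentile.  Magnitudes are stored as the X component of a
#' max-deviation vector (Y = Z = 0), so the Euclidean reduction recovers
#' them exactly.
#'
#' @param p a [Persona-class].
#' @param window readings per entry block (default 100).
#' @return list with `sessions` (list of [Session-class]) and `ledger`
#'   (data.frame of per-block ground truth: true shape/scale, jump and
#'   contamination flags) plus the persona `seed`.
#' @export
simulatePersonaStream <- function(p, window = 100L) {
  stopifnot(is(p, "Persona"))
  validObject(p)
  withSeed(p@seed, {
    la <- log(p@a0); lb <- log(p@b0)
    bounds <- rbind(c(log(p@a0 / 10), log(10 * p@a0)),
                    c(log(p@b0 / 10), log(10 * p@b0)))
    reflect <- function(v, lo, hi) {
      # fold back into [lo, hi]
      rng <- hi - lo
      v <- (v - lo) %% (2 * rng)
      lo + ifelse(v > rng, 2 * rng - v, v)
    }
    blocksPerSession <- p@readingsPerSession %/% window
    extra <- p@readingsPerSession %% window
    sessions <- vector("list", p@days * p@sessionsPerDay)
    ledger <- NULL
    blockId <- 0L
    si <- 0L
    for (d in seq_len(p@days)) for (s in seq_len(p@sessionsPerDay)) {
      vals <- numeric(0)
      for (blk in seq_len(blocksPerSession)) {
        blockId <- blockId + 1L
        la <- reflect(la + rnorm(1, 0, p@driftSd),
                      bounds[1, 1], bounds[1, 2])
        lb <- reflect(lb + rnorm(1, 0, p@driftSd),
                      bounds[2, 1], bounds[2, 2])
        jumped <- runif(1) < p@jumpProb
        if (jumped) {
          fa <- exp(runif(1, -log(p@jumpScale), log(p@jumpScale)))
          fb <- exp(runif(1, -log(p@jumpScale), log(p@jumpScale)))
          la <- reflect(la + log(fa), bounds[1, 1], bounds[1, 2])
          lb <- reflect(lb + log(fb), bounds[2, 1], bounds[2, 2])
        }
        x <- rgamma(window, shape = exp(la), scale = exp(lb))
        contaminated <- runif(1) < p@contaminationProb
        if (contaminated) {
          far <- 10 * quantile(x, 0.99)
          idx <- sample.int(window, max(1L, round(0.2 * window)))
          x[idx] <- abs(rnorm(length(idx), mean = far, sd = far / 50))
        }
        vals <- c(vals, x)
        ledger <- rbind(ledger, data.frame(
          block = blockId, day = d, session = s,
          shape = exp(la), scale = exp(lb),
          jump = jumped, contaminated = contaminated))
      }
      if (extra > 0L)  # trailing readings at current parameters
        vals <- c(vals, rgamma(extra, shape = exp(la), scale = exp(lb)))
      si <- si + 1L
      sessions[[si]] <- new("Session", participantId = p@personaId,
        dayIndex = d, sessionIndex = s,
        readings = data.frame(t = seq_along(vals) - 1,
                              x_maxdev = vals, y_maxdev = 0,
                              z_maxdev = 0),
        nDropped = 0L)
    }
    list(sessions = sessions, ledger = ledger, seed = p@seed)
  })
}

#' Default synthetic cohort specification
#'
#' Six NC-like and nine PD-like personas (the reference cohort's group
#' sizes) with ages spread over the cohort's observed range and per-persona
#' sub-seeds derived deterministically from one global seed.
#'
#' @param seed global seed.
#' @param ... overrides applied to every persona (e.g. `days = 7L`).
#' @return list of [Persona-class].
#' @export
defaultCohortSpec <- function(seed = 1L, ...) {
  ncAges <- c(42, 55, 57, 67, 77, 77)
  pdAges <- c(54, 55, 69, 46, 55, 57, 55, 80, 65)
  personas <- c(
    lapply(seq_along(ncAges), function(i)
      ncPersona(sprintf("NC%02d", i), age = ncAges[i],
                seed = seed * 1000L + i, ...)),
    lapply(seq_along(pdAges), function(i)
      pdPersona(sprintf("PD%02d", i), age = pdAges[i],
                seed = seed * 1000L + 100L + i, ...)))
  personas
}

#' Simulate a cohort to disk
#'
#' Writes session files in the `<participant>/<day>/<session>.csv` layout
#' plus a ground-truth ledger and manifest in JSON.
#'
#' @param personas list of [Persona-class], e.g. [defaultCohortSpec()].
#' @param dir output directory.
#' @param window readings per entry block.
#' @return (invisibly) the manifest: per-persona id, label, age, file
#'   paths, and ledger path.
#' @export
simulateCohort <- function(personas, dir, window = 100L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir)
  manifest <- lapply(personas, function(p) {
    sim <- simulatePersonaStream(p, window = window)
    files <- vapply(sim$sessions, function(s) {
      # manifest paths are relative to dir so cohorts are relocatable
      rel <- file.path(p@personaId, s@dayIndex,
                       paste0(s@sessionIndex, ".csv"))
      writeSession(s, file.path(dir, rel))
      rel
    }, character(1))
    rel <- file.path(p@personaId, "ground_truth.json")
    jsonlite::write_json(sim$ledger, file.path(dir, rel), digits = NA)
    list(participant = p@personaId, label = p@label, age = p@age,
         seed = p@seed, files = files, ledger = rel)
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
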