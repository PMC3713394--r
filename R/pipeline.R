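#' Pipeline configuration
#'
#' Validates and assembles the knobs of the end-to-end pipeline.  Defaults
#' are the method's canonical settings: 100-reading entries, dip-test
#' discard at p < 0.01, stochastic-motion cutoff 0.002, peak threshold 1,
#' k = 2 clusters.
#'
#' @param inputDir directory of session files laid out as
#'   `<participant>/<day>/<session>.csv` with a `manifest.json` giving
#'   labels and ages (as written by [simulateCohort()]); NULL when
#'   `personas` is given.
#' @param personas list of [Persona-class] to simulate instead of reading
#'   `inputDir`.
#' @param window entry size, >= 2.
#' @param dipAlpha dip-test discard threshold.
#' @param nBoot dip-test bootstrap replicates.
#' @param speedCutoff stochastic-motion cutoff.
#' @param peakThreshold speed-peak threshold.
#' @param minEntries minimum surviving entries per participant; fewer and
#'   the participant is excluded from the cohort stage.
#' @param restarts,seed clustering and simulation controls.
#' @param outDir output directory for the run artifacts.
#' @return validated config list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(inputDir = NULL, personas = NULL, window = 100L,
                           dipAlpha = 0.01, nBoot = 500L,
                           speedCutoff = 0.002, peakThreshold = 1,
                           minEntries = 20L, restarts = 50L, seed = 1L,
                           outDir = tempfile("stochsig_run")) {
  if (is.null(inputDir) && is.null(personas))
    stop("supply inputDir or personas")
  if (window < 2L) stop("window must be >= 2")
  if (dipAlpha <= 0 || dipAlpha >= 1) stop("dipAlpha must be in (0, 1)")
  if (speedCutoff <= 0 || peakThreshold <= 0)
    stop("thresholds must be positive")
  structure(list(inputDir = inputDir, personas = personas,
                 window = as.integer(window), dipAlpha = dipAlpha,
                 nBoot = as.integer(nBoot), speedCutoff = speedCutoff,
                 peakThreshold = peakThreshold,
                 minEntries = as.integer(minEntries),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 outDir = outDir),
            class = "pipelineConfig")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path config file; `personas` entries are lists of [persona()]
#'   arguments.
#' @return a `pipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$personas)) {
    if (is.data.frame(raw$personas))  # simplified JSON arrives as a table
      raw$personas <- lapply(seq_len(nrow(raw$personas)), function(i)
        as.list(raw$personas[i, ]))
    raw$personas <- lapply(raw$personas, function(p) do.call(persona, p))
  }
  do.call(pipelineConfig, raw)
}

.readCohortDir <- function(dir) {
  manifestPath <- file.path(dir, "manifest.json")
  if (!file.exists(manifestPath))
    stop("missing cohort metadata: ", manifestPath)
  manifest <- jsonlite::read_json(manifestPath, simplifyVector = FALSE)
  lapply(manifest, function(m) {
    files <- file.path(dir, unlist(m$files))
    sessions <- lapply(files, readSession)
    list(participant = m$participant, label = m$label, age = m$age,
         sessions = sessions)
  })
}

#' Run the full stochastic-signature pipeline
#'
#' Executes the method end to end: (1) gather per-session max-deviation
#' magnitudes per participant; (2) chunk into entries and fit per-entry
#' Gamma estimates with dip-test screening; (3) piece the acquisition-
#' ordered points into a stochastic trajectory; (4) compute the speed
#' profile; (5) collect the speed peaks above threshold; (6) Gamma-fit the
#' peaks into the per-person signature; (7) cluster the cohort scatter;
#' (8) validate against the veridical labels and run the cohort
#' regressions.  Per-stage outputs (signatures.csv, person_signatures.csv,
#' cohort_report.json, run.log) land under `config$outDir`; runs are
#' reproducible given identical config and seed.
#'
#' @param config a `pipelineConfig` from [pipelineConfig()].
#' @return (invisibly) list with `scatter` ([CohortScatter-class] or NULL),
#'   `report` (cohortReport or NULL), `people` (per-person records) and
#'   `manifest` of written files.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(config$outDir, "run.log")
  logLines <- c(sprintf("stochsig %s",
                        as.character(utils::packageVersion("stochsig"))),
                sprintf("seed %d, window %d, dipAlpha %g, cutoff %g, threshold %g",
                        config$seed, config$window, config$dipAlpha,
                        config$speedCutoff, config$peakThreshold))
  if (!is.null(config$personas)) {
    simDir <- file.path(config$outDir, "sessions")
    simulateCohort(config$personas, simDir, window = config$window)
    inputDir <- simDir
    logLines <- c(logLines, sprintf("simulated %d personas -> %s",
                                    length(config$personas), simDir))
  } else inputDir <- config$inputDir
  cohortIn <- .readCohortDir(inputDir)

  sigTables <- list()
  people <- list()
  for (rec in cohortIn) {
    series <- magnitudeSeries(rec$sessions)
    entries <- chunkEntries(series, window = config$window)
    sigs <- entrySignatures(entries, dipAlpha = config$dipAlpha,
                            nBoot = config$nBoot, seed = config$seed)
    nDisc <- attr(sigs, "discarded")
    logLines <- c(logLines,
                  sprintf("%s: %d entries, %d discarded as multimodal",
                          rec$participant, length(entries), nDisc))
    sigTables[[rec$participant]] <- signatureTable(sigs, rec$participant)
    if (length(sigs) < max(config$minEntries, 2L)) {
      logLines <- c(logLines, sprintf(
        "%s: excluded (%d surviving entries < %d)", rec$participant,
        length(sigs), config$minEntries))
      next
    }
    traj <- buildTrajectory(sigs, participantId = rec$participant)
    prof <- shiftMagnitudes(traj, cutoff = config$speedCutoff)
    peaks <- suppressWarnings(
      extractPeaks(prof, threshold = config$peakThreshold))
    sig <- suppressWarnings(
      personSignature(rec$participant, peaks, prof,
                      nEntries = length(sigs), nDiscarded = nDisc))
    if (is.null(sig)) {
      logLines <- c(logLines, sprintf("%s: excluded (%d peaks < 10)",
                                      rec$participant, length(peaks)))
      next
    }
    people[[rec$participant]] <- list(label = rec$label, age = rec$age,
                                      trajectory = traj, profile = prof,
                                      signature = sig)
  }
  write.table(do.call(rbind, sigTables),
              file.path(config$outDir, "signatures.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)

  scatter <- NULL
  report <- NULL
  if (length(people)) {
    ptab <- personTable(lapply(people, `[[`, "signature"))
    ptab$label <- vapply(people, `[[`, character(1), "label")
    ptab$age <- vapply(people, `[[`, numeric(1), "age")
    write.table(ptab, file.path(config$outDir, "person_signatures.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    if (all(table(factor(ptab$label, levels = c("NC", "PD"))) >= 3L)) {
      scatter <- cohortScatter(ptab)
      report <- cohortReport(scatter, restarts = config$restarts,
                             seed = config$seed)
      writeCohortReport(report, config$outDir)
    } else {
      warning("fewer than 3 members in a group; cohort stage skipped")
      logLines <- c(logLines, "cohort stage skipped: group too small")
    }
  } else warning("no participant survived; cohort stage skipped")
  writeLines(logLines, logPath)
  invisible(list(scatter = scatter, report = report, people = people,
                 manifest = list.files(config$outDir, recursive = TRUE)))
}
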