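#' Published reference cohort of stochastic signatures
#'
#' Loads the per-participant signature table of the published 15-person
#' smartphone-accelerometry cohort (6 normal controls, 9 Parkinson's
#' patients; a 16th control was excluded because nearly all of her entries
#' failed the unimodality screen).  Each row carries the Gamma (shape,
#' scale) point of the person's speed-peak distribution, its 95% bounds,
#' age, and the min/max shift of the speed profile.  This fixture lets the
#' cohort stage run and be checked without the original raw streams, which
#' are not redistributable.
#'
#' @return a [CohortScatter-class] with 15 rows (extra columns `minShift`,
#'   `shapeLo`, `shapeHi`, `scaleLo`, `scaleHi` preserved).
#' @examples
#' referenceCohort()
#' @export
referenceCohort <- function() {
  path <- system.file("extdata", "reference_cohort.tsv",
                      package = "stochsig", mustWork = TRUE)
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  if (nrow(d) != 15L || !identical(sum(d$label == "NC"), 6L))
    stop("reference cohort fixture failed its integrity check")
  cohortScatter(d)
}

#' Replicate the cohort-stage results on the reference cohort
#'
#' Runs only the cohort stage ([cohortReport()]) on the packaged reference
#' signatures: power-law fits of scale on shape (full cohort and per
#' group), k = 2 city-block k-medians clustering with misclassification
#' against the veridical labels, the PD Fano-factor-on-distance
#' regression, the NC age-on-shape regression, and the group rank-sum
#' tests.
#'
#' @param restarts,seed clustering controls.
#' @param scatter alternative scatter (defaults to [referenceCohort()]);
#'   rows may be removed for robustness checks.
#' @return a `cohortReport` list.
#' @export
referenceReport <- function(restarts = 50L, seed = 1L,
                            scatter = referenceCohort()) {
  cohortReport(scatter, restarts = restarts, seed = seed)
}
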