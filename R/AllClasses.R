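# Cell-state codes for the evidence matrix assay.
CELL_ABSENT <- 0L
CELL_INCLUDED <- 1L
CELL_STRUCTURAL_MISSING <- 2L

#' OverviewDataset: the raw material of an overlap assessment
#'
#' Container for one overview of systematic reviews: the included reviews
#' (matrix columns), the primary-study references they cite (matrix rows,
#' grouped into publication threads by `study_id`), and the review-by-
#' reference inclusion links. Outcome labels on both axes drive the
#' outcome-level and scope-adjusted analyses.
#'
#' Structural requirements (column names and types) are enforced by the
#' class validity; semantic invariants (identifier uniqueness, dangling
#' links, outcome-universe containment) are reported by
#' [validateDataset()], which never throws.
#'
#' @slot reviews `DataFrame` with columns `review_id` (character),
#'   `search_date` (`Date`), `covers_main_outcome` (logical), `outcomes`
#'   (`CharacterList`).
#' @slot references `DataFrame` with columns `reference_id`, `study_id`
#'   (the publication-thread key), `publication_date` (`Date`), `outcomes`
#'   (`CharacterList`).
#' @slot inclusions `DataFrame` with columns `review_id`, `reference_id`.
#' @slot mainOutcome the overview's main outcome label.
#' @slot outcomeUniverse all outcome labels the overview considers.
#'
#' @aliases OverviewDataset-class
#' @export
setClass("OverviewDataset",
  slots = c(
    reviews = "DataFrame",
    references = "DataFrame",
    inclusions = "DataFrame",
    mainOutcome = "character",
    outcomeUniverse = "character"
  )
)

setValidity("OverviewDataset", function(object) {
  msg <- character()
  needRev <- c("review_id", "search_date", "covers_main_outcome", "outcomes")
  needRef <- c("reference_id", "study_id", "publication_date", "outcomes")
  needInc <- c("review_id", "reference_id")
  if (!all(needRev %in% colnames(object@reviews)))
    msg <- c(msg, sprintf("reviews must have columns: %s",
                          paste(needRev, collapse = ", ")))
  if (!all(needRef %in% colnames(object@references)))
    msg <- c(msg, sprintf("references must have columns: %s",
                          paste(needRef, collapse = ", ")))
  if (!all(needInc %in% colnames(object@inclusions)))
    msg <- c(msg, sprintf("inclusions must have columns: %s",
                          paste(needInc, collapse = ", ")))
  if (length(object@mainOutcome) != 1L)
    msg <- c(msg, "mainOutcome must be a single label")
  if (length(msg)) msg else TRUE
})

#' EvidenceMatrix: a citation matrix with cell states
#'
#' An evidence (citation) matrix is a two-dimensional table whose rows are
#' primary-study references (or collapsed publication threads) and whose
#' columns are systematic reviews. It extends
#' [SummarizedExperiment::SummarizedExperiment] with a single integer assay
#' `"state"` coding each cell as 0 (absent), 1 (included) or 2 (structurally
#' missing: the study appeared after the review's search date, so the review
#' could not possibly have included it).
#'
#' Row annotations carry `study_id`, `publication_date` and `outcomes`;
#' column annotations carry `search_date`, `covers_main_outcome` and
#' `outcomes`; `metadata()` records `rowMode` (`"reference"` or `"study"`),
#' the construction `provenance` (a [ScenarioSpec-class] or `"raw"`) and the
#' adjustments applied so far. Rows without a single included cell are
#' dropped at construction, so the included-cell count N is always at least
#' the row count r.
#'
#' @aliases EvidenceMatrix-class
#' @export
setClass("EvidenceMatrix", contains = "SummarizedExperiment")

setValidity("EvidenceMatrix", function(object) {
  msg <- character()
  if (!"state" %in% SummarizedExperiment::assayNames(object))
    return("assay 'state' is required")
  st <- SummarizedExperiment::assay(object, "state")
  if (!is.integer(st))
    msg <- c(msg, "assay 'state' must be integer")
  else if (length(st) && !all(st %in% c(CELL_ABSENT, CELL_INCLUDED,
                                        CELL_STRUCTURAL_MISSING)))
    msg <- c(msg, "cell states must be 0 (absent), 1 (included) or 2 (structural missing)")
  if (nrow(st) > 0L && ncol(st) > 0L) {
    bad <- rownames(st)[rowSums(st == CELL_INCLUDED) == 0L]
    if (length(bad))
      msg <- c(msg, sprintf("rows without any included cell: %s",
                            paste(bad, collapse = ", ")))
  }
  rm <- S4Vectors::metadata(object)$rowMode
  if (is.null(rm) || !rm %in% c("reference", "study"))
    msg <- c(msg, "metadata rowMode must be 'reference' or 'study'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "row ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "review ids (column names) must be unique")
  if (length(msg)) msg else TRUE
})

#' ScenarioSpec: one matrix-construction scenario
#'
#' One of the sixteen combinations of level of analysis (overview vs
#' outcome) with the three binary matrix adjustments (scope, publication
#' threads, structural missingness). Scenarios 1--8 are overview-level and
#' 9--16 outcome-level; within each level the flag pattern runs: none,
#' scope, threads, missingness, scope+threads, scope+missingness,
#' threads+missingness, all three.
#'
#' @slot index scenario index, 1--16.
#' @slot level `"overview"` or `"outcome"`.
#' @slot adjustScope restrict columns to reviews relevant to the main
#'   outcome and drop rows contributing to no overview outcome.
#' @slot adjustThreads collapse publication threads to one row per study.
#' @slot adjustMissingness mark unreachable cells as structural zeros and
#'   remove them from the CCA denominator.
#'
#' @aliases ScenarioSpec-class
#' @export
setClass("ScenarioSpec",
  slots = c(
    index = "integer",
    level = "character",
    adjustScope = "logical",
    adjustThreads = "logical",
    adjustMissingness = "logical"
  )
)

setValidity("ScenarioSpec", function(object) {
  msg <- character()
  if (length(object@index) != 1L || is.na(object@index) ||
      object@index < 1L || object@index > 16L)
    msg <- c(msg, "index must be a single integer in 1..16")
  if (length(object@level) != 1L || !object@level %in% c("overview", "outcome"))
    msg <- c(msg, "level must be 'overview' or 'outcome'")
  for (s in c("adjustScope", "adjustThreads", "adjustMissingness"))
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
      msg <- c(msg, sprintf("%s must be TRUE or FALSE", s))
  if (length(msg)) msg else TRUE
})

#' CCAResult: corrected covered area for one evidence matrix
#'
#' Holds the overall CCA, the cell counts it is computed from (N included
#' cells, r rows, c reviews, SZ structural zeros), and -- when produced by
#' [pairwiseCCA()] -- the full pairwise CCA matrix with summary statistics.
#' An undefined CCA (fewer than two reviews, or a saturated/empty
#' denominator) is stored as `NA` with a human-readable reason rather than
#' silently coerced to a number.
#'
#' @slot overall overall CCA as a percentage in `[0, 100]`, or `NA`.
#' @slot undefinedReason why `overall` is `NA` (`NA_character_` if defined).
#' @slot N,r,c,SZ integer cell counts behind the formula.
#' @slot pairwise symmetric numeric matrix of pairwise CCA percentages
#'   (`NA` diagonal; `NA` for undefined pairs); empty unless computed.
#' @slot pairwiseSummary list with `median`, `q1`, `q3`, `min`, `max`
#'   (over defined pairs, linear-interpolation quartiles), `n_pairs` and
#'   `n_undefined`.
#'
#' @aliases CCAResult-class
#' @export
setClass("CCAResult",
  slots = c(
    overall = "numeric",
    undefinedReason = "character",
    N = "integer",
    r = "integer",
    c = "integer",
    SZ = "integer",
    pairwise = "matrix",
    pairwiseSummary = "list"
  ),
  prototype = list(
    overall = NA_real_,
    undefinedReason = NA_character_,
    N = 0L, r = 0L, c = 0L, SZ = 0L,
    pairwise = matrix(numeric(0), 0, 0),
    pairwiseSummary = list()
  )
)

setValidity("CCAResult", function(object) {
  msg <- character()
  if (length(object@overall) != 1L)
    msg <- c(msg, "overall must be a single value (possibly NA)")
  if (!is.na(object@overall) &&
      (object@overall < -1e-9 || object@overall > 100 + 1e-9))
    msg <- c(msg, "overall CCA must lie in [0, 100]")
  pw <- object@pairwise
  if (length(pw) && !all(is.na(pw) | (pw >= -1e-9 & pw <= 100 + 1e-9)))
    msg <- c(msg, "pairwise CCA values must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' SweepResult: all sixteen scenarios on one overview
#'
#' Per-scenario overall and pairwise CCA together with the cell counts, as
#' produced by [runScenarioSweep()]. The impact of the matrix-construction
#' assumptions is the max minus min of the defined values, via
#' [impactRange()], and its magnitude is labelled by [classifyChange()].
#'
#' @slot records `DataFrame` with one row per scenario: index, level,
#'   adjustment flags, outcome, overall CCA (or `NA` plus a note), N, r, c,
#'   SZ and the pairwise summary statistics.
#' @slot results named list of [CCAResult-class] objects (or `NULL` where a
#'   scenario failed), keeping the full pairwise matrices.
#' @slot outcome the outcome label used for the outcome-level scenarios.
#'
#' @aliases SweepResult-class
#' @export
setClass("SweepResult",
  slots = c(
    records = "DataFrame",
    results = "list",
    outcome = "character"
  )
)

setValidity("SweepResult", function(object) {
  msg <- character()
  if (nrow(object@records) != 16L)
    msg <- c(msg, "a sweep holds exactly 16 scenario records")
  if (length(object@results) != 16L)
    msg <- c(msg, "a sweep holds exactly 16 result slots")
  if (length(msg)) msg else TRUE
})

#' GeneratorConfig: parameters of the synthetic-overview generator
#'
#' See [generatorConfig()] for the meaning and defaults of each field.
#'
#' @aliases GeneratorConfig-class
#' @export
setClass("GeneratorConfig",
  slots = c(
    nReviews = "integer",
    nStudies = "integer",
    inclusionProb = "numeric",
    popularityConcentration = "numeric",
    threadMeanExtraRefs = "numeric",
    lateFraction = "numeric",
    nOutcomes = "integer",
    reviewOutcomeProb = "numeric",
    studyOutcomeProb = "numeric",
    mainOutcomeReviewProb = "numeric",
    seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@nReviews < 2L) msg <- c(msg, "nReviews must be >= 2")
  if (object@nStudies < 1L) msg <- c(msg, "nStudies must be >= 1")
  if (object@nOutcomes < 1L) msg <- c(msg, "nOutcomes must be >= 1")
  for (p in c("inclusionProb", "lateFraction", "reviewOutcomeProb",
              "studyOutcomeProb", "mainOutcomeReviewProb")) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a probability in [0, 1]", p))
  }
  if (!(object@popularityConcentration > 0))
    msg <- c(msg, "popularityConcentration must be positive (Inf allowed)")
  if (object@threadMeanExtraRefs < 0)
    msg <- c(msg, "threadMeanExtraRefs must be non-negative")
  if (length(msg)) msg else TRUE
})
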