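# Evidence-matrix construction and the three matrix adjustments.

# Internal constructor from a prepared state matrix + annotations.
.newEvidenceMatrix <- function(state, rowData, colData, rowMode,
                               provenance = "raw", adjustments = character(),
                               level = "overview", outcome = NA_character_) {
  keep <- if (nrow(state)) rowSums(state == CELL_INCLUDED) > 0L else logical(0)
  state <- state[keep, , drop = FALSE]
  rowData <- rowData[keep, , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(state = state), rowData = rowData, colData = colData)
  S4Vectors::metadata(se) <- list(rowMode = rowMode, provenance = provenance,
                                  adjustments = adjustments, level = level,
                                  outcome = outcome)
  methods::new("EvidenceMatrix", se)
}

#' Build an evidence matrix from an overview dataset
#'
#' Constructs the initial (unadjusted) citation matrix: one row per
#' primary-study reference, one column per systematic review, a cell marked
#' included where the review cites the reference. At the overview level all
#' reviews form columns; at the outcome level only reviews reporting the
#' requested outcome are kept, and rows are additionally restricted to
#' references contributing data to that outcome. Rows with no remaining
#' inclusion are dropped, so every row of the result has at least one
#' included cell.
#'
#' @param dataset an [OverviewDataset-class].
#' @param level `"overview"` (one matrix for everything) or `"outcome"`
#'   (restrict both axes to one outcome).
#' @param outcome outcome label for `level = "outcome"`; defaults to the
#'   dataset's main outcome. Must belong to the outcome universe.
#' @return an [EvidenceMatrix-class] with `rowMode = "reference"` and raw
#'   provenance.
#' @examples
#' ds <- generateOverview(generatorConfig(nReviews = 5, nStudies = 30, seed = 3))
#' m <- buildMatrix(ds)
#' dim(m)
#' buildMatrix(ds, level = "outcome")   # main-outcome columns only
#' @export
buildMatrix <- function(dataset, level = c("overview", "outcome"),
                        outcome = NULL) {
  stopifnot(methods::is(dataset, "OverviewDataset"))
  level <- match.arg(level)
  rev <- dataset@reviews
  ref <- dataset@references
  inc <- dataset@inclusions
  if (nrow(rev) == 0L) stop("empty overview: dataset has zero reviews")

  if (level == "outcome") {
    if (is.null(outcome)) outcome <- dataset@mainOutcome
    if (!.outcomeKey(outcome) %in% .outcomeKey(dataset@outcomeUniverse))
      stop(sprintf("unknown outcome label: '%s'", outcome))
    keepRev <- .eachHasOutcome(rev$outcomes, outcome)
    if (!any(keepRev))
      stop(sprintf("no review reports outcome '%s'", outcome))
    rev <- rev[keepRev, , drop = FALSE]
    keepRef <- .eachHasOutcome(ref$outcomes, outcome)
    ref <- ref[keepRef, , drop = FALSE]
  } else {
    outcome <- NA_character_
  }

  inc <- inc[inc$review_id %in% rev$review_id &
             inc$reference_id %in% ref$reference_id, , drop = FALSE]

  state <- matrix(CELL_ABSENT, nrow = nrow(ref), ncol = nrow(rev),
                  dimnames = list(ref$reference_id, rev$review_id))
  if (nrow(inc)) {
    ij <- cbind(match(inc$reference_id, ref$reference_id),
                match(inc$review_id, rev$review_id))
    state[ij] <- CELL_INCLUDED
  }

  rowData <- ref[, c("study_id", "publication_date", "outcomes")]
  rownames(rowData) <- ref$reference_id
  colData <- rev[, c("search_date", "covers_main_outcome", "outcomes")]
  rownames(colData) <- rev$review_id
  .newEvidenceMatrix(state, rowData, colData, rowMode = "reference",
                     level = level, outcome = outcome)
}

#' Construct an evidence matrix directly from a cell-state matrix
#'
#' Low-level constructor for matrices that do not come from an
#' [OverviewDataset-class] -- hand-built examples, simulations, or matrices
#' transcribed from published overviews. Cells are 0 (absent), 1 (included)
#' or 2 (structurally missing); rows without an included cell are dropped.
#' Dates and scope flags default to `NA` and may be supplied when the
#' date-dependent adjustments are needed.
#'
#' @param state integer matrix of cell states; dimnames are used as row and
#'   review identifiers (generated if absent).
#' @param publicationDates per-row publication dates.
#' @param searchDates per-review search dates.
#' @param coversMainOutcome per-review logical scope flag.
#' @param rowMode `"reference"` or `"study"`.
#' @return an [EvidenceMatrix-class] with provenance `"manual"`.
#' @examples
#' m <- EvidenceMatrix(matrix(c(1, 1, 0, 1), 2, 2))
#' overallCCA(m)
#' @export
EvidenceMatrix <- function(state, publicationDates = NULL, searchDates = NULL,
                           coversMainOutcome = NA, rowMode = "reference") {
  state <- as.matrix(state)
  mode(state) <- "integer"
  if (is.null(rownames(state)))
    rownames(state) <- sprintf("row%d", seq_len(nrow(state)))
  if (is.null(colnames(state)))
    colnames(state) <- sprintf("review%d", seq_len(ncol(state)))
  if (is.null(publicationDates)) publicationDates <- rep(as.Date(NA), nrow(state))
  if (is.null(searchDates)) searchDates <- rep(as.Date(NA), ncol(state))
  coversMainOutcome <- rep(as.logical(coversMainOutcome), length.out = ncol(state))
  rd <- S4Vectors::DataFrame(
    study_id = rownames(state),
    publication_date = as.Date(publicationDates),
    outcomes = IRanges::CharacterList(rep(list(character()), nrow(state))),
    row.names = rownames(state))
  cd <- S4Vectors::DataFrame(
    search_date = as.Date(searchDates),
    covers_main_outcome = coversMainOutcome,
    outcomes = IRanges::CharacterList(rep(list(character()), ncol(state))),
    row.names = colnames(state))
  .newEvidenceMatrix(state, rd, cd, rowMode = rowMode, provenance = "manual")
}

#' Evidence-matrix accessors
#'
#' `cellStates()` returns the integer state matrix (0 absent, 1 included,
#' 2 structurally missing); `rowMode()` says whether rows are individual
#' references or collapsed publication threads; `provenance()` returns the
#' [ScenarioSpec-class] that produced the matrix, or `"raw"`.
#'
#' @param x an [EvidenceMatrix-class].
#' @name evidenceMatrix-accessors
NULL

#' @rdname evidenceMatrix-accessors
#' @export
setMethod("cellStates", "EvidenceMatrix",
          function(x) SummarizedExperiment::assay(x, "state"))

#' @rdname evidenceMatrix-accessors
#' @export
setMethod("rowMode", "EvidenceMatrix",
          function(x) S4Vectors::metadata(x)$rowMode)

#' @rdname evidenceMatrix-accessors
#' @export
setMethod("provenance", "EvidenceMatrix",
          function(x) S4Vectors::metadata(x)$provenance)

setMethod("show", "EvidenceMatrix", function(object) {
  st <- cellStates(object)
  md <- S4Vectors::metadata(object)
  prov <- md$provenance
  provTxt <- if (methods::is(prov, "ScenarioSpec"))
    sprintf("scenario %d", prov@index) else as.character(prov)
  cat(sprintf("EvidenceMatrix: %d %s row(s) x %d review(s) [%s level, %s]\n",
              nrow(st), md$rowMode, ncol(st), md$level, provTxt))
  cat(sprintf("  N (included) = %d, SZ (structural zeros) = %d",
              sum(st == CELL_INCLUDED), sum(st == CELL_STRUCTURAL_MISSING)))
  if (length(md$adjustments))
    cat(sprintf("; adjustments: %s", paste(md$adjustments, collapse = " -> ")))
  cat("\n")
})

#' Matrix-construction adjustments
#'
#' The three binary assumptions applied to a raw evidence matrix:
#'
#' * `adjustScope(x)` keeps only the reviews relevant to the overview's
#'   main outcome (`covers_main_outcome`) and deletes rows whose
#'   reference(s) contribute data to no overview outcome; rows left without
#'   an included cell are then dropped.
#' * `collapseThreads(x)` merges each publication thread (references
#'   sharing a `study_id`) into a single study-level row: a study is
#'   included by a review as soon as any member reference is, and a cell is
#'   structurally missing only if every member cell was. The collapsed
#'   row's publication date is the thread's earliest.
#' * `markStructuralMissingness(x)` turns every absent cell whose row was
#'   published strictly after the column's search date into a structural
#'   zero, which [overallCCA()] removes from the denominator. Equal dates
#'   count as reachable. An included cell is never changed; if one is found
#'   where the publication postdates the search, a data-quality warning is
#'   raised.
#'
#' Adjustments never create rows or inclusions: N and r are non-increasing
#' under scope and thread adjustment, and missingness marking changes
#' neither.
#'
#' @param x an [EvidenceMatrix-class].
#' @return the adjusted [EvidenceMatrix-class].
#' @seealso [applyScenario()] for the canonical composition
#'   scope -> threads -> missingness.
#' @name matrixAdjustments
NULL

#' @rdname matrixAdjustments
#' @export
setMethod("adjustScope", "EvidenceMatrix", function(x) {
  cd <- SummarizedExperiment::colData(x)
  keepCol <- !is.na(cd$covers_main_outcome) & cd$covers_main_outcome
  if (!any(keepCol))
    stop("scope adjustment empties matrix: no review covers the main outcome")
  rd <- SummarizedExperiment::rowData(x)
  keepRow <- lengths(rd$outcomes) > 0L
  st <- cellStates(x)[keepRow, keepCol, drop = FALSE]
  md <- S4Vectors::metadata(x)
  .newEvidenceMatrix(st, rd[keepRow, , drop = FALSE],
                     cd[keepCol, , drop = FALSE],
                     rowMode = md$rowMode, provenance = md$provenance,
                     adjustments = c(md$adjustments, "scope"),
                     level = md$level, outcome = md$outcome)
})

#' @rdname matrixAdjustments
#' @export
setMethod("collapseThreads", "EvidenceMatrix", function(x) {
  md <- S4Vectors::metadata(x)
  if (md$rowMode == "study")
    stop("already at study level: publication threads are collapsed")
  rd <- SummarizedExperiment::rowData(x)
  st <- cellStates(x)
  studies <- unique(rd$study_id)
  newState <- matrix(CELL_ABSENT, nrow = length(studies), ncol = ncol(st),
                     dimnames = list(studies, colnames(st)))
  pubDate <- rep(as.Date(NA), length(studies))
  outcomes <- vector("list", length(studies))
  members <- vector("list", length(studies))
  for (k in seq_along(studies)) {
    i <- which(rd$study_id == studies[k])
    sub <- st[i, , drop = FALSE]
    anyInc <- colSums(sub == CELL_INCLUDED) > 0L
    allSM <- colSums(sub == CELL_STRUCTURAL_MISSING) == nrow(sub)
    newState[k, anyInc] <- CELL_INCLUDED
    newState[k, !anyInc & allSM] <- CELL_STRUCTURAL_MISSING
    d <- rd$publication_date[i]
    if (any(!is.na(d))) pubDate[k] <- min(d, na.rm = TRUE)
    outcomes[[k]] <- unique(unlist(rd$outcomes[i], use.names = FALSE))
    members[[k]] <- rownames(rd)[i]
  }
  newRd <- S4Vectors::DataFrame(
    study_id = studies,
    publication_date = pubDate,
    outcomes = IRanges::CharacterList(outcomes),
    member_references = IRanges::CharacterList(members),
    row.names = studies)
  .newEvidenceMatrix(newState, newRd, SummarizedExperiment::colData(x),
                     rowMode = "study", provenance = md$provenance,
                     adjustments = c(md$adjustments, "threads"),
                     level = md$level, outcome = md$outcome)
})

#' @rdname matrixAdjustments
#' @export
setMethod("markStructuralMissingness", "EvidenceMatrix", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  cd <- SummarizedExperiment::colData(x)
  noPub <- is.na(rd$publication_date)
  noSearch <- is.na(cd$search_date)
  if (any(noPub) || any(noSearch))
    stop(sprintf(
      "missing dates: %s",
      paste(c(if (any(noPub)) sprintf("rows without publication_date: %s",
                                      paste(rownames(rd)[noPub], collapse = ", ")),
              if (any(noSearch)) sprintf("reviews without search_date: %s",
                                         paste(rownames(cd)[noSearch], collapse = ", "))),
            collapse = "; ")))
  st <- cellStates(x)
  unreachable <- outer(as.numeric(rd$publication_date),
                       as.numeric(cd$search_date), `>`)
  conflicted <- unreachable & st == CELL_INCLUDED
  if (any(conflicted)) {
    idx <- which(conflicted, arr.ind = TRUE)
    warning(sprintf(
      "data quality: %d included cell(s) where the publication postdates the review search date (e.g. %s in %s); left as included",
      nrow(idx), rownames(st)[idx[1L, 1L]], colnames(st)[idx[1L, 2L]]))
  }
  st[unreachable & st == CELL_ABSENT] <- CELL_STRUCTURAL_MISSING
  md <- S4Vectors::metadata(x)
  .newEvidenceMatrix(st, rd, cd, rowMode = md$rowMode,
                     provenance = md$provenance,
                     adjustments = c(md$adjustments, "missingness"),
                     level = md$level, outcome = md$outcome)
})

#' Enumerate the sixteen matrix-construction scenarios
#'
#' Returns the canonical ordered list of [ScenarioSpec-class] objects.
#' Scenarios 1--8 are overview-level, 9--16 outcome-level; within each
#' level the adjustment pattern is: none; scope; threads; missingness;
#' scope+threads; scope+missingness; threads+missingness; all three. So
#' scenario 1 is the fully unadjusted matrix and scenario 16 the
#' outcome-level, fully adjusted one.
#'
#' @return list of 16 `ScenarioSpec`s, pairwise distinct and exhaustive
#'   over level x the three binary flags.
#' @examples
#' specs <- enumerateScenarios()
#' specs[[1]]
#' specs[[16]]
#' @export
enumerateScenarios <- function() {
  flagPattern <- list(
    c(FALSE, FALSE, FALSE),
    c(TRUE, FALSE, FALSE),
    c(FALSE, TRUE, FALSE),
    c(FALSE, FALSE, TRUE),
    c(TRUE, TRUE, FALSE),
    c(TRUE, FALSE, TRUE),
    c(FALSE, TRUE, TRUE),
    c(TRUE, TRUE, TRUE))
  specs <- vector("list", 16L)
  for (i in 1:16) {
    f <- flagPattern[[(i - 1L) %% 8L + 1L]]
    specs[[i]] <- methods::new("ScenarioSpec",
      index = i,
      level = if (i <= 8L) "overview" else "outcome",
      adjustScope = f[1L], adjustThreads = f[2L], adjustMissingness = f[3L])
  }
  specs
}

setMethod("show", "ScenarioSpec", function(object) {
  adj <- c("scope", "threads", "missingness")[
    c(object@adjustScope, object@adjustThreads, object@adjustMissingness)]
  cat(sprintf("ScenarioSpec %d: %s level, %s\n", object@index, object@level,
              if (length(adj)) paste(adj, collapse = " + ") else "unadjusted"))
})

#' Build the evidence matrix for one scenario
#'
#' Composes [buildMatrix()] with the flagged adjustments in the fixed
#' canonical order scope -> threads -> missingness, so that structural
#' zeros are marked on the rows and columns actually analysed. The
#' resulting matrix records the scenario in its provenance.
#'
#' @param dataset an [OverviewDataset-class].
#' @param spec a [ScenarioSpec-class], e.g. from [enumerateScenarios()].
#' @param outcome outcome label for outcome-level scenarios; defaults to
#'   the dataset's main outcome.
#' @return an [EvidenceMatrix-class].
#' @examples
#' ds <- generateOverview(generatorConfig(seed = 11))
#' applyScenario(ds, enumerateScenarios()[[8]])
#' @export
applyScenario <- function(dataset, spec, outcome = NULL) {
  stopifnot(methods::is(spec, "ScenarioSpec"))
  m <- buildMatrix(dataset, level = spec@level, outcome = outcome)
  if (spec@adjustScope) m <- adjustScope(m)
  if (spec@adjustThreads) m <- collapseThreads(m)
  if (spec@adjustMissingness) m <- markStructuralMissingness(m)
  S4Vectors::metadata(m)$provenance <- spec
  m
}
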