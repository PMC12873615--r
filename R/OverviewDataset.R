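#' Construct an overview dataset
#'
#' Assembles the three tables describing one overview of systematic reviews
#' -- reviews, primary-study references and review-by-reference inclusion
#' links -- into a validated [OverviewDataset-class]. Dates may be given as
#' `Date`, full ISO-8601 strings, or bare years (see [parseMixedDate()]);
#' outcome columns may be `CharacterList`s or `"|"`-separated strings.
#'
#' Identifiers are opaque: publication-thread membership is taken from
#' `study_id` as given, and no attempt is made to parse or deduplicate
#' citations. Outcome labels are trimmed and compared case-insensitively
#' throughout the package.
#'
#' @param reviews data.frame/DataFrame with `review_id`, `search_date`,
#'   `covers_main_outcome`, `outcomes`.
#' @param references data.frame/DataFrame with `reference_id`, `study_id`,
#'   `publication_date`, `outcomes`.
#' @param inclusions data.frame/DataFrame with `review_id`, `reference_id`.
#' @param mainOutcome the overview's main outcome label.
#' @param outcomeUniverse all outcome labels considered; defaults to the
#'   union of `mainOutcome` and every label observed on either axis.
#'
#' @return an [OverviewDataset-class].
#' @seealso [validateDataset()], [buildMatrix()], [generateOverview()]
#' @examples
#' ds <- generateOverview(generatorConfig(nReviews = 4, nStudies = 20, seed = 7))
#' ds
#' validateDataset(ds)
#' @export
OverviewDataset <- function(reviews, references, inclusions,
                            mainOutcome, outcomeUniverse = NULL) {
  reviews <- S4Vectors::DataFrame(reviews)
  references <- S4Vectors::DataFrame(references)
  inclusions <- S4Vectors::DataFrame(inclusions)

  reviews$review_id <- as.character(reviews$review_id)
  reviews$search_date <- parseMixedDate(reviews$search_date, "search")
  reviews$covers_main_outcome <- as.logical(reviews$covers_main_outcome)
  if (!methods::is(reviews$outcomes, "CharacterList"))
    reviews$outcomes <- .splitOutcomes(reviews$outcomes)
  reviews$outcomes <- IRanges::CharacterList(lapply(reviews$outcomes, trimws))

  references$reference_id <- as.character(references$reference_id)
  references$study_id <- as.character(references$study_id)
  references$publication_date <-
    parseMixedDate(references$publication_date, "publication")
  if (!methods::is(references$outcomes, "CharacterList"))
    references$outcomes <- .splitOutcomes(references$outcomes)
  references$outcomes <- IRanges::CharacterList(lapply(references$outcomes, trimws))

  inclusions$review_id <- as.character(inclusions$review_id)
  inclusions$reference_id <- as.character(inclusions$reference_id)

  mainOutcome <- trimws(as.character(mainOutcome))
  if (is.null(outcomeUniverse)) {
    outcomeUniverse <- unique(c(mainOutcome,
                                unlist(reviews$outcomes, use.names = FALSE),
                                unlist(references$outcomes, use.names = FALSE)))
  }
  outcomeUniverse <- unique(trimws(as.character(outcomeUniverse)))

  methods::new("OverviewDataset",
               reviews = reviews, references = references,
               inclusions = inclusions, mainOutcome = mainOutcome,
               outcomeUniverse = outcomeUniverse)
}

#' @rdname OverviewDataset
#' @param x an `OverviewDataset`.
#' @export
setMethod("reviews", "OverviewDataset", function(x) x@reviews)

#' @rdname OverviewDataset
#' @export
setMethod("references", "OverviewDataset", function(x) x@references)

#' @rdname OverviewDataset
#' @export
setMethod("inclusions", "OverviewDataset", function(x) x@inclusions)

#' @rdname OverviewDataset
#' @export
setMethod("mainOutcome", "OverviewDataset", function(x) x@mainOutcome)

#' @rdname OverviewDataset
#' @export
setMethod("outcomeUniverse", "OverviewDataset", function(x) x@outcomeUniverse)

setMethod("show", "OverviewDataset", function(object) {
  cat("OverviewDataset\n")
  cat(sprintf("  %d reviews, %d references (%d publication threads), %d inclusion links\n",
              nrow(object@reviews), nrow(object@references),
              length(unique(object@references$study_id)),
              nrow(object@inclusions)))
  cat(sprintf("  main outcome: '%s'; outcome universe: %s\n",
              object@mainOutcome,
              paste(object@outcomeUniverse, collapse = ", ")))
  nviol <- length(validateDataset(object))
  if (nviol) cat(sprintf("  ** %d validation violation(s); see validateDataset() **\n",
                         nviol))
})

#' Validate an overview dataset
#'
#' Checks every semantic invariant of an [OverviewDataset-class] and returns
#' a character vector of human-readable violations -- one per broken rule,
#' naming the offending entity. An empty vector means the dataset is
#' internally consistent. Validation reports and never throws, so a partly
#' broken dataset can be inspected and repaired.
#'
#' Rules checked: unique `review_id` and `reference_id`; unique inclusion
#' pairs; inclusion links resolving to known reviews and references; the
#' main outcome belonging to the outcome universe; and every review/reference
#' outcome label belonging to the outcome universe (case-insensitively).
#'
#' @param dataset an [OverviewDataset-class].
#' @return character vector of violation descriptions (empty if valid).
#' @examples
#' ds <- generateOverview(generatorConfig(nReviews = 3, nStudies = 10, seed = 1))
#' validateDataset(ds)  # character(0)
#' @export
validateDataset <- function(dataset) {
  stopifnot(methods::is(dataset, "OverviewDataset"))
  rev <- dataset@reviews
  ref <- dataset@references
  inc <- dataset@inclusions
  out <- character()

  dup <- unique(rev$review_id[duplicated(rev$review_id)])
  if (length(dup))
    out <- c(out, sprintf("duplicated review_id: %s", paste(dup, collapse = ", ")))
  dup <- unique(ref$reference_id[duplicated(ref$reference_id)])
  if (length(dup))
    out <- c(out, sprintf("duplicated reference_id: %s", paste(dup, collapse = ", ")))
  bad <- is.na(ref$study_id) | !nzchar(ref$study_id)
  if (any(bad))
    out <- c(out, sprintf("references without a study_id (publication thread): %s",
                          paste(ref$reference_id[bad], collapse = ", ")))

  pairKey <- paste(inc$review_id, inc$reference_id, sep = "\r")
  dup <- unique(pairKey[duplicated(pairKey)])
  if (length(dup))
    out <- c(out, sprintf("duplicated inclusion pair(s): %s",
                          paste(gsub("\r", " / ", dup), collapse = "; ")))
  dangling <- setdiff(unique(inc$review_id), rev$review_id)
  if (length(dangling))
    out <- c(out, sprintf("inclusion references unknown review_id: %s",
                          paste(dangling, collapse = ", ")))
  dangling <- setdiff(unique(inc$reference_id), ref$reference_id)
  if (length(dangling))
    out <- c(out, sprintf("inclusion references unknown reference_id: %s",
                          paste(dangling, collapse = ", ")))

  uniKeys <- .outcomeKey(dataset@outcomeUniverse)
  if (!.outcomeKey(dataset@mainOutcome) %in% uniKeys)
    out <- c(out, sprintf("main outcome '%s' not in outcome universe",
                          dataset@mainOutcome))
  stray <- setdiff(.outcomeKey(unlist(rev$outcomes, use.names = FALSE)), uniKeys)
  if (length(stray))
    out <- c(out, sprintf("review outcome label(s) outside the universe: %s",
                          paste(stray, collapse = ", ")))
  stray <- setdiff(.outcomeKey(unlist(ref$outcomes, use.names = FALSE)), uniKeys)
  if (length(stray))
    out <- c(out, sprintf("reference outcome label(s) outside the universe: %s",
                          paste(stray, collapse = ", ")))
  out
}
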