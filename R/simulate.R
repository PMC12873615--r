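# Seeded synthetic-overview generator.

#' Configure the synthetic-overview generator
#'
#' Parameters of [generateOverview()]. The defaults emulate a typical
#' intervention overview: 15 systematic reviews (the median observed among
#' published overviews) searching over a five-year window, 80 candidate
#' primary studies, a mean inclusion propensity of 0.15 (roughly a dozen
#' studies per review), occasional companion reports, and a tenth of the
#' studies published after the earliest search date so that structural
#' zeros exist.
#'
#' @param nReviews number of systematic reviews (>= 2).
#' @param nStudies number of primary studies.
#' @param inclusionProb mean per-study inclusion propensity: the
#'   probability that a given review includes a given (reachable) study.
#' @param popularityConcentration concentration of the Beta distribution
#'   the per-study propensities are drawn from (mean `inclusionProb`);
#'   small values make a few studies much more cited than others, `Inf`
#'   makes every propensity exactly `inclusionProb`.
#' @param threadMeanExtraRefs mean number of extra references per study
#'   beyond the first (Poisson); 0 gives singleton publication threads.
#' @param lateFraction fraction of studies published after the earliest
#'   review search date, creating structurally missing cells.
#' @param nOutcomes number of outcome labels (`O1` is the main outcome).
#' @param reviewOutcomeProb probability a review reports each non-main
#'   outcome.
#' @param studyOutcomeProb probability a study contributes to each outcome.
#' @param mainOutcomeReviewProb probability a review is relevant to the
#'   main outcome (`covers_main_outcome`).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return a [GeneratorConfig-class].
#' @export
generatorConfig <- function(nReviews = 15L, nStudies = 80L,
                            inclusionProb = 0.15,
                            popularityConcentration = 10,
                            threadMeanExtraRefs = 0.2,
                            lateFraction = 0.1,
                            nOutcomes = 4L,
                            reviewOutcomeProb = 0.5,
                            studyOutcomeProb = 0.5,
                            mainOutcomeReviewProb = 0.7,
                            seed = 1L) {
  methods::new("GeneratorConfig",
               nReviews = as.integer(nReviews), nStudies = as.integer(nStudies),
               inclusionProb = inclusionProb,
               popularityConcentration = popularityConcentration,
               threadMeanExtraRefs = threadMeanExtraRefs,
               lateFraction = lateFraction, nOutcomes = as.integer(nOutcomes),
               reviewOutcomeProb = reviewOutcomeProb,
               studyOutcomeProb = studyOutcomeProb,
               mainOutcomeReviewProb = mainOutcomeReviewProb,
               seed = as.integer(seed))
}

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    "GeneratorConfig: %d reviews x %d studies, inclusion propensity %.2f (concentration %s)\n",
    object@nReviews, object@nStudies, object@inclusionProb,
    format(object@popularityConcentration)))
  cat(sprintf("  threads: mean %.2f extra refs; late fraction %.2f; %d outcomes; seed %d\n",
              object@threadMeanExtraRefs, object@lateFraction,
              object@nOutcomes, object@seed))
})

# Deterministic sub-streams: each generation phase reseeds from seed+offset
# so adding entities of one class does not perturb the draws of another.
.withSubstream <- function(seed, offset, expr) {
  set.seed((seed + offset) %% .Machine$integer.max)
  expr
}

#' Generate a synthetic overview dataset
#'
#' Draws a complete [OverviewDataset-class] with controlled overlap
#' structure: review search dates spread over 2016--2020; study publication
#' dates with a `lateFraction` share postdating the earliest search date;
#' per-study inclusion propensities from a Beta distribution with mean
#' `inclusionProb`; publication threads of 1 + Poisson(`threadMeanExtraRefs`)
#' references; and outcome labels on both axes with the configured
#' probabilities, the main outcome guaranteed non-empty on each axis. A
#' review can only include a study whose publication date does not exceed
#' the review's search date (equal dates are reachable), and cites one or
#' more of the thread's reachable references when it does. All references
#' of a thread share the study's outcome labels.
#'
#' The output is fully reproducible from `config@seed`; the caller's RNG
#' state is left untouched.
#'
#' @param config a [GeneratorConfig-class].
#' @return an [OverviewDataset-class] that passes [validateDataset()].
#' @examples
#' ds <- generateOverview(generatorConfig(nReviews = 6, nStudies = 40, seed = 42))
#' overallCCA(buildMatrix(ds))
#' @export
generateOverview <- function(config) {
  stopifnot(methods::is(config, "GeneratorConfig"))
  methods::validObject(config)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  nR <- config@nReviews
  nS <- config@nStudies
  seed <- config@seed

  windowStart <- as.Date("2016-01-01")
  windowEnd <- as.Date("2020-12-31")
  searchDates <- .withSubstream(seed, 1L, {
    windowStart + sample.int(as.integer(windowEnd - windowStart) + 1L,
                             nR, replace = TRUE) - 1L
  })
  earliestSearch <- min(searchDates)

  studyDates <- .withSubstream(seed, 2L, {
    late <- stats::runif(nS) < config@lateFraction
    d <- rep(as.Date(NA), nS)
    earlySpan <- as.integer(earliestSearch - as.Date("2005-01-01"))
    d[!late] <- as.Date("2005-01-01") +
      sample.int(earlySpan + 1L, sum(!late), replace = TRUE) - 1L
    lateSpan <- as.integer(as.Date("2022-12-31") - earliestSearch)
    if (any(late))
      d[late] <- earliestSearch + sample.int(lateSpan, sum(late), replace = TRUE)
    d
  })

  p <- config@inclusionProb
  k <- config@popularityConcentration
  propensity <- .withSubstream(seed, 3L, {
    if (is.infinite(k) || p %in% c(0, 1)) rep(p, nS)
    else stats::rbeta(nS, p * k, (1 - p) * k)
  })

  studyIds <- sprintf("S%04d", seq_len(nS))
  refTab <- .withSubstream(seed, 4L, {
    nRefs <- 1L + stats::rpois(nS, config@threadMeanExtraRefs)
    studyIdx <- rep(seq_len(nS), nRefs)
    refNum <- sequence(nRefs)
    offs <- integer(length(studyIdx))
    extra <- refNum > 1L  # companion reports appear up to a year later
    offs[extra] <- sample.int(365L, sum(extra), replace = TRUE)
    data.frame(reference_id = sprintf("%s.R%d", studyIds[studyIdx], refNum),
               study_id = studyIds[studyIdx],
               publication_date = studyDates[studyIdx] + offs,
               study_idx = studyIdx)
  })

  labels <- sprintf("O%d", seq_len(config@nOutcomes))
  mainLab <- labels[1L]
  outcomeDraw <- .withSubstream(seed, 5L, {
    coversMain <- stats::runif(nR) < config@mainOutcomeReviewProb
    if (!any(coversMain)) coversMain[1L] <- TRUE
    revOut <- lapply(seq_len(nR), function(i) {
      others <- labels[-1L][stats::runif(config@nOutcomes - 1L) <
                              config@reviewOutcomeProb]
      out <- c(if (coversMain[i]) mainLab, others)
      if (!length(out)) out <- sample(labels, 1L)
      out
    })
    coversMain <- vapply(revOut, function(o) mainLab %in% o, logical(1L))
    stuOut <- lapply(seq_len(nS), function(s) {
      out <- labels[stats::runif(config@nOutcomes) < config@studyOutcomeProb]
      if (!length(out)) out <- sample(labels, 1L)
      out
    })
    if (!any(vapply(stuOut, function(o) mainLab %in% o, logical(1L))))
      stuOut[[1L]] <- unique(c(mainLab, stuOut[[1L]]))
    list(coversMain = coversMain, revOut = revOut, stuOut = stuOut)
  })

  reviewIds <- sprintf("SR%02d", seq_len(nR))
  refsByStudy <- split(seq_len(nrow(refTab)), refTab$study_idx)
  drawInclusions <- function(offset) .withSubstream(seed, offset, {
    rows <- vector("list", nR)
    for (i in seq_len(nR)) {
      hitStudy <- studyDates <= searchDates[i] &
        stats::runif(nS) < propensity
      refReach <- refTab$publication_date <= searchDates[i]
      # each reachable member of a hit thread is cited independently;
      # a hit study with no cited member gets one reachable member forced
      cited <- hitStudy[refTab$study_idx] & refReach &
        stats::runif(nrow(refTab)) < 0.5
      citedPerStudy <- tabulate(refTab$study_idx[cited], nS)
      for (s in which(hitStudy & citedPerStudy == 0L)) {
        cand <- refsByStudy[[s]][refReach[refsByStudy[[s]]]]
        cited[cand[sample.int(length(cand), 1L)]] <- TRUE
      }
      rows[[i]] <- data.frame(review_id = rep(reviewIds[i], sum(cited)),
                              reference_id = refTab$reference_id[cited])
    }
    do.call(rbind, rows)
  })
  incTab <- NULL
  for (attempt in seq_len(100L)) {
    incTab <- drawInclusions(6L + attempt - 1L)
    if (nrow(incTab) > 0L) break
  }
  if (is.null(incTab) || nrow(incTab) == 0L)
    stop(sprintf(
      "generator produced no eligible inclusions after 100 attempts (inclusionProb = %g, lateFraction = %g); increase inclusionProb or nStudies",
      p, config@lateFraction))

  OverviewDataset(
    reviews = S4Vectors::DataFrame(
      review_id = reviewIds,
      search_date = searchDates,
      covers_main_outcome = outcomeDraw$coversMain,
      outcomes = IRanges::CharacterList(outcomeDraw$revOut)),
    references = S4Vectors::DataFrame(
      reference_id = refTab$reference_id,
      study_id = refTab$study_id,
      publication_date = refTab$publication_date,
      outcomes = IRanges::CharacterList(
        outcomeDraw$stuOut[match(refTab$study_id, studyIds)])),
    inclusions = incTab,
    mainOutcome = mainLab,
    outcomeUniverse = labels)
}

#' Expected pairwise CCA for independent inclusion
#'
#' For two reviews that each include any given study independently with
#' probability `p`, conditional on the study appearing in at least one of
#' them, the expected pairwise CCA (equivalently the expected Jaccard
#' overlap of the two study sets, in the large-sample limit) is
#' \deqn{100 \cdot \frac{p}{2 - p}.}
#' Derivation: conditional on membership in the union, the three outcomes
#' (only A, only B, both) have probabilities proportional to
#' p(1-p), p(1-p), p^2, so the both-fraction is p^2 / (2p - p^2) = p/(2-p).
#' Used as a closed-form oracle for parameter-recovery tests of
#' [generateOverview()].
#'
#' @param p per-study inclusion probability, in (0, 1].
#' @return the expected pairwise CCA as a percentage.
#' @examples
#' expectedPairwiseCCA(0.5)  # 33.33...
#' @export
expectedPairwiseCCA <- function(p) {
  if (any(p <= 0)) stop("p must be positive: with p = 0 no study is in the union")
  if (any(p > 1)) stop("p must be a probability in (0, 1]")
  100 * p / (2 - p)
}
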