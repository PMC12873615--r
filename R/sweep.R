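# Sixteen-scenario sensitivity sweep and impact quantification.

#' Run all sixteen matrix-construction scenarios on one overview
#'
#' Builds the evidence matrix for every scenario from
#' [enumerateScenarios()], computes overall and pairwise CCA for each, and
#' collects the per-scenario cell counts and pairwise summaries into a
#' [SweepResult-class]. A scenario whose matrix cannot be constructed (for
#' example, scope adjustment on an overview where no review covers the main
#' outcome) is recorded as `NA` with the error message in its note; it
#' never aborts the sweep. The sweep is deterministic: two runs on the same
#' dataset give identical records.
#'
#' @param dataset an [OverviewDataset-class].
#' @param outcome outcome label for the outcome-level scenarios (9--16);
#'   defaults to the dataset's main outcome.
#' @return a [SweepResult-class] with exactly 16 records.
#' @examples
#' ds <- generateOverview(generatorConfig(seed = 2))
#' sw <- runScenarioSweep(ds)
#' sw
#' impactRange(sw, "overall")
#' @export
runScenarioSweep <- function(dataset, outcome = NULL) {
  stopifnot(methods::is(dataset, "OverviewDataset"))
  specs <- enumerateScenarios()
  if (is.null(outcome)) outcome <- dataset@mainOutcome
  n <- length(specs)
  rec <- S4Vectors::DataFrame(
    scenario = vapply(specs, function(s) s@index, integer(1L)),
    level = vapply(specs, function(s) s@level, character(1L)),
    adjust_scope = vapply(specs, function(s) s@adjustScope, logical(1L)),
    adjust_threads = vapply(specs, function(s) s@adjustThreads, logical(1L)),
    adjust_missingness = vapply(specs, function(s) s@adjustMissingness, logical(1L)),
    outcome = vapply(specs, function(s)
      if (s@level == "outcome") outcome else NA_character_, character(1L)),
    overall_cca = rep(NA_real_, n),
    N = rep(NA_integer_, n), r = rep(NA_integer_, n),
    c = rep(NA_integer_, n), SZ = rep(NA_integer_, n),
    pairwise_median = rep(NA_real_, n), pairwise_q1 = rep(NA_real_, n),
    pairwise_q3 = rep(NA_real_, n), pairwise_min = rep(NA_real_, n),
    pairwise_max = rep(NA_real_, n), n_pairs = rep(NA_integer_, n),
    n_undefined_pairs = rep(NA_integer_, n),
    note = rep(NA_character_, n))
  results <- vector("list", n)
  names(results) <- sprintf("scenario_%02d", seq_len(n))

  for (k in seq_len(n)) {
    notes <- character()
    res <- withCallingHandlers(
      tryCatch({
        m <- applyScenario(dataset, specs[[k]], outcome = outcome)
        if (ncol(m) >= 2L) pairwiseCCA(m) else overallCCA(m)
      }, error = function(e) {
        notes <<- c(notes, conditionMessage(e))
        NULL
      }),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (!is.null(res)) {
      rec$overall_cca[k] <- res@overall
      rec$N[k] <- res@N; rec$r[k] <- res@r
      rec$c[k] <- res@c; rec$SZ[k] <- res@SZ
      if (is.na(res@overall)) notes <- c(notes, res@undefinedReason)
      s <- res@pairwiseSummary
      if (length(s)) {
        rec$pairwise_median[k] <- s$median
        rec$pairwise_q1[k] <- s$q1; rec$pairwise_q3[k] <- s$q3
        rec$pairwise_min[k] <- s$min; rec$pairwise_max[k] <- s$max
        rec$n_pairs[k] <- s$n_pairs
        rec$n_undefined_pairs[k] <- s$n_undefined
      }
      results[[k]] <- res
    }
    if (length(notes)) rec$note[k] <- paste(unique(notes), collapse = "; ")
  }
  methods::new("SweepResult", records = rec, results = results,
               outcome = outcome)
}

#' SweepResult accessors
#'
#' `sweepRecords()` returns the 16-row per-scenario `DataFrame`;
#' `sweepResults()` the list of full [CCAResult-class] objects (with the
#' pairwise matrices), `NULL` where a scenario failed.
#'
#' @param x a [SweepResult-class].
#' @name SweepResult
NULL

#' @rdname SweepResult
#' @export
setMethod("sweepRecords", "SweepResult", function(x) x@records)

#' @rdname SweepResult
#' @export
setMethod("sweepResults", "SweepResult", function(x) x@results)

setMethod("show", "SweepResult", function(object) {
  rec <- object@records
  cat(sprintf("SweepResult: 16 scenarios (outcome level uses '%s')\n",
              object@outcome))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%5.1f", v))
  for (k in seq_len(nrow(rec))) {
    adj <- c("S", "T", "M")[unlist(rec[k, c("adjust_scope", "adjust_threads",
                                            "adjust_missingness")])]
    cat(sprintf("  %2d %-8s %-3s overall %s  pairwise median %s\n",
                rec$scenario[k], rec$level[k],
                if (length(adj)) paste(adj, collapse = "") else "-",
                fmt(rec$overall_cca[k]), fmt(rec$pairwise_median[k])))
  }
  ok <- sum(!is.na(rec$overall_cca))
  if (ok >= 2L)
    cat(sprintf("  impact (max - min): overall %.1f, pairwise median %.1f\n",
                impactRange(object, "overall"),
                tryCatch(impactRange(object, "pairwise-median"),
                         error = function(e) NA_real_)))
})

#' Impact of matrix-construction assumptions
#'
#' The impact of the assumptions on an overview is the difference between
#' the maximum and minimum CCA values observed across the sixteen
#' scenarios, computed either on the overall CCA or on the per-scenario
#' median pairwise CCA (the boxplot centre). Undefined scenarios are
#' excluded; fewer than two defined values make the impact itself
#' undefined and raise an error.
#'
#' @param sweep a [SweepResult-class].
#' @param method `"overall"` or `"pairwise-median"`.
#' @return the impact as a percentage-point difference (>= 0).
#' @export
impactRange <- function(sweep, method = c("overall", "pairwise-median")) {
  stopifnot(methods::is(sweep, "SweepResult"))
  method <- match.arg(method)
  v <- switch(method,
              "overall" = sweep@records$overall_cca,
              "pairwise-median" = sweep@records$pairwise_median)
  v <- v[!is.na(v)]
  if (length(v) < 2L)
    stop("impact undefined: fewer than 2 scenarios with a defined value")
  max(v) - min(v)
}

#' Label the magnitude of a CCA change across scenarios
#'
#' Operational, non-normative categories for the absolute change in CCA
#' across scenarios: minimal if the change is at most 5 percentage points,
#' moderate if above 5 and below 10, marked if 10 or more.
#'
#' @param delta numeric vector of non-negative CCA changes (percentage
#'   points).
#' @return character vector among `"minimal"`, `"moderate"`, `"marked"`.
#' @examples
#' classifyChange(c(1.4, 5.7, 13.5))
#' @export
classifyChange <- function(delta) {
  if (any(is.na(delta))) stop("cannot classify an undefined change")
  if (any(delta < 0)) stop("change in CCA must be non-negative")
  ifelse(delta <= 5, "minimal", ifelse(delta < 10, "moderate", "marked"))
}
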