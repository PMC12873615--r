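# Corrected covered area: overall, pairwise, and interpretation bands.

.ccaCounts <- function(st) {
  list(N = sum(st == CELL_INCLUDED), r = nrow(st), c = ncol(st),
       SZ = sum(st == CELL_STRUCTURAL_MISSING))
}

.ccaFromCounts <- function(N, r, c, SZ) {
  if (c < 2L) return(list(value = NA_real_, reason = "CCA requires >=2 reviews"))
  if (r < 1L) return(list(value = NA_real_, reason = "empty matrix"))
  denom <- r * c - r - SZ
  if (denom <= 0)
    return(list(value = NA_real_, reason = "fully saturated/empty denominator"))
  list(value = 100 * (N - r) / denom, reason = NA_character_)
}

#' Corrected covered area (CCA)
#'
#' The CCA answers: of all the study entries in the matrix, what proportion
#' are duplicates? With N the total number of included cells, r the number
#' of rows (unique references or studies), c the number of reviews and SZ
#' the number of structural zeros,
#'
#' \deqn{CCA = 100 \cdot \frac{N - r}{r c - r - SZ}}
#'
#' On a matrix without structural-missingness marking SZ = 0 and this is
#' the classical corrected covered area; on a marked matrix the structural
#' zeros are removed from the denominator, which can only increase the
#' value (`adjustDenominator = FALSE` recovers the unadjusted figure on the
#' same matrix).
#'
#' `overallCCA()` computes the statistic over the whole matrix.
#' `pairwiseCCA()` computes it for every unordered pair of reviews: the
#' matrix is restricted to the two columns, rows with no included cell in
#' either are dropped, and the same formula is applied with c = 2 (SZ
#' counted within the retained sub-matrix by default; `globalSZ = TRUE`
#' reuses the whole-matrix count instead). On an unadjusted matrix the
#' pairwise CCA of reviews A and B is algebraically the Jaccard index of
#' their study sets: 100 times the intersection over the union.
#'
#' A CCA that cannot be computed (fewer than two reviews, an empty matrix,
#' or a non-positive denominator) is reported as `NA` with a reason, never
#' as 0: "no comparable evidence" and "no overlap" are different findings.
#' Pairwise summary statistics (median and linear-interpolation quartiles)
#' are taken over defined pairs only, with the undefined count reported
#' alongside.
#'
#' @param x an [EvidenceMatrix-class].
#' @param ... passed to methods.
#' @param adjustDenominator subtract structural zeros from the denominator
#'   (default `TRUE`; irrelevant when the matrix carries none).
#' @param globalSZ for `pairwiseCCA()`, count structural zeros over the
#'   whole matrix instead of each pair's sub-matrix.
#' @return a [CCAResult-class].
#' @examples
#' ds <- generateOverview(generatorConfig(seed = 5))
#' m <- buildMatrix(ds)
#' overallCCA(m)
#' res <- pairwiseCCA(m)
#' pairwiseSummary(res)
#' @name cca
NULL

#' @rdname cca
#' @export
setMethod("overallCCA", "EvidenceMatrix",
          function(x, adjustDenominator = TRUE) {
  st <- cellStates(x)
  cnt <- .ccaCounts(st)
  res <- .ccaFromCounts(cnt$N, cnt$r, cnt$c,
                        if (adjustDenominator) cnt$SZ else 0L)
  methods::new("CCAResult", overall = res$value, undefinedReason = res$reason,
               N = as.integer(cnt$N), r = as.integer(cnt$r),
               c = as.integer(cnt$c), SZ = as.integer(cnt$SZ))
})

#' @rdname cca
#' @export
setMethod("pairwiseCCA", "EvidenceMatrix",
          function(x, adjustDenominator = TRUE, globalSZ = FALSE) {
  st <- cellStates(x)
  cnt <- .ccaCounts(st)
  if (cnt$c < 2L) stop("pairwise CCA requires >=2 reviews")
  ids <- colnames(st)
  pw <- matrix(NA_real_, cnt$c, cnt$c, dimnames = list(ids, ids))
  for (i in seq_len(cnt$c - 1L)) {
    for (j in seq(i + 1L, cnt$c)) {
      sub <- st[, c(i, j), drop = FALSE]
      keep <- rowSums(sub == CELL_INCLUDED) > 0L
      sub <- sub[keep, , drop = FALSE]
      r2 <- nrow(sub)
      N2 <- sum(sub == CELL_INCLUDED)
      SZ2 <- if (!adjustDenominator) 0L
             else if (globalSZ) cnt$SZ
             else sum(sub == CELL_STRUCTURAL_MISSING)
      v <- .ccaFromCounts(N2, r2, 2L, SZ2)
      pw[i, j] <- pw[j, i] <- v$value
    }
  }
  vals <- pw[upper.tri(pw)]
  defined <- vals[!is.na(vals)]
  q <- if (length(defined)) stats::quantile(defined, c(0.25, 0.5, 0.75),
                                            names = FALSE, type = 7)
       else rep(NA_real_, 3L)
  summ <- list(median = q[2L], q1 = q[1L], q3 = q[3L],
               min = if (length(defined)) min(defined) else NA_real_,
               max = if (length(defined)) max(defined) else NA_real_,
               n_pairs = length(vals), n_undefined = sum(is.na(vals)))
  ov <- .ccaFromCounts(cnt$N, cnt$r, cnt$c,
                       if (adjustDenominator) cnt$SZ else 0L)
  methods::new("CCAResult", overall = ov$value, undefinedReason = ov$reason,
               N = as.integer(cnt$N), r = as.integer(cnt$r),
               c = as.integer(cnt$c), SZ = as.integer(cnt$SZ),
               pairwise = pw, pairwiseSummary = summ)
})

#' CCAResult accessors
#'
#' `ccaValue()` returns the overall CCA percentage (`NA` if undefined),
#' `pairwiseValues()` the symmetric pairwise matrix, and
#' `pairwiseSummary()` the list of summary statistics over defined pairs.
#'
#' @param x a [CCAResult-class].
#' @name CCAResult
NULL

#' @rdname CCAResult
#' @export
setMethod("ccaValue", "CCAResult", function(x) x@overall)

#' @rdname CCAResult
#' @export
setMethod("pairwiseValues", "CCAResult", function(x) x@pairwise)

#' @rdname CCAResult
#' @export
setMethod("pairwiseSummary", "CCAResult", function(x) x@pairwiseSummary)

setMethod("show", "CCAResult", function(object) {
  if (is.na(object@overall)) {
    cat(sprintf("CCAResult: overall CCA undefined (%s)\n", object@undefinedReason))
  } else {
    cat(sprintf("CCAResult: overall CCA = %.1f%% (%s overlap)\n",
                object@overall, classifyOverlap(object@overall)))
  }
  cat(sprintf("  N = %d, r = %d, c = %d, SZ = %d\n",
              object@N, object@r, object@c, object@SZ))
  s <- object@pairwiseSummary
  if (length(s))
    cat(sprintf("  pairwise: median %.1f%% [Q1 %.1f, Q3 %.1f], range %.1f-%.1f over %d pair(s) (%d undefined)\n",
                s$median, s$q1, s$q3, s$min, s$max, s$n_pairs, s$n_undefined))
})

#' Interpret a CCA value against the published overlap bands
#'
#' The conventional (and avowedly arbitrary) interpretation thresholds are
#' <5% slight, 5--10% moderate, 10--15% high and >15% very high overlap.
#' Because the published bands are ambiguous exactly at 5, 10 and 15, this
#' package fixes the convention `[0,5)` slight, `[5,10)` moderate,
#' `[10,15]` high, `(15,100]` very high: the strict inequalities printed at
#' the outer bands are honoured and the high band is closed at both ends.
#'
#' @param cca numeric vector of CCA percentages in `[0, 100]`; `NA` is an
#'   error (an undefined CCA cannot be classified).
#' @return character vector with values among `"slight"`, `"moderate"`,
#'   `"high"`, `"very high"`.
#' @examples
#' classifyOverlap(c(4.9, 5, 10, 15, 15.1))
#' @export
classifyOverlap <- function(cca) {
  if (any(is.na(cca))) stop("cannot classify undefined CCA")
  if (any(cca < 0 | cca > 100)) stop("CCA must lie in [0, 100]")
  ifelse(cca < 5, "slight",
         ifelse(cca < 10, "moderate",
                ifelse(cca <= 15, "high", "very high")))
}
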