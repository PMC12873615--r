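test_that("the overall CCA formula reproduces hand-computed cases", {
  # 3 reviews each including the same 4 studies: complete overlap
  sat <- stateMatrix(matrix(1L, 4, 3))
  expect_equal(ccaValue(overallCCA(sat)), 100)

  # every study in exactly one review: no overlap
  disj <- stateMatrix(diag(3) * 1L)
  expect_equal(ccaValue(overallCCA(disj)), 0)

  # r = 10, c = 4, N = 16 -> 100*6/30 = 20, cross-checked by cell counting
  st <- matrix(0L, 10, 4)
  st[cbind(1:10, rep(1:4, length.out = 10))] <- 1L   # one inclusion per row
  st[cbind(1:6, rep(2:4, length.out = 6))] <- 1L     # six duplicate entries
  stopifnot(sum(st) == 16L)
  m <- stateMatrix(st)
  expect_equal(ccaValue(overallCCA(m)), 20)
  expect_equal(ccaValue(overallCCA(m)), bruteForceCCA(st))

  # toy overview: N = 9, r = 6, c = 3
  res <- overallCCA(buildMatrix(toyDataset()))
  expect_identical(c(res@N, res@r, res@c, res@SZ), c(9L, 6L, 3L, 0L))
  expect_equal(ccaValue(res), 25)
})

test_that("structural zeros shrink only the denominator", {
  # r = 3, c = 2, N = 5, SZ = 1
  st <- matrix(c(1L, 1L, 1L, 1L, 1L, 2L), 3, 2)
  m <- stateMatrix(st)
  resAdj <- overallCCA(m)
  resRaw <- overallCCA(m, adjustDenominator = FALSE)
  expect_equal(ccaValue(resRaw), 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(ccaValue(resAdj), 100)
  expect_identical(resAdj@SZ, 1L)
  expect_identical(resAdj@N, resRaw@N)
})

test_that("formula matches the per-row duplicate-counting oracle", {
  set.seed(404)
  for (k in 1:200) {
    st <- randomStateMatrix(sample(2:25, 1L), sample(2:8, 1L),
                            pInc = stats::runif(1, 0.1, 0.9),
                            pSM = stats::runif(1, 0, 0.4))
    m <- stateMatrix(st)
    expect_equal(ccaValue(overallCCA(m)), bruteForceCCA(st, adjust = TRUE))
    expect_equal(ccaValue(overallCCA(m, adjustDenominator = FALSE)),
                 bruteForceCCA(st, adjust = FALSE))
  }
})

test_that("pairwise CCA is the Jaccard overlap on unadjusted matrices", {
  # A = {s1,s2,s3}, B = {s2,s3,s4}: two shared of four -> 50%
  st <- matrix(c(1L, 1L, 1L, 0L,
                 0L, 1L, 1L, 1L), 4, 2,
               dimnames = list(paste0("s", 1:4), c("A", "B")))
  expect_equal(pairwiseValues(pairwiseCCA(stateMatrix(st)))["A", "B"], 50)
  # disjoint reviews
  expect_equal(pairwiseValues(pairwiseCCA(stateMatrix(diag(2) * 1L)))[1L, 2L], 0)
  # identical reviews
  expect_equal(pairwiseValues(pairwiseCCA(stateMatrix(matrix(1L, 3, 2))))[1L, 2L], 100)

  set.seed(808)
  for (k in 1:50) {
    st <- randomStateMatrix(sample(2:20, 1L), sample(2:6, 1L),
                            pInc = stats::runif(1, 0.1, 0.9))
    got <- pairwiseValues(pairwiseCCA(stateMatrix(st)))
    expect_equal(got, jaccardPairs(st))
  }
})

test_that("undefined CCA carries a reason and is never coerced to a number", {
  one <- stateMatrix(matrix(c(1L, 1L), 2, 1))
  res <- overallCCA(one)
  expect_true(is.na(ccaValue(res)))
  expect_match(res@undefinedReason, ">=2 reviews")
  expect_error(pairwiseCCA(one), ">=2 reviews")

  # structural zeros consuming the whole denominator: r*c - r - SZ = 0
  satRow <- stateMatrix(matrix(c(1L, 2L), 1, 2))
  expect_true(is.na(ccaValue(overallCCA(satRow))))
  expect_match(overallCCA(satRow)@undefinedReason, "denominator")
  expect_equal(ccaValue(overallCCA(satRow, adjustDenominator = FALSE)), 0)

  # a pair with structural zeros saturating its sub-matrix is NA, and the
  # summary is over defined pairs only
  st <- matrix(c(1L, 1L, 2L, 2L, 1L, 1L), 2, 3)
  res <- pairwiseCCA(stateMatrix(st))
  pw <- pairwiseValues(res)
  expect_true(is.na(pw[1L, 2L]))           # denominator r - SZ = 0
  s <- pairwiseSummary(res)
  expect_identical(s$n_pairs, 3L)
  expect_identical(s$n_undefined, 2L)
  expect_false(is.na(s$median))
})

test_that("missingness adjustment never lowers the overall CCA", {
  set.seed(77)
  for (k in 1:50) {
    st <- randomStateMatrix(sample(3:20, 1L), sample(2:6, 1L), pSM = 0.3)
    m <- stateMatrix(st)
    adj <- ccaValue(overallCCA(m))
    raw <- ccaValue(overallCCA(m, adjustDenominator = FALSE))
    if (!is.na(adj) && !is.na(raw)) expect_gte(adj, raw)
  }
})

test_that("CCA is invariant under row and column permutation", {
  set.seed(99)
  st <- randomStateMatrix(12, 5, pSM = 0.2)
  m <- stateMatrix(st)
  perm <- stateMatrix(st[sample(nrow(st)), sample(ncol(st))])
  expect_equal(ccaValue(overallCCA(m)), ccaValue(overallCCA(perm)))
  pw1 <- pairwiseValues(pairwiseCCA(m))
  pw2 <- pairwiseValues(pairwiseCCA(perm))
  expect_equal(pw1[rownames(pw2), colnames(pw2)], pw2)
})

test_that("CCA stays within [0, 100] on arbitrary valid matrices", {
  set.seed(321)
  for (k in 1:100) {
    st <- randomStateMatrix(sample(1:15, 1L), sample(2:7, 1L),
                            pInc = stats::runif(1, 0.05, 1),
                            pSM = stats::runif(1, 0, 0.5))
    v <- ccaValue(overallCCA(stateMatrix(st)))
    if (!is.na(v)) {
      expect_gte(v, 0)
      expect_lte(v, 100)
    }
  }
})

test_that("overlap bands follow the documented boundary convention", {
  expect_identical(classifyOverlap(c(0, 4.9, 5, 9.9, 10, 15, 15.1, 22.1, 100)),
                   c("slight", "slight", "moderate", "moderate", "high",
                     "high", "very high", "very high", "very high"))
  expect_error(classifyOverlap(NA_real_), "undefined")
  expect_error(classifyOverlap(101), "\\[0, 100\\]")
})
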