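test_that("the raw matrix honours the construction contract", {
  ds <- toyDataset()
  m <- buildMatrix(ds)
  st <- cellStates(m)
  expect_identical(dim(st), c(6L, 3L))
  expect_identical(rowMode(m), "reference")
  expect_identical(provenance(m), "raw")
  expect_true(all(rowSums(st == 1L) >= 1L))
  # every inclusion pair marked, nothing else
  expect_identical(sum(st == 1L), nrow(inclusions(ds)))
  expect_true(all(st[cbind(inclusions(ds)$reference_id,
                           inclusions(ds)$review_id)] == 1L))
  expect_true(all(st != 2L))
})

test_that("rows with no inclusion are dropped at construction", {
  ds <- toyDataset()
  ds@references <- rbind(
    ds@references,
    S4Vectors::DataFrame(reference_id = "orphan", study_id = "s9",
                         publication_date = as.Date("2012-01-01"),
                         outcomes = IRanges::CharacterList(list("pain"))))
  m <- buildMatrix(ds)
  expect_false("orphan" %in% rownames(m))
  expect_identical(nrow(m), 6L)
})

test_that("outcome level keeps only the reviews and rows with that outcome", {
  ds <- toyDataset()
  m <- buildMatrix(ds, level = "outcome", outcome = "pain")
  expect_setequal(colnames(m), c("SRA", "SRB"))   # SRC reports function only
  # brute-force filtering of the inclusion table as oracle
  keepRefs <- c("s1a", "s1b", "s2a", "s4a")       # refs with 'pain'
  inc <- as.data.frame(inclusions(ds))
  inc <- inc[inc$review_id %in% c("SRA", "SRB") & inc$reference_id %in% keepRefs, ]
  expect_setequal(rownames(m), unique(inc$reference_id))
  # s3a is cited by SRB too, but contributes no pain data -> gone
  expect_false("s3a" %in% rownames(m))
  # a reference included only by a review not covering the outcome drops out
  mf <- buildMatrix(ds, level = "outcome", outcome = "function")
  expect_setequal(colnames(mf), c("SRA", "SRC"))
  expect_false("s4a" %in% rownames(mf))

  expect_error(buildMatrix(ds, level = "outcome", outcome = "mortality"),
               "unknown outcome.*mortality")
  empty <- ds
  empty@reviews <- empty@reviews[0L, ]
  expect_error(buildMatrix(empty), "empty overview")
})

test_that("scope adjustment keeps main-outcome reviews and contributing rows", {
  ds <- toyDataset()
  m <- adjustScope(buildMatrix(ds))
  expect_setequal(colnames(m), c("SRA", "SRB"))   # SRC not relevant to main outcome
  expect_false("s5a" %in% rownames(m))            # contributes to no outcome
  expect_true("s3a" %in% rownames(m))             # still included by SRB

  # dropping the column holding a row's sole inclusion removes the row:
  # brute-force audit over all rows after the column filter
  st <- cellStates(buildMatrix(ds))
  survivors <- rownames(st)[rowSums(st[, c("SRA", "SRB"), drop = FALSE] == 1L) > 0L]
  survivors <- setdiff(survivors, "s5a")
  expect_setequal(rownames(m), survivors)

  # identity when every review covers the main outcome and rows contribute
  ds2 <- toyDataset()
  ds2@reviews$covers_main_outcome <- TRUE
  ds2@references$outcomes[[6L]] <- "pain"
  m2 <- adjustScope(buildMatrix(ds2))
  expect_identical(cellStates(m2), cellStates(buildMatrix(ds2)))

  none <- toyDataset()
  none@reviews$covers_main_outcome <- FALSE
  expect_error(adjustScope(buildMatrix(none)), "scope adjustment empties matrix")
})

test_that("thread collapse unions member citations per study", {
  ds <- toyDataset()
  m <- collapseThreads(buildMatrix(ds))
  expect_identical(rowMode(m), "study")
  st <- cellStates(m)
  # the two s1 reports were cited by different reviews -> one row in both
  expect_identical(st["s1", c("SRA", "SRB")], c(SRA = 1L, SRB = 1L))
  expect_identical(nrow(st), 5L)
  expect_error(collapseThreads(m), "already at study level")

  # singleton threads: identity up to row labels
  single <- ds
  single@references$study_id <- single@references$reference_id
  ms <- collapseThreads(buildMatrix(single))
  expect_identical(unname(cellStates(ms)), unname(cellStates(buildMatrix(single))))
})

test_that("collapsing a thread cited by one review shrinks N and r equally", {
  # 3 reports of one study all cited by the same review, plus 2 anchor studies
  ds <- OverviewDataset(
    reviews = data.frame(review_id = c("A", "B"),
                         search_date = "2020", covers_main_outcome = TRUE,
                         outcomes = "o"),
    references = data.frame(
      reference_id = c("t1", "t2", "t3", "u1", "v1"),
      study_id = c("T", "T", "T", "U", "V"),
      publication_date = "2010", outcomes = "o"),
    inclusions = data.frame(
      review_id = c("A", "A", "A", "A", "B", "B"),
      reference_id = c("t1", "t2", "t3", "u1", "u1", "v1")),
    mainOutcome = "o")
  before <- buildMatrix(ds)
  after <- collapseThreads(before)
  cntB <- overlapCCA:::.ccaCounts(cellStates(before))
  cntA <- overlapCCA:::.ccaCounts(cellStates(after))
  expect_identical(cntB$N - cntA$N, 2L)
  expect_identical(cntB$r - cntA$r, 2L)
  # at study granularity the pairwise study sets are what the collapsed
  # matrix reports: its pairwise CCA equals the study-set Jaccard oracle
  pwB <- jaccardPairs(cellStates(after))
  expect_equal(pairwiseValues(pairwiseCCA(after))["A", "B"], pwB["A", "B"])
})

test_that("structural missingness marks unreachable absences only", {
  ds <- toyDataset()
  m <- markStructuralMissingness(buildMatrix(ds))
  st <- cellStates(m)
  # s4a published 2019-01-01, SRC searched 2018-01-01, not included -> SM
  expect_identical(st["s4a", "SRC"], 2L)
  # reachable absences stay absent; inclusions untouched
  expect_identical(st["s3a", "SRA"], 0L)
  expect_identical(sum(st == 1L), sum(cellStates(buildMatrix(ds)) == 1L))

  # all rows published before all searches: identity
  early <- stateMatrix(matrix(c(1L, 0L, 0L, 1L), 2, 2))
  expect_identical(cellStates(markStructuralMissingness(early)),
                   cellStates(early))

  # equal dates are reachable (no structural zero)
  eq <- stateMatrix(matrix(c(1L, 1L, 0L, 1L), 2, 2),
                    pub = as.Date(c("2020-01-01", "2020-01-01")),
                    search = as.Date(c("2020-01-01", "2021-01-01")))
  expect_identical(sum(cellStates(markStructuralMissingness(eq)) == 2L), 0L)

  # an included-but-unreachable cell stays included with a data-quality warning
  odd <- stateMatrix(matrix(c(1L, 1L, 0L, 1L), 2, 2),
                     pub = as.Date(c("2021-06-01", "2010-01-01")),
                     search = as.Date(c("2020-01-01", "2022-01-01")))
  expect_warning(m2 <- markStructuralMissingness(odd), "data quality")
  expect_identical(cellStates(m2)[1L, 1L], 1L)

  # missing dates are an error naming the entities
  noDate <- stateMatrix(matrix(c(1L, 1L), 2, 1), pub = as.Date(c(NA, "2010-01-01")))
  expect_error(markStructuralMissingness(noDate), "x1")
})

test_that("the sixteen scenarios enumerate in the canonical order", {
  specs <- enumerateScenarios()
  expect_length(specs, 16L)
  expect_identical(vapply(specs, function(s) s@level, character(1L)),
                   rep(c("overview", "outcome"), each = 8L))
  key <- vapply(specs, function(s)
    paste(s@level, s@adjustScope, s@adjustThreads, s@adjustMissingness),
    character(1L))
  expect_identical(anyDuplicated(key), 0L)
  s1 <- specs[[1L]]
  expect_false(s1@adjustScope || s1@adjustThreads || s1@adjustMissingness)
  expect_true(specs[[2L]]@adjustScope &&
                !specs[[2L]]@adjustThreads && !specs[[2L]]@adjustMissingness)
  expect_true(specs[[3L]]@adjustThreads &&
                !specs[[3L]]@adjustScope && !specs[[3L]]@adjustMissingness)
  expect_true(specs[[4L]]@adjustMissingness &&
                !specs[[4L]]@adjustScope && !specs[[4L]]@adjustThreads)
  s16 <- specs[[16L]]
  expect_identical(s16@level, "outcome")
  expect_true(s16@adjustScope && s16@adjustThreads && s16@adjustMissingness)
  # flag patterns repeat identically across the two levels
  for (i in 1:8)
    expect_identical(
      c(specs[[i]]@adjustScope, specs[[i]]@adjustThreads, specs[[i]]@adjustMissingness),
      c(specs[[i + 8L]]@adjustScope, specs[[i + 8L]]@adjustThreads,
        specs[[i + 8L]]@adjustMissingness))
})

test_that("applyScenario equals the explicit composition", {
  ds <- generateOverview(generatorConfig(nReviews = 6, nStudies = 40,
                                         lateFraction = 0.2,
                                         threadMeanExtraRefs = 0.4, seed = 21))
  specs <- enumerateScenarios()
  expect_identical(cellStates(applyScenario(ds, specs[[1L]])),
                   cellStates(buildMatrix(ds)))
  manual <- markStructuralMissingness(collapseThreads(adjustScope(buildMatrix(ds))))
  auto <- applyScenario(ds, specs[[8L]])
  expect_identical(cellStates(auto), cellStates(manual))
  expect_identical(provenance(auto)@index, 8L)

  # scope is near-vacuous at outcome level when all reviews cover the outcome
  ds2 <- toyDataset()
  ds2@reviews$covers_main_outcome <- TRUE
  expect_identical(cellStates(applyScenario(ds2, specs[[9L]])),
                   cellStates(applyScenario(ds2, specs[[10L]])))
})

test_that("adjustments never create rows or inclusions", {
  for (seed in c(3, 17, 88)) {
    ds <- generateOverview(generatorConfig(nReviews = 8, nStudies = 50,
                                           threadMeanExtraRefs = 0.5,
                                           lateFraction = 0.25, seed = seed))
    m <- buildMatrix(ds)
    cnt <- overlapCCA:::.ccaCounts(cellStates(m))
    for (adj in list(adjustScope, collapseThreads)) {
      cnt2 <- overlapCCA:::.ccaCounts(cellStates(adj(m)))
      expect_lte(cnt2$N, cnt$N)
      expect_lte(cnt2$r, cnt$r)
    }
    cnt3 <- overlapCCA:::.ccaCounts(cellStates(markStructuralMissingness(m)))
    expect_identical(cnt3$N, cnt$N)
    expect_identical(cnt3$r, cnt$r)
  }
})

test_that("scope and thread adjustment commute when threads share outcomes", {
  for (seed in c(5, 41)) {
    ds <- generateOverview(generatorConfig(nReviews = 7, nStudies = 40,
                                           threadMeanExtraRefs = 0.6,
                                           seed = seed))
    m <- buildMatrix(ds)
    a <- collapseThreads(adjustScope(m))
    b <- adjustScope(collapseThreads(m))
    expect_identical(cellStates(a)[rownames(b), colnames(b)], cellStates(b))
  }
})
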