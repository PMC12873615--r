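# Fixtures and independent oracles shared across the suite.

# Hand-built overview: 3 reviews, 5 studies (one two-reference thread),
# dates chosen so that every adjustment has something to do.
#   state matrix (rows x reviews SRA/SRB/SRC):
#     s1a 1 0 0   s1b 0 1 0   s2a 1 1 1   s3a 0 1 1   s4a 0 1 0   s5a 1 0 0
#   N = 9, r = 6, c = 3  ->  overall CCA = 100*(9-6)/(18-6) = 25
toyDataset <- function() {
  OverviewDataset(
    reviews = data.frame(
      review_id = c("SRA", "SRB", "SRC"),
      search_date = c("2019-06-30", "2020-12-31", "2018-01-01"),
      covers_main_outcome = c(TRUE, TRUE, FALSE),
      outcomes = c("pain|function", "pain", "function")),
    references = data.frame(
      reference_id = c("s1a", "s1b", "s2a", "s3a", "s4a", "s5a"),
      study_id = c("s1", "s1", "s2", "s3", "s4", "s5"),
      publication_date = c("2015-03-01", "2015-09-01", "2016-01-01",
                           "2017-05-20", "2019-01-01", "2010-01-01"),
      outcomes = c("pain", "pain", "pain|function", "function", "pain", "")),
    inclusions = data.frame(
      review_id = c("SRA", "SRA", "SRA", "SRB", "SRB", "SRB", "SRB",
                    "SRC", "SRC"),
      reference_id = c("s1a", "s2a", "s5a", "s1b", "s2a", "s4a", "s3a",
                       "s3a", "s2a")),
    mainOutcome = "pain",
    outcomeUniverse = c("pain", "function"))
}

# Wrap a raw 0/1/2 integer state matrix into an EvidenceMatrix, with
# optional dates so missingness marking can be exercised.
stateMatrix <- function(state, pub = NULL, search = NULL, covers = NULL,
                        rowMode = "reference") {
  state <- matrix(as.integer(state), nrow(state), ncol(state),
                  dimnames = dimnames(state))
  if (is.null(rownames(state))) rownames(state) <- sprintf("x%d", seq_len(nrow(state)))
  if (is.null(colnames(state))) colnames(state) <- sprintf("R%d", seq_len(ncol(state)))
  if (is.null(pub)) pub <- rep(as.Date("2010-01-01"), nrow(state))
  if (is.null(search)) search <- rep(as.Date("2020-01-01"), ncol(state))
  if (is.null(covers)) covers <- rep(TRUE, ncol(state))
  rd <- S4Vectors::DataFrame(
    study_id = rownames(state), publication_date = as.Date(pub),
    outcomes = IRanges::CharacterList(rep(list("o"), nrow(state))),
    row.names = rownames(state))
  cd <- S4Vectors::DataFrame(
    search_date = as.Date(search), covers_main_outcome = covers,
    outcomes = IRanges::CharacterList(rep(list("o"), ncol(state))),
    row.names = colnames(state))
  overlapCCA:::.newEvidenceMatrix(state, rd, cd, rowMode = rowMode)
}

# Random state matrix where every row has at least one included cell and
# a pSM share of the absent cells is structurally missing.
randomStateMatrix <- function(r, c, pInc = 0.3, pSM = 0) {
  st <- matrix(ifelse(stats::runif(r * c) < pInc, 1L, 0L), r, c,
               dimnames = list(sprintf("x%d", seq_len(r)),
                               sprintf("R%d", seq_len(c))))
  for (i in seq_len(r))
    if (!any(st[i, ] == 1L)) st[i, sample.int(c, 1L)] <- 1L
  absent <- which(st == 0L)
  if (pSM > 0 && length(absent)) {
    sm <- absent[stats::runif(length(absent)) < pSM]
    st[sm] <- 2L
  }
  st
}

# Independent overall-CCA oracle: per-row duplicate counting. Each row
# contributes (included - 1) duplicates out of (c - 1 - structural zeros)
# duplication opportunities; CCA is the pooled duplicate fraction.
bruteForceCCA <- function(state, adjust = TRUE) {
  r <- nrow(state); cc <- ncol(state)
  if (cc < 2L || r < 1L) return(NA_real_)
  dup <- 0; opp <- 0
  for (i in seq_len(r)) {
    dup <- dup + sum(state[i, ] == 1L) - 1L
    opp <- opp + cc - 1L - if (adjust) sum(state[i, ] == 2L) else 0L
  }
  if (opp <= 0) return(NA_real_)
  100 * dup / opp
}

# Set-based pairwise oracle: 100 * |A n B| / |A u B| over included cells.
jaccardPairs <- function(state) {
  cc <- ncol(state)
  sets <- lapply(seq_len(cc), function(j) rownames(state)[state[, j] == 1L])
  out <- matrix(NA_real_, cc, cc, dimnames = list(colnames(state), colnames(state)))
  for (i in seq_len(cc - 1L)) for (j in seq(i + 1L, cc)) {
    u <- union(sets[[i]], sets[[j]])
    out[i, j] <- out[j, i] <-
      if (length(u)) 100 * length(intersect(sets[[i]], sets[[j]])) / length(u)
      else NA_real_
  }
  out
}
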