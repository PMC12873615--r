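# Readers and writers: overview datasets (3-CSV or JSON), evidence
# matrices (wide CSV + provenance sidecar), sweep results (long CSV + JSON).

.metadataHeader <- function(seed = NULL) {
  c(sprintf("# overlapCCA %s", as.character(utils::packageVersion("overlapCCA"))),
    "# scenario ordering: 1-8 overview level, 9-16 outcome level; per level: none, scope, threads, missingness, scope+threads, scope+missingness, threads+missingness, all",
    "# overlap bands: [0,5) slight, [5,10) moderate, [10,15] high, (15,100] very high",
    "# change bands: [0,5] minimal, (5,10) moderate, [10,Inf) marked",
    if (!is.null(seed)) sprintf("# seed: %d", seed))
}

.dsToTables <- function(dataset) {
  rev <- as.data.frame(dataset@reviews[, c("review_id", "search_date",
                                           "covers_main_outcome")])
  rev$outcomes <- .joinOutcomes(dataset@reviews$outcomes)
  ref <- as.data.frame(dataset@references[, c("reference_id", "study_id",
                                              "publication_date")])
  ref$outcomes <- .joinOutcomes(dataset@references$outcomes)
  rev <- rev[, c("review_id", "search_date", "covers_main_outcome", "outcomes")]
  ref <- ref[, c("reference_id", "study_id", "publication_date", "outcomes")]
  list(reviews = rev, references = ref,
       inclusions = as.data.frame(dataset@inclusions))
}

#' Write an overview dataset to disk
#'
#' Writes the documented three-CSV layout (`reviews.csv`, `references.csv`,
#' `inclusions.csv`; outcome labels `"|"`-separated, dates ISO-8601) plus a
#' `manifest.json` recording the main outcome and outcome universe, into
#' `dir`. [readOverviewDataset()] restores the dataset identically.
#'
#' @param dataset an [OverviewDataset-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeOverviewDataset <- function(dataset, dir) {
  stopifnot(methods::is(dataset, "OverviewDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- .dsToTables(dataset)
  paths <- file.path(dir, c("reviews.csv", "references.csv",
                            "inclusions.csv", "manifest.json"))
  utils::write.csv(tabs$reviews, paths[1L], row.names = FALSE)
  utils::write.csv(tabs$references, paths[2L], row.names = FALSE)
  utils::write.csv(tabs$inclusions, paths[3L], row.names = FALSE)
  jsonlite::write_json(
    list(main_outcome = dataset@mainOutcome,
         outcome_universe = dataset@outcomeUniverse),
    paths[4L], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read an overview dataset
#'
#' Reads either a directory holding the three-CSV layout written by
#' [writeOverviewDataset()] (with an optional `manifest.json` supplying the
#' main outcome and outcome universe) or a single JSON document with
#' `reviews`, `references`, `inclusions`, `main_outcome` and optional
#' `outcome_universe` fields. Dates may be full ISO-8601 or bare years.
#' The result is validated; violations are reported as a single aggregated
#' error listing every problem.
#'
#' @param path directory with the CSV tables, or a `.json` file.
#' @param mainOutcome main outcome label; overrides (or substitutes for) a
#'   manifest.
#' @return a validated [OverviewDataset-class].
#' @export
readOverviewDataset <- function(path, mainOutcome = NULL) {
  if (dir.exists(path)) {
    need <- file.path(path, c("reviews.csv", "references.csv", "inclusions.csv"))
    missing <- need[!file.exists(need)]
    if (length(missing))
      stop(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
    rev <- utils::read.csv(need[1L], colClasses = "character")
    ref <- utils::read.csv(need[2L], colClasses = "character")
    inc <- utils::read.csv(need[3L], colClasses = "character")
    universe <- NULL
    manifest <- file.path(path, "manifest.json")
    if (file.exists(manifest)) {
      man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
      if (is.null(mainOutcome)) mainOutcome <- man$main_outcome
      universe <- man$outcome_universe
    }
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    rev <- doc$reviews; ref <- doc$references; inc <- doc$inclusions
    if (is.null(mainOutcome)) mainOutcome <- doc$main_outcome
    universe <- doc$outcome_universe
  } else {
    stop(sprintf("input not found: '%s' (expected a directory or a .json file)",
                 path))
  }
  if (is.null(mainOutcome))
    stop("main outcome not given and no manifest provides one")
  .checkColumns(rev, c("review_id", "search_date", "covers_main_outcome",
                       "outcomes"), "reviews")
  .checkColumns(ref, c("reference_id", "study_id", "publication_date",
                       "outcomes"), "references")
  .checkColumns(inc, c("review_id", "reference_id"), "inclusions")
  rev$covers_main_outcome <- .parseLogical(rev$covers_main_outcome)
  ds <- OverviewDataset(rev, ref, inc, mainOutcome = mainOutcome,
                        outcomeUniverse = universe)
  viol <- validateDataset(ds)
  if (length(viol))
    stop(sprintf("dataset failed validation:\n  - %s",
                 paste(viol, collapse = "\n  - ")))
  ds
}

.checkColumns <- function(df, need, what) {
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(sprintf("%s table lacks column(s): %s", what,
                 paste(miss, collapse = ", ")))
}

.parseLogical <- function(x) {
  v <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[v %in% c("FALSE", "F", "0", "NO")] <- FALSE
  out
}

#' Write an evidence matrix as wide CSV
#'
#' One row per reference/study, one column per review; cells are `1`
#' (included), `0` (absent) or `"SM"` (structurally missing). A sidecar
#' JSON next to the CSV records the provenance: scenario index and flags
#' (or `"raw"`), row mode, level and outcome.
#'
#' @param x an [EvidenceMatrix-class].
#' @param file output CSV path; the sidecar is written to the same path
#'   with extension `.json`.
#' @return invisibly, the two paths written.
#' @export
writeEvidenceMatrix <- function(x, file) {
  stopifnot(methods::is(x, "EvidenceMatrix"))
  st <- cellStates(x)
  chr <- matrix(as.character(st), nrow(st), ncol(st), dimnames = dimnames(st))
  chr[st == CELL_STRUCTURAL_MISSING] <- "SM"
  df <- data.frame(row_id = rownames(st), chr, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  md <- S4Vectors::metadata(x)
  prov <- md$provenance
  provList <- if (methods::is(prov, "ScenarioSpec")) {
    list(scenario = prov@index, level = prov@level,
         adjust_scope = prov@adjustScope, adjust_threads = prov@adjustThreads,
         adjust_missingness = prov@adjustMissingness)
  } else list(scenario = as.character(prov))
  sidecar <- paste0(tools::file_path_sans_ext(file), ".json")
  jsonlite::write_json(
    c(provList, list(row_mode = md$rowMode, level = md$level,
                     outcome = md$outcome, adjustments = md$adjustments)),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(file, sidecar))
}

#' Read an evidence matrix from wide CSV
#'
#' Inverse of [writeEvidenceMatrix()] for the cell states. Row and column
#' annotations that the CSV does not carry (dates, outcome labels) are
#' filled with `NA`, so the result supports [overallCCA()] /
#' [pairwiseCCA()] but not re-running date-dependent adjustments. This is
#' also the entry point for externally constructed matrices (e.g. matrices
#' deposited alongside published overviews) saved in the same layout.
#'
#' @param file CSV path; a sidecar `.json` written by
#'   [writeEvidenceMatrix()] is honoured for the row mode if present.
#' @return an [EvidenceMatrix-class].
#' @export
readEvidenceMatrix <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, colClasses = "character")
  if (colnames(df)[1L] != "row_id")
    stop("first column must be 'row_id'")
  rowIds <- df$row_id
  cellChr <- as.matrix(df[, -1L, drop = FALSE])
  st <- matrix(CELL_ABSENT, nrow(cellChr), ncol(cellChr),
               dimnames = list(rowIds, colnames(cellChr)))
  st[cellChr == "1"] <- CELL_INCLUDED
  st[toupper(cellChr) == "SM"] <- CELL_STRUCTURAL_MISSING
  bad <- !cellChr %in% c("0", "1") & toupper(cellChr) != "SM"
  if (any(bad))
    stop(sprintf("unrecognised cell value(s): %s",
                 paste(unique(cellChr[bad]), collapse = ", ")))
  rowMode <- "reference"
  sidecar <- paste0(tools::file_path_sans_ext(file), ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$row_mode)) rowMode <- side$row_mode
  }
  rd <- S4Vectors::DataFrame(study_id = rowIds,
                             publication_date = rep(as.Date(NA), length(rowIds)),
                             outcomes = IRanges::CharacterList(
                               rep(list(character()), length(rowIds))),
                             row.names = rowIds)
  cd <- S4Vectors::DataFrame(search_date = rep(as.Date(NA), ncol(st)),
                             covers_main_outcome = rep(NA, ncol(st)),
                             outcomes = IRanges::CharacterList(
                               rep(list(character()), ncol(st))),
                             row.names = colnames(st))
  .newEvidenceMatrix(st, rd, cd, rowMode = rowMode, provenance = "imported")
}

#' Write sweep results
#'
#' Writes the sixteen-scenario sweep as a long-format CSV (one row per
#' scenario and method, overall and pairwise-median, with the cell counts
#' and any per-scenario note) and/or a JSON summary including the impact
#' ranges and their change categories. Every file begins with a metadata
#' header recording the tool version, the scenario-ordering and
#' band-boundary conventions, and the seed when given, so a run can be
#' reproduced from its outputs. Undefined values are written as `NA` (CSV)
#' or `null` (JSON), never as zeros.
#'
#' @param sweep a [SweepResult-class].
#' @param dir output directory (created if needed).
#' @param formats subset of `"csv"`, `"json"`, `"png"` (the `"png"` format
#'   saves the [plotSweep()] figure).
#' @param seed optional integer recorded in the metadata header.
#' @return invisibly, the paths written.
#' @export
writeSweepResults <- function(sweep, dir, formats = c("csv", "json"),
                              seed = NULL) {
  stopifnot(methods::is(sweep, "SweepResult"))
  unknown <- setdiff(formats, c("csv", "json", "png"))
  if (length(unknown))
    stop(sprintf("unknown format(s): %s", paste(unknown, collapse = ", ")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- as.data.frame(sweep@records)
  paths <- character()

  long <- rbind(
    data.frame(rec[, c("scenario", "level", "adjust_scope", "adjust_threads",
                       "adjust_missingness", "outcome")],
               method = "overall", cca = rec$overall_cca,
               n_pairs = NA_integer_, note = rec$note),
    data.frame(rec[, c("scenario", "level", "adjust_scope", "adjust_threads",
                       "adjust_missingness", "outcome")],
               method = "pairwise_median", cca = rec$pairwise_median,
               n_pairs = rec$n_pairs, note = rec$note))
  long <- long[order(long$scenario, long$method), ]

  impacts <- lapply(c(overall = "overall", pairwise_median = "pairwise-median"),
                    function(m) {
    tryCatch({
      d <- impactRange(sweep, m)
      list(impact = d, change_category = classifyChange(d))
    }, error = function(e) list(impact = NULL,
                                change_category = NULL,
                                note = conditionMessage(e)))
  })

  if ("csv" %in% formats) {
    p <- file.path(dir, "sweep_long.csv")
    writeLines(.metadataHeader(seed), p)
    suppressWarnings(utils::write.table(long, p, sep = ",", row.names = FALSE,
                                        col.names = TRUE, append = TRUE,
                                        qmethod = "double"))
    paths <- c(paths, p)
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "sweep_summary.json")
    jsonlite::write_json(list(
      metadata = list(
        tool = sprintf("overlapCCA %s",
                       as.character(utils::packageVersion("overlapCCA"))),
        scenario_ordering = "1-8 overview level, 9-16 outcome level; per level: none, scope, threads, missingness, scope+threads, scope+missingness, threads+missingness, all",
        overlap_bands = "[0,5) slight, [5,10) moderate, [10,15] high, (15,100] very high",
        change_bands = "[0,5] minimal, (5,10) moderate, [10,Inf) marked",
        seed = seed,
        outcome = sweep@outcome),
      scenarios = rec,
      impact = impacts),
      p, auto_unbox = TRUE, pretty = TRUE, na = "null", digits = NA)
    paths <- c(paths, p)
  }
  if ("png" %in% formats) {
    p <- file.path(dir, "sweep_boxplot.png")
    ggplot2::ggsave(p, plotSweep(sweep), width = 7, height = 6, dpi = 150)
    paths <- c(paths, p)
  }
  invisible(paths)
}
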