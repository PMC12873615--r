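# Internal helpers: date parsing and outcome-label handling.

#' Parse mixed-precision calendar dates
#'
#' Accepts ISO-8601 full dates (`"2019-03-14"`) or bare years (`"2019"`).
#' A bare year is canonicalised conservatively: review search dates resolve
#' to 31 December of that year and publication dates to 1 January, which
#' minimises false structural zeros when only year precision is available.
#'
#' @param x character vector of dates (or `Date`, returned as-is).
#' @param role `"search"` for review search dates, `"publication"` for
#'   reference publication dates; decides how a bare year is anchored.
#' @return a `Date` vector; unparseable entries become `NA`.
#' @export
parseMixedDate <- function(x, role = c("search", "publication")) {
  role <- match.arg(role)
  if (inherits(x, "Date")) return(x)
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  isYear <- grepl("^\\d{4}$", x)
  isFull <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(isYear)) {
    anchor <- if (role == "search") "-12-31" else "-01-01"
    out[isYear] <- as.Date(paste0(x[isYear], anchor))
  }
  if (any(isFull)) out[isFull] <- as.Date(x[isFull])
  out
}

# Canonical form used for all outcome-label comparisons: labels are free
# strings compared case-insensitively after whitespace trimming.
.outcomeKey <- function(x) tolower(trimws(x))

# TRUE where any element of `labels` matches `target` under the canonical
# comparison.
.hasOutcome <- function(labels, target) {
  .outcomeKey(target) %in% .outcomeKey(labels)
}

# Per-element membership test for a CharacterList column.
.eachHasOutcome <- function(charList, target) {
  vapply(as.list(charList), .hasOutcome, logical(1L), target = target)
}

.joinOutcomes <- function(charList) {
  vapply(as.list(charList), function(v) paste(v, collapse = "|"), character(1L))
}

.splitOutcomes <- function(x) {
  IRanges::CharacterList(lapply(strsplit(as.character(x), "|", fixed = TRUE),
                                function(v) trimws(v[nzchar(trimws(v))])))
}
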