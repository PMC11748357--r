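#' ICD-10 code table for manner-of-death classification
#'
#' The gold registry carries no manner variable; manner is derived from the
#' underlying cause of death (UCOD).  Entries are single ICD-10 codes
#' (optionally 4-character, e.g. `"Y87.0"`) or closed 3-character ranges
#' within one letter block (e.g. `"X60-X84"`).  The suicide and
#' undetermined sets must be disjoint.
#'
#' The default table follows the standard CDC groupings for intentional
#' self-harm and events of undetermined intent: suicide X60--X84, Y87.0,
#' U03; undetermined Y10--Y34, Y87.2, Y89.9.
#'
#' @param suicide character vector of codes/ranges classified as suicide.
#' @param undetermined character vector classified as undetermined intent.
#' @return an object of class `code_table`.
#' @export
#' @examples
#' ct <- code_table()
#' classify_manner(c("X70", "Y21", "I21", NA), ct)
code_table <- function(suicide = c("X60-X84", "Y87.0", "U03"),
                       undetermined = c("Y10-Y34", "Y87.2", "Y89.9")) {
  su <- parse_code_entries(suicide)
  un <- parse_code_entries(undetermined)
  if (entries_overlap(su, un)) {
    stopf("suicide and undetermined code sets overlap")
  }
  structure(list(suicide = su, undetermined = un), class = "code_table")
}

parse_code_entries <- function(entries) {
  out <- lapply(entries, function(e) {
    e0 <- e
    e <- gsub(".", "", toupper(trimws(e)), fixed = TRUE)
    if (grepl("^[A-Z][0-9]{2}-[A-Z][0-9]{2}$", e)) {
      lo <- substr(e, 1, 3)
      hi <- substr(e, 5, 7)
      if (substr(lo, 1, 1) != substr(hi, 1, 1) || lo > hi) {
        stopf("invalid code range: %s", e0)
      }
      list(kind = "range", lo = lo, hi = hi)
    } else if (grepl("^[A-Z][0-9]{2}[0-9A-Z]{0,2}$", e)) {
      list(kind = "prefix", prefix = e)
    } else {
      stopf("cannot parse code table entry: %s", e0)
    }
  })
  out
}

entry_codes3 <- function(entry) {
  # set of 3-character stems an entry can touch (for disjointness checking)
  if (entry$kind == "range") {
    letter <- substr(entry$lo, 1, 1)
    sprintf("%s%02d", letter,
            as.integer(substr(entry$lo, 2, 3)):as.integer(substr(entry$hi, 2, 3)))
  } else {
    substr(entry$prefix, 1, 3)
  }
}

entries_overlap <- function(a, b) {
  for (ea in a) {
    for (eb in b) {
      shared <- intersect(entry_codes3(ea), entry_codes3(eb))
      if (!length(shared)) next
      # a 3-char stem shared only through two distinct 4+ char prefixes
      # (Y87.0 vs Y87.2) is not an overlap
      if (ea$kind == "range" || eb$kind == "range") return(TRUE)
      pa <- ea$prefix
      pb <- eb$prefix
      if (startsWith(pa, pb) || startsWith(pb, pa)) return(TRUE)
    }
  }
  FALSE
}

code_in_entry <- function(code3, code, entry) {
  if (entry$kind == "range") {
    code3 >= entry$lo & code3 <= entry$hi
  } else if (nchar(entry$prefix) <= 3L) {
    code3 == entry$prefix
  } else {
    startsWith(code, entry$prefix)
  }
}

#' Classify manner of death from an underlying cause of death code
#'
#' Pure function: a code in the suicide ranges maps to `"suicide"`, in the
#' undetermined ranges to `"undetermined"`, anywhere else to `"other"`;
#' a missing code maps to `"unknown"`.
#'
#' @param ucod character vector of ICD-10 codes (dots tolerated) or `NA`.
#' @param codes a [code_table()].
#' @param record_id optional ids used to name an offending record when a
#'   code string is malformed.
#' @return character vector in `{"suicide","undetermined","other","unknown"}`.
#' @export
classify_manner <- function(ucod, codes = code_table(), record_id = NULL) {
  stopifnot(inherits(codes, "code_table"))
  x <- canonical_ucod(ucod)
  bad <- !is.na(x) & !grepl("^[A-Z][0-9]{2}[0-9A-Z]{0,2}$", x)
  if (any(bad)) {
    who <- if (!is.null(record_id)) record_id[bad][1] else which(bad)[1]
    stopf("malformed ICD-10 code '%s' (record %s)", ucod[bad][1], who)
  }
  out <- rep("other", length(x))
  out[is.na(x)] <- "unknown"
  ok <- !is.na(x)
  if (any(ok)) {
    c3 <- substr(x, 1, 3)
    in_set <- function(entries) {
      hit <- rep(FALSE, length(x))
      for (e in entries) hit[ok] <- hit[ok] | code_in_entry(c3[ok], x[ok], e)
      hit
    }
    out[in_set(codes$suicide)] <- "suicide"
    out[in_set(codes$undetermined)] <- "undetermined"
  }
  out
}
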