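#' Round half-up
#'
#' Commercial ("half-up") rounding, used everywhere a percentage is
#' reported: 0.125 at 2 dp becomes 0.13, not base R's banker's 0.12.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # small epsilon guards values sitting a binary ulp below the .5 boundary
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Percentage of a count over a total, half-up rounded
#'
#' @param n numerator count.
#' @param total denominator count; a zero total yields `NA` (the quantity
#'   is undefined, never reported as 0).
#' @param digits decimal places (default 2, the reporting convention).
#' @return numeric vector of percentages on the 0--100 scale.
#' @export
pct <- function(n, total, digits = 2) {
  out <- 100 * n / total
  out[rep_len(total == 0, length(out))] <- NA_real_
  round_half_up(out, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' State-year stratum label
#'
#' @param state 2-letter state code.
#' @param year calendar year.
#' @return character label, e.g. `"NY-2015"`.
#' @export
stratum_label <- function(state, year) paste(state, year, sep = "-")

# canonical renderings used in match keys and code comparison ---------------

canonical_ucod <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- gsub(".", "", x, fixed = TRUE)
  x[!nzchar(x) | is.na(x)] <- NA_character_
  x
}

canonical_letter <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[!nzchar(x) | is.na(x)] <- NA_character_
  x
}

canonical_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("m", "male")] <- "male"
  out[x %in% c("f", "female")] <- "female"
  out
}

# MCOD codes travel internally as a single space-separated canonical string
mcod_collapse <- function(df, prefix = "mcod") {
  cols <- paste0(prefix, seq_len(14))
  cols <- cols[cols %in% names(df)]
  if (!length(cols)) {
    return(rep("", nrow(df)))
  }
  m <- vapply(cols, function(cl) canonical_ucod(df[[cl]]), character(nrow(df)))
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1L)
  apply(m, 1L, function(r) paste(r[!is.na(r)], collapse = " "))
}

mcod_split <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  strsplit(x, " ", fixed = TRUE)
}

mcod_expand <- function(x) {
  codes <- mcod_split(x)
  out <- matrix(NA_character_, nrow = length(x), ncol = 14,
                dimnames = list(NULL, paste0("mcod", 1:14)))
  for (i in seq_along(codes)) {
    ci <- codes[[i]][nzchar(codes[[i]])]
    if (length(ci)) out[i, seq_along(ci)] <- ci
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

days_in_year <- function(year) {
  ifelse(year %% 4 == 0 & (year %% 100 != 0 | year %% 400 == 0), 366L, 365L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
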