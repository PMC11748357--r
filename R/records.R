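# Harmonized death-record schema shared by both registries.  MCOD codes are
# carried as one space-separated canonical string; `mcod1..mcod14` columns
# are the external CSV rendering (see read_registry()/write_harmonized()).
RECORD_COLUMNS <- c(
  "record_id", "source", "state", "year", "death_date", "age_at_death",
  "sex", "dmb", "filn", "ucod", "mcod", "manner", "military_history",
  "veteran_flag"
)

LINKAGE_VARIABLES <- c("age_at_death", "sex", "ucod", "dmb", "filn", "death_date")

mdr_required_cols <- c("record_id", "state", "year", "death_date",
                       "date_of_birth", "sex", "ucod", "filn")
nvdrs_required_cols <- c("record_id", "state", "year", "death_date",
                         "age_at_death", "dmb", "sex", "filn", "ucod",
                         "manner", "military_history")

validate_registry_schema <- function(raw, source) {
  req <- if (source == "MDR") mdr_required_cols else nvdrs_required_cols
  missing <- setdiff(req, names(raw))
  if (length(missing)) {
    stopf("%s input is missing required column(s): %s",
          source, paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

parse_date <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA
  suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
}

# completed calendar years between two dates (birthday rule)
completed_years <- function(birth, ref) {
  b <- as.POSIXlt(birth)
  r <- as.POSIXlt(ref)
  age <- r$year - b$year
  before_birthday <- (r$mon < b$mon) | (r$mon == b$mon & r$mday < b$mday)
  age - as.integer(before_birthday)
}

#' Harmonize a raw gold-registry (MDR-like) extract
#'
#' Derives day-of-month of birth and age at death from the date of birth,
#' then drops the date of birth entirely: no output of the package carries
#' a full date of birth.  Records with an unparseable (present but
#' invalid) date, or a death date preceding the birth date, are rejected;
#' the rejects and their reasons are attached as `attr(, "rejected")`.
#'
#' @param raw data frame with columns `record_id, state, year, death_date,
#'   date_of_birth, sex, ucod, filn` and optionally `mcod1..mcod14`,
#'   `veteran_flag`.
#' @param codes a [code_table()] used to classify manner from the UCOD.
#' @return harmonized data frame (one row per retained record) with the
#'   shared record schema; `attr(, "rejected")` holds a data frame of
#'   rejected record ids and reasons.
#' @export
harmonize_mdr <- function(raw, codes = code_table()) {
  validate_registry_schema(raw, "MDR")
  dod <- parse_date(raw$death_date)
  dob <- parse_date(raw$date_of_birth)
  dod_str <- trimws(as.character(raw$death_date))
  dob_str <- trimws(as.character(raw$date_of_birth))

  reason <- rep(NA_character_, nrow(raw))
  reason[nzchar(dod_str) & !is.na(dod_str) & is.na(dod)] <- "unparseable death_date"
  reason[is.na(reason) & nzchar(dob_str) & !is.na(dob_str) & is.na(dob)] <-
    "unparseable date_of_birth"
  reason[is.na(reason) & !is.na(dob) & !is.na(dod) & dod < dob] <-
    "death precedes birth"
  keep <- is.na(reason)

  rejected <- data.frame(record_id = as.character(raw$record_id)[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    message(sprintf("harmonize_mdr: rejected %d record(s): %s",
                    nrow(rejected),
                    paste(unique(rejected$reason), collapse = "; ")))
  }

  raw <- raw[keep, , drop = FALSE]
  dod <- dod[keep]
  dob <- dob[keep]

  out <- data.frame(
    record_id = as.character(raw$record_id),
    source = "MDR",
    state = canonical_letter(raw$state),
    year = as.integer(raw$year),
    death_date = dod,
    age_at_death = ifelse(!is.na(dob) & !is.na(dod),
                          completed_years(dob, dod), NA_integer_),
    sex = canonical_sex(raw$sex),
    dmb = ifelse(!is.na(dob), as.POSIXlt(dob)$mday, NA_integer_),
    filn = canonical_letter(raw$filn),
    ucod = canonical_ucod(raw$ucod),
    mcod = mcod_collapse(raw),
    stringsAsFactors = FALSE
  )
  out$manner <- classify_manner(out$ucod, codes, out$record_id)
  out$military_history <- NA_character_
  out$veteran_flag <- if ("veteran_flag" %in% names(raw)) {
    as.logical(raw$veteran_flag)
  } else {
    TRUE
  }
  out <- out[, RECORD_COLUMNS]
  attr(out, "rejected") <- rejected
  out
}

#' Harmonize a raw surveillance-registry (NVDRS-like) extract
#'
#' @param raw data frame with columns `record_id, state, year, death_date,
#'   age_at_death, dmb, sex, filn, ucod, manner, military_history` and
#'   optionally `mcod1..mcod14`.
#' @param codes a [code_table()] (kept for interface symmetry; the
#'   surveillance registry's manner comes from its own manner variable).
#' @return harmonized data frame with the shared record schema.
#' @export
harmonize_nvdrs <- function(raw, codes = code_table()) {
  validate_registry_schema(raw, "NVDRS")
  dod <- parse_date(raw$death_date)
  dmb <- suppressWarnings(as.integer(raw$dmb))
  bad_dmb <- !is.na(dmb) & (dmb < 1L | dmb > 31L)
  if (any(bad_dmb)) {
    warning(sprintf("%d dmb value(s) outside 1-31 set to missing", sum(bad_dmb)))
    dmb[bad_dmb] <- NA_integer_
  }
  mil <- tolower(trimws(as.character(raw$military_history)))
  mil[!mil %in% c("yes", "no")] <- "unknown"
  manner <- tolower(trimws(as.character(raw$manner)))
  manner[!manner %in% c("suicide", "undetermined")] <- "other"

  out <- data.frame(
    record_id = as.character(raw$record_id),
    source = "NVDRS",
    state = canonical_letter(raw$state),
    year = as.integer(raw$year),
    death_date = dod,
    age_at_death = suppressWarnings(as.integer(raw$age_at_death)),
    sex = canonical_sex(raw$sex),
    dmb = dmb,
    filn = canonical_letter(raw$filn),
    ucod = canonical_ucod(raw$ucod),
    mcod = mcod_collapse(raw),
    manner = manner,
    military_history = mil,
    veteran_flag = NA,
    stringsAsFactors = FALSE
  )
  out[, RECORD_COLUMNS]
}

#' Restrict to eligible records
#'
#' Keeps suicide and undetermined-intent deaths among decedents aged 17+
#' (records with missing age are retained; age becomes a missing match-key
#' field).  Idempotent and never increases the record count.
#'
#' @param records harmonized record data frame (either source).
#' @return filtered data frame.
#' @export
filter_eligible <- function(records) {
  keep <- records$manner %in% c("suicide", "undetermined") &
    (is.na(records$age_at_death) | records$age_at_death >= 17L)
  records[keep, , drop = FALSE]
}

#' Read and harmonize a registry CSV
#'
#' External contract: delimited text with a documented header per source;
#' MCOD as columns `mcod1..mcod14`, empty cell = absent code.
#'
#' @param path CSV file path.
#' @param source `"MDR"` or `"NVDRS"`.
#' @param codes a [code_table()].
#' @return harmonized record data frame.
#' @export
read_registry <- function(path, source = c("MDR", "NVDRS"),
                          codes = code_table()) {
  source <- match.arg(source)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (source == "MDR") harmonize_mdr(raw, codes) else harmonize_nvdrs(raw, codes)
}

#' Write a harmonized record table to CSV
#'
#' Both sources share an identical output schema (plus the `source`
#' column); the internal MCOD string is expanded back to `mcod1..mcod14`.
#'
#' @param records harmonized record data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(records, path) {
  stopifnot(!"date_of_birth" %in% names(records))
  out <- cbind(records[setdiff(names(records), "mcod")],
               mcod_expand(records$mcod))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
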