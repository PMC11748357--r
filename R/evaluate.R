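#' Percentage of records linked
#'
#' @param n_matched count of linked gold-registry records.
#' @param n_total count available.
#' @return percentage (half-up, 2 dp); `NA` when `n_total` is 0 (the rate
#'   is undefined and is never reported as 0).
#' @export
match_rate <- function(n_matched, n_total) {
  if (any(n_total == 0)) {
    warning("match rate undefined for zero available records; reported as NA")
  }
  pct(n_matched, n_total)
}

#' Profile state-year strata of the surveillance registry
#'
#' One profile per stratum: record count, per-variable missing
#' proportions over the six match variables, the proportion of records
#' missing two or more of them, the partial-reporting flag, and the
#' `complete` flag.  A stratum is complete iff it is not a partial
#' reporter and its share of records missing 2+ match variables does not
#' exceed the threshold (exclusion is strictly-greater-than; strata
#' sitting exactly at the threshold are kept and flagged `at_threshold`).
#'
#' @param nvdrs harmonized surveillance table.
#' @param partial_reporting character vector of partial-reporting stratum
#'   labels (`"PA-2016"`) or bare state codes.
#' @param threshold completeness threshold, default 0.10.
#' @return data frame, one row per observed stratum.
#' @export
profile_strata <- function(nvdrs, partial_reporting = character(),
                           threshold = 0.10) {
  miss <- vapply(LINKAGE_VARIABLES, function(v) is.na(nvdrs[[v]]),
                 logical(nrow(nvdrs)))
  if (nrow(nvdrs) == 1L) miss <- matrix(miss, nrow = 1L)
  n_miss <- if (nrow(nvdrs)) rowSums(miss) else integer(0)
  stratum <- stratum_label(nvdrs$state, nvdrs$year)
  out <- lapply(split(seq_len(nrow(nvdrs)), stratum), function(i) {
    st <- nvdrs$state[i[1]]
    yr <- nvdrs$year[i[1]]
    props <- colMeans(miss[i, , drop = FALSE])
    p2 <- mean(n_miss[i] >= 2L)
    data.frame(stratum = stratum_label(st, yr), state = st, year = yr,
               n_nvdrs_records = length(i),
               t(props), prop_missing_2plus = p2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(stratum = character(), state = character(),
                      year = integer(), n_nvdrs_records = integer(),
                      prop_missing_2plus = numeric())
    for (v in LINKAGE_VARIABLES) out[[v]] <- numeric()
  }
  names(out)[names(out) %in% LINKAGE_VARIABLES] <-
    paste0("miss_", names(out)[names(out) %in% LINKAGE_VARIABLES])
  out$partial_reporting <- out$stratum %in% partial_reporting |
    out$state %in% partial_reporting
  out$at_threshold <- out$prop_missing_2plus == threshold
  out$complete <- !out$partial_reporting &
    out$n_nvdrs_records > 0L &
    out$prop_missing_2plus <= threshold
  out
}

complete_strata <- function(profiles) profiles$stratum[profiles$complete]

#' Match percentages by confidence tier
#'
#' Shares of gold-registry records linked at the exact / probable /
#' possible tiers plus the unmatched remainder, as percentages of all
#' gold records in scope.  With `restrict_to_complete`, both the matches
#' and the denominator are limited to complete state-year strata.
#'
#' @param result a `linkage_result`.
#' @param mdr the harmonized gold table the linkage ran on.
#' @param restrict_to_complete limit scope to complete strata.
#' @param profiles output of [profile_strata()]; required when
#'   restricting.
#' @return data frame `tier, n, pct` (tiers in order exact, probable,
#'   possible, unmatched; percentages half-up 2 dp and summing to 100
#'   within rounding).
#' @export
stage_breakdown <- function(result, mdr, restrict_to_complete = FALSE,
                            profiles = NULL) {
  matches <- result$matches
  mdr_stratum <- stratum_label(mdr$state, mdr$year)
  if (restrict_to_complete) {
    stopifnot(!is.null(profiles))
    keep <- complete_strata(profiles)
    matches <- matches[matches$stratum %in% keep, , drop = FALSE]
    total <- sum(mdr_stratum %in% keep)
  } else {
    total <- nrow(mdr)
  }
  tiers <- c("exact", "probable", "possible")
  n <- vapply(tiers, function(tt) sum(matches$tier == tt), integer(1))
  n <- c(n, unmatched = total - sum(n))
  data.frame(tier = names(n), n = as.integer(n), pct = pct(n, total),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-stratum match rates
#'
#' @param result a `linkage_result`.
#' @param mdr harmonized gold table.
#' @return data frame `stratum, n_mdr, n_matched, pct`.
#' @export
state_year_match_rates <- function(result, mdr) {
  stratum <- stratum_label(mdr$state, mdr$year)
  tab <- table(stratum)
  mt <- table(factor(result$matches$stratum, levels = names(tab)))
  data.frame(stratum = names(tab),
             n_mdr = as.integer(tab),
             n_matched = as.integer(mt),
             pct = pct(as.integer(mt), as.integer(tab)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Concordance diagnostics for relaxed variables
#'
#' For the passes that dropped UCOD from the key (2a, 3b): how many
#' linked pairs had the surveillance UCOD missing, present but different,
#' or (via duplicate arbitration) present and equal.  For the pass that
#' dropped the death date (2d): missing, within 30 days (inclusive), or
#' more than 30 days apart.
#'
#' @param result a `linkage_result`.
#' @param mdr,nvdrs the harmonized tables the linkage ran on.
#' @return data frame `stage_id, category, n, pct` (pct of the pairs
#'   matched at that stage, half-up 2 dp).
#' @export
concordance_report <- function(result, mdr, nvdrs) {
  m <- result$matches
  rows <- list()
  add <- function(stage, cats) {
    if (!sum(m$stage_id == stage)) return()
    n_stage <- sum(m$stage_id == stage)
    rows[[length(rows) + 1L]] <<- data.frame(
      stage_id = stage, category = names(cats), n = as.integer(cats),
      pct = pct(as.integer(cats), n_stage), stringsAsFactors = FALSE)
  }
  for (stage in c("S2a", "S3b")) {
    sel <- m$stage_id == stage
    if (!any(sel)) next
    mu <- mdr$ucod[match(m$mdr_record_id[sel], mdr$record_id)]
    nu <- nvdrs$ucod[match(m$nvdrs_record_id[sel], nvdrs$record_id)]
    add(stage, c(
      ucod_missing = sum(is.na(nu)),
      ucod_present_different = sum(!is.na(nu) & (is.na(mu) | nu != mu)),
      ucod_present_same = sum(!is.na(nu) & !is.na(mu) & nu == mu)))
  }
  sel <- m$stage_id == "S2d"
  if (any(sel)) {
    md <- mdr$death_date[match(m$mdr_record_id[sel], mdr$record_id)]
    nd <- nvdrs$death_date[match(m$nvdrs_record_id[sel], nvdrs$record_id)]
    dd <- abs(as.numeric(nd - md))
    add("S2d", c(
      date_missing = sum(is.na(dd)),
      date_within_30d = sum(!is.na(dd) & dd <= 30),
      date_over_30d = sum(!is.na(dd) & dd > 30)))
  }
  if (!length(rows)) {
    return(data.frame(stage_id = character(), category = character(),
                      n = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-variable missingness by data source
#'
#' @param records harmonized record table (one source or both row-bound).
#' @return data frame `source, variable, n_missing, n_total, pct`
#'   (half-up 2 dp) over the six match variables.
#' @export
profile_missingness <- function(records) {
  out <- lapply(split(records, records$source), function(df) {
    data.frame(source = df$source[1],
               variable = LINKAGE_VARIABLES,
               n_missing = vapply(LINKAGE_VARIABLES,
                                  function(v) sum(is.na(df[[v]])), integer(1)),
               n_total = nrow(df),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out$pct <- pct(out$n_missing, out$n_total)
  out
}
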