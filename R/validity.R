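#' Wilson score confidence interval for a binomial proportion
#'
#' @param x successes.
#' @param n trials.
#' @param conf confidence level (default 0.95).
#' @return data frame `lower, upper` on the proportion scale
#'   (`NA` rows where `n == 0`); vectorized over `x`, `n`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- ifelse(n > 0, x / n, NA_real_)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  data.frame(lower = pmax(centre - half, 0), upper = pmin(centre + half, 1))
}

#' Clopper-Pearson (exact) confidence interval
#'
#' @inheritParams wilson_ci
#' @return data frame `lower, upper` on the proportion scale.
#' @export
clopper_pearson_ci <- function(x, n, conf = 0.95) {
  ci <- t(vapply(seq_along(x), function(i) {
    if (is.na(n[i]) || n[i] == 0) return(c(NA_real_, NA_real_))
    stats::binom.test(x[i], n[i], conf.level = conf)$conf.int
  }, numeric(2)))
  data.frame(lower = ci[, 1], upper = ci[, 2])
}

#' Build stratified validity tables for the military-history indicator
#'
#' Within complete state-year strata, cross-tabulates the surveillance
#' registry's military-history indicator against linked veteran status
#' (a surveillance record linked to the gold registry is a confirmed
#' veteran death; unlinked records are treated as status-negative, the
#' only operationalization available without identifiers).  One row per
#' manner of death (suicide, undetermined, and their union `"all"`) x
#' grouping (overall; by sex; by age band 17-39 / 40-64 / 65+).  Each
#' record's stratification uses its own source's fields; records with
#' missing age (or sex) drop out of the age- (sex-) stratified rows only.
#'
#' @param result a `linkage_result`.
#' @param mdr,nvdrs the harmonized, eligible tables the linkage ran on.
#' @param profiles output of [profile_strata()].
#' @return data frame of counts: `manner, grouping, level,
#'   n_mdr_veterans, n_linked_yes, n_linked_no, n_linked_unknown,
#'   n_unlinked_yes, n_unlinked_no, n_unlinked_unknown`.
#' @export
build_validity_tables <- function(result, mdr, nvdrs, profiles) {
  keep <- complete_strata(profiles)
  mdr_s <- mdr[stratum_label(mdr$state, mdr$year) %in% keep, , drop = FALSE]
  nv_s <- nvdrs[stratum_label(nvdrs$state, nvdrs$year) %in% keep, ,
                drop = FALSE]
  nv_s$linked <- nv_s$record_id %in% result$matches$nvdrs_record_id
  nv_s$band <- as.character(age_band_of(nv_s$age_at_death))
  mdr_s$band <- as.character(age_band_of(mdr_s$age_at_death))

  cells <- rbind(
    data.frame(grouping = "overall", level = "overall"),
    data.frame(grouping = "sex", level = SEX_LEVELS),
    data.frame(grouping = "age", level = AGE_BANDS)
  )
  manners <- c("suicide", "undetermined", "all")

  one <- function(manner, grouping, level) {
    pick <- function(df) {
      sel <- if (manner == "all") rep(TRUE, nrow(df)) else df$manner == manner
      if (grouping == "sex") sel <- sel & !is.na(df$sex) & df$sex == level
      if (grouping == "age") sel <- sel & !is.na(df$band) & df$band == level
      df[sel, , drop = FALSE]
    }
    nv <- pick(nv_s)
    cnt <- function(linked, ind) {
      sum(nv$linked == linked & nv$military_history == ind)
    }
    data.frame(
      manner = manner, grouping = grouping, level = level,
      n_mdr_veterans = nrow(pick(mdr_s)),
      n_linked_yes = cnt(TRUE, "yes"),
      n_linked_no = cnt(TRUE, "no"),
      n_linked_unknown = cnt(TRUE, "unknown"),
      n_unlinked_yes = cnt(FALSE, "yes"),
      n_unlinked_no = cnt(FALSE, "no"),
      n_unlinked_unknown = cnt(FALSE, "unknown"),
      stringsAsFactors = FALSE
    )
  }
  grid <- expand.grid(i = seq_len(nrow(cells)), manner = manners,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    one(grid$manner[g], cells$grouping[grid$i[g]], cells$level[grid$i[g]])
  }))
  rownames(out) <- NULL
  out
}

#' Diagnostic-accuracy metrics with confidence intervals
#'
#' From a validity count table:
#' * sensitivity = linked-with-yes / gold veteran deaths (an unlinked
#'   gold veteran is a false negative);
#' * specificity = unlinked-with-no / all unlinked (status-negative
#'   denominator);
#' * accuracy = (linked-with-yes + unlinked-with-no) / all surveillance
#'   records in scope;
#' * PPV = linked-with-yes / all indicator-yes records;
#' * NPV = unlinked-with-no / all indicator-no records.
#'
#' "Unknown" indicators count against accuracy on both sides and are
#' excluded from the PPV/NPV denominators, which range over yes- and
#' no-records respectively.  Zero denominators give `NA`, never 0.
#'
#' @param tables count table from [build_validity_tables()].
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @param conf confidence level.
#' @return long data frame: one row per table row x metric, with
#'   `estimate, ci_low, ci_high` as percentages (half-up 2 dp), the
#'   numerator `x` and denominator `n`, and the source counts.
#' @export
metrics_from_table <- function(tables, ci_method = c("wilson",
                                                     "clopper-pearson"),
                               conf = 0.95) {
  ci_method <- match.arg(ci_method)
  ci_fun <- if (ci_method == "wilson") wilson_ci else clopper_pearson_ci
  t <- tables
  n_nvdrs <- t$n_linked_yes + t$n_linked_no + t$n_linked_unknown +
    t$n_unlinked_yes + t$n_unlinked_no + t$n_unlinked_unknown
  defs <- list(
    sensitivity = list(x = t$n_linked_yes, n = t$n_mdr_veterans),
    specificity = list(x = t$n_unlinked_no,
                       n = t$n_unlinked_yes + t$n_unlinked_no +
                         t$n_unlinked_unknown),
    accuracy = list(x = t$n_linked_yes + t$n_unlinked_no, n = n_nvdrs),
    ppv = list(x = t$n_linked_yes, n = t$n_linked_yes + t$n_unlinked_yes),
    npv = list(x = t$n_unlinked_no, n = t$n_linked_no + t$n_unlinked_no)
  )
  out <- do.call(rbind, lapply(names(defs), function(mname) {
    d <- defs[[mname]]
    ci <- ci_fun(d$x, d$n, conf)
    cbind(t[c("manner", "grouping", "level")],
          data.frame(metric = mname,
                     estimate = pct(d$x, d$n),
                     ci_low = round_half_up(100 * ci$lower, 2),
                     ci_high = round_half_up(100 * ci$upper, 2),
                     x = d$x, n = d$n, stringsAsFactors = FALSE),
          t[setdiff(names(t), c("manner", "grouping", "level"))])
  }))
  rownames(out) <- NULL
  out
}
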