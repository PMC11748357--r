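# Deterministic codification of the manual duplicate-review cascade:
# MCOD containment, then review of the pass's relaxed variables, then the
# military-history indicator.  Each rule is evaluated over the full set of
# candidate pairings, which keeps the cascade order-invariant: a rule fires
# only when it singles out exactly one pairing.

#' Arbitrate one duplicate group
#'
#' A duplicate group is a match key shared by more than one possible
#' MDR-NVDRS pairing within a stratum.  The cascade resolves it to a
#' single pair, or declares it unresolved (its members then re-enter the
#' candidate pools for later passes):
#'
#' * **Rule 1 (`mcod_rule`)** — resolve if exactly one pairing satisfies
#'   MDR MCOD \eqn{\subseteq} NVDRS MCOD (exact canonical-code
#'   containment).  An NVDRS record with a fully missing MCOD, or an MDR
#'   record with no MCOD codes, is uninformative for this rule; partially
#'   missing NVDRS slots never block a candidate, only a contradiction
#'   (a required code absent from a non-empty NVDRS set) does.
#' * **Rule 2 (`field_review_rule`)** — over the variables this pass
#'   relaxed: resolve if exactly one pairing agrees exactly on all of
#'   them (both values present); failing that, if death date was relaxed,
#'   resolve to the unique pairing with strictly minimal absolute
#'   death-date difference.
#' * **Rule 3 (`military_rule`)** — applicable only when the group holds
#'   a single MDR record (the indicator is an NVDRS attribute): resolve
#'   if exactly one NVDRS candidate has `military_history == "yes"`.
#'
#' If no rule fires — in particular when every reviewed NVDRS field is
#' missing — the group is unresolved due to insufficient information.
#'
#' @param group list with `stratum`, `key`, `mdr_ids`, `nvdrs_ids`.
#' @param mdr_pool,nvdrs_pool harmonized record tables containing the
#'   group members.
#' @param spec the [stage_spec()] of the pass that produced the group.
#' @return list with `resolved` (logical), and when resolved `mdr_id`,
#'   `nvdrs_id`, `resolution` in
#'   `{"mcod_rule","field_review_rule","military_rule"}`.
#' @export
resolve_group <- function(group, mdr_pool, nvdrs_pool, spec) {
  m <- mdr_pool[match(group$mdr_ids, mdr_pool$record_id), , drop = FALSE]
  n <- nvdrs_pool[match(group$nvdrs_ids, nvdrs_pool$record_id), , drop = FALSE]
  stopifnot(!anyNA(m$record_id), !anyNA(n$record_id))
  pair <- expand.grid(mi = seq_len(nrow(m)), ni = seq_len(nrow(n)))
  if (nrow(pair) < 2L) stopf("not a duplicate group: fewer than 2 pairings")

  done <- function(i, rule) {
    list(resolved = TRUE,
         mdr_id = m$record_id[pair$mi[i]],
         nvdrs_id = n$record_id[pair$ni[i]],
         resolution = rule)
  }

  # Rule 1: unique MCOD containment
  m_codes <- mcod_split(m$mcod)
  n_codes <- mcod_split(n$mcod)
  support1 <- vapply(seq_len(nrow(pair)), function(i) {
    M <- m_codes[[pair$mi[i]]]
    N <- n_codes[[pair$ni[i]]]
    length(M) > 0L && length(N) > 0L && all(M %in% N)
  }, logical(1))
  if (sum(support1) == 1L) return(done(which(support1), "mcod_rule"))

  # Rule 2: review of the variables this pass relaxed
  relaxed <- setdiff(LINKAGE_VARIABLES, spec$key_variables)
  if (length(relaxed)) {
    mk <- lapply(relaxed, function(v) render_key_var(m, v))
    nk <- lapply(relaxed, function(v) render_key_var(n, v))
    agree <- vapply(seq_len(nrow(pair)), function(i) {
      all(vapply(seq_along(relaxed), function(j) {
        a <- mk[[j]][pair$mi[i]]
        b <- nk[[j]][pair$ni[i]]
        !is.na(a) && !is.na(b) && a == b
      }, logical(1)))
    }, logical(1))
    if (sum(agree) == 1L) return(done(which(agree), "field_review_rule"))
    if ("death_date" %in% relaxed) {
      dd <- abs(as.numeric(m$death_date[pair$mi] - n$death_date[pair$ni]))
      dd[is.na(dd)] <- Inf
      if (any(is.finite(dd)) && sum(dd == min(dd)) == 1L) {
        return(done(which.min(dd), "field_review_rule"))
      }
    }
  }

  # Rule 3: unique 'yes' military-history indicator (single-MDR groups only)
  if (nrow(m) == 1L) {
    yes <- !is.na(n$military_history) & n$military_history == "yes"
    if (sum(yes) == 1L) {
      return(done(which(pair$ni == which(yes)), "military_rule"))
    }
  }

  list(resolved = FALSE)
}

#' Summarize duplicate resolutions by method
#'
#' @param result a `linkage_result` from [run_linkage()].
#' @return data frame with one row per resolution method actually used:
#'   `method`, `n` resolved groups, and `pct` of all resolved groups
#'   (half-up, 2 dp).  Zero resolved groups give a zero-row frame (no
#'   division is attempted).
#' @export
summarize_resolutions <- function(result) {
  res <- result$matches$resolution
  res <- res[res != "unique_key"]
  if (!length(res)) {
    return(data.frame(method = character(), n = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(res)
  data.frame(method = names(tab),
             n = as.integer(tab),
             pct = pct(as.integer(tab), length(res)),
             stringsAsFactors = FALSE, row.names = NULL)
}
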