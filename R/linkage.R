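#' Execute one linkage pass over the unmatched pools
#'
#' Records are compared only within state-year strata (the stratum is
#' prefixed to every concatenated key).  Keys occurring exactly once on
#' each side produce a match with resolution `unique_key`; keys with more
#' than one possible pairing form duplicate groups, which are arbitrated
#' by [resolve_group()].  Matched records (and the resolved members of
#' duplicate groups) are removed from the remaining pools; members of
#' unresolved groups are carried forward to later passes.  For stage 3b
#' the surveillance pool is first limited to records missing both dmb and
#' filn (the others stay in the remaining pool, untouched).
#'
#' @param mdr_pool,nvdrs_pool harmonized record tables: the unmatched
#'   residue of earlier passes.
#' @param spec a [stage_spec()].
#' @param resolve arbitrate duplicate groups (default `TRUE`); with
#'   `FALSE` every duplicate group is carried forward unresolved.
#' @return list with `matches` (data frame: `mdr_record_id,
#'   nvdrs_record_id, stratum, stage_id, tier, resolution`), `groups`
#'   (audit data frame of duplicate groups), `mdr_remaining`,
#'   `nvdrs_remaining`.
#' @export
run_pass <- function(mdr_pool, nvdrs_pool, spec, resolve = TRUE) {
  mkey <- build_stage_key(mdr_pool, spec)
  nkey <- build_stage_key(nvdrs_pool, spec)
  if (identical(spec$nvdrs_pool_restriction, "dmb_filn_missing")) {
    nkey[!(is.na(nvdrs_pool$dmb) & is.na(nvdrs_pool$filn))] <- NA_character_
  }
  mfull <- ifelse(is.na(mkey), NA_character_,
                  paste(mdr_pool$state, mdr_pool$year, mkey, sep = "|"))
  nfull <- ifelse(is.na(nkey), NA_character_,
                  paste(nvdrs_pool$state, nvdrs_pool$year, nkey, sep = "|"))

  mt <- table(mfull[!is.na(mfull)])
  nt <- table(nfull[!is.na(nfull)])
  common <- intersect(names(mt), names(nt))

  uu <- common[mt[common] == 1L & nt[common] == 1L]
  mi <- match(uu, mfull)
  ni <- match(uu, nfull)
  if (length(uu)) {
    # stratum fence: a key join may never straddle state-year strata
    stopifnot(mdr_pool$state[mi] == nvdrs_pool$state[ni],
              mdr_pool$year[mi] == nvdrs_pool$year[ni])
  }
  matches <- data.frame(
    mdr_record_id = mdr_pool$record_id[mi],
    nvdrs_record_id = nvdrs_pool$record_id[ni],
    stratum = stratum_label(mdr_pool$state[mi], mdr_pool$year[mi]),
    stage_id = rep(spec$stage_id, length(uu)),
    tier = rep(spec$tier, length(uu)),
    resolution = rep("unique_key", length(uu)),
    stringsAsFactors = FALSE
  )

  dup_keys <- common[mt[common] * nt[common] >= 2L]
  groups <- vector("list", length(dup_keys))
  for (k in seq_along(dup_keys)) {
    key <- dup_keys[k]
    g <- list(key = key,
              mdr_ids = mdr_pool$record_id[!is.na(mfull) & mfull == key],
              nvdrs_ids = nvdrs_pool$record_id[!is.na(nfull) & nfull == key])
    g$stratum <- stratum_label(
      mdr_pool$state[mdr_pool$record_id == g$mdr_ids[1]],
      mdr_pool$year[mdr_pool$record_id == g$mdr_ids[1]])
    out <- if (resolve) resolve_group(g, mdr_pool, nvdrs_pool, spec) else
      list(resolved = FALSE)
    groups[[k]] <- data.frame(
      stratum = g$stratum, stage_id = spec$stage_id, key = key,
      n_mdr = length(g$mdr_ids), n_nvdrs = length(g$nvdrs_ids),
      mdr_ids = paste(g$mdr_ids, collapse = ";"),
      nvdrs_ids = paste(g$nvdrs_ids, collapse = ";"),
      resolved = out$resolved,
      resolution = if (out$resolved) out$resolution else NA_character_,
      mdr_record_id = if (out$resolved) out$mdr_id else NA_character_,
      nvdrs_record_id = if (out$resolved) out$nvdrs_id else NA_character_,
      stringsAsFactors = FALSE
    )
    if (out$resolved) {
      matches <- rbind(matches, data.frame(
        mdr_record_id = out$mdr_id, nvdrs_record_id = out$nvdrs_id,
        stratum = g$stratum, stage_id = spec$stage_id, tier = spec$tier,
        resolution = out$resolution, stringsAsFactors = FALSE))
    }
  }
  groups <- if (length(groups)) do.call(rbind, groups) else empty_group_audit()

  list(
    matches = matches,
    groups = groups,
    mdr_remaining = mdr_pool[!mdr_pool$record_id %in% matches$mdr_record_id, ,
                             drop = FALSE],
    nvdrs_remaining = nvdrs_pool[!nvdrs_pool$record_id %in%
                                   matches$nvdrs_record_id, , drop = FALSE]
  )
}

empty_group_audit <- function() {
  data.frame(stratum = character(), stage_id = character(), key = character(),
             n_mdr = integer(), n_nvdrs = integer(), mdr_ids = character(),
             nvdrs_ids = character(), resolved = logical(),
             resolution = character(), mdr_record_id = character(),
             nvdrs_record_id = character(), stringsAsFactors = FALSE)
}

#' Run the full multi-stage deterministic linkage
#'
#' Applies the pass sequence in order, removing matched records from both
#' registries between passes.  Inputs must already be harmonized and
#' filtered to eligible records.
#'
#' @param mdr,nvdrs harmonized record tables.
#' @param stages list of [stage_spec()]s, default [default_stage_specs()].
#' @param resolve arbitrate duplicate groups (default `TRUE`).
#' @return a `linkage_result`: list with `matches` (all resolved pairs,
#'   with stage, tier and resolution provenance), `stage_counts`,
#'   `duplicates` (group audit trail), `unmatched_mdr`,
#'   `unmatched_nvdrs` (record ids), `n_mdr`, `n_nvdrs`, `stages`.
#' @export
run_linkage <- function(mdr, nvdrs, stages = default_stage_specs(),
                        resolve = TRUE) {
  stopifnot(!anyDuplicated(mdr$record_id), !anyDuplicated(nvdrs$record_id))
  mpool <- mdr
  npool <- nvdrs
  all_matches <- list()
  all_groups <- list()
  counts <- list()
  for (spec in stages) {
    p <- run_pass(mpool, npool, spec, resolve = resolve)
    all_matches[[spec$stage_id]] <- p$matches
    all_groups[[spec$stage_id]] <- p$groups
    counts[[spec$stage_id]] <- data.frame(
      stage_id = spec$stage_id, tier = spec$tier,
      n_matched = nrow(p$matches),
      n_unique_key = sum(p$matches$resolution == "unique_key"),
      n_duplicate_groups = nrow(p$groups),
      n_groups_resolved = sum(p$groups$resolved),
      stringsAsFactors = FALSE)
    mpool <- p$mdr_remaining
    npool <- p$nvdrs_remaining
  }
  matches <- do.call(rbind, c(all_matches, list(make.row.names = FALSE)))
  stopifnot(!anyDuplicated(matches$mdr_record_id),
            !anyDuplicated(matches$nvdrs_record_id))
  structure(list(
    matches = matches,
    stage_counts = do.call(rbind, c(counts, list(make.row.names = FALSE))),
    duplicates = do.call(rbind, c(all_groups, list(make.row.names = FALSE))),
    unmatched_mdr = mpool$record_id,
    unmatched_nvdrs = npool$record_id,
    n_mdr = nrow(mdr),
    n_nvdrs = nrow(nvdrs),
    stages = stages
  ), class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("Deterministic linkage: %d of %d MDR records matched (%s%%)\n",
              nrow(x$matches), x$n_mdr,
              format(pct(nrow(x$matches), x$n_mdr), nsmall = 2)))
  print(x$stage_counts, row.names = FALSE)
  invisible(x)
}
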