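#' Definition of one linkage pass
#'
#' A stage is an ordered subset of the six match variables (age, sex,
#' UCOD, day-of-month of birth, first initial of last name, death date),
#' a confidence tier, and, for stage 3b only, a restriction of the
#' surveillance-side candidate pool.  Age and sex are part of every key.
#'
#' @param stage_id one of `"S1","S2a","S2b","S2c","S2d","S3a","S3b"`.
#' @param key_variables ordered character subset of the six match variables.
#' @param tier `"exact"`, `"probable"` or `"possible"`.
#' @param nvdrs_pool_restriction `NULL`, or `"dmb_filn_missing"` (stage 3b:
#'   only surveillance records missing *both* dmb and filn are candidates).
#' @return a `stage_spec` object.
#' @export
stage_spec <- function(stage_id, key_variables, tier,
                       nvdrs_pool_restriction = NULL) {
  stopifnot(all(key_variables %in% LINKAGE_VARIABLES),
            all(c("age_at_death", "sex") %in% key_variables),
            tier %in% c("exact", "probable", "possible"))
  structure(list(stage_id = stage_id,
                 key_variables = key_variables,
                 tier = tier,
                 nvdrs_pool_restriction = nvdrs_pool_restriction),
            class = "stage_spec")
}

#' The default three-stage, seven-pass sequence
#'
#' Stage 1 matches on all six variables ("exact").  Stage 2 relaxes one
#' variable per pass, in order: 2a drops UCOD, 2b drops dmb, 2c drops
#' filn, 2d drops death date ("probable").  Stage 3a drops dmb and filn;
#' stage 3b drops UCOD from the key but restricts surveillance candidates
#' to records missing both dmb and filn, making its effective key
#' age + sex + death date ("possible").
#'
#' @return named list of [stage_spec()] objects in execution order.
#' @export
default_stage_specs <- function() {
  all6 <- LINKAGE_VARIABLES
  drop <- function(...) setdiff(all6, c(...))
  specs <- list(
    S1  = stage_spec("S1",  all6, "exact"),
    S2a = stage_spec("S2a", drop("ucod"), "probable"),
    S2b = stage_spec("S2b", drop("dmb"), "probable"),
    S2c = stage_spec("S2c", drop("filn"), "probable"),
    S2d = stage_spec("S2d", drop("death_date"), "probable"),
    S3a = stage_spec("S3a", drop("dmb", "filn"), "possible"),
    S3b = stage_spec("S3b", drop("ucod", "dmb", "filn"), "possible",
                     nvdrs_pool_restriction = "dmb_filn_missing")
  )
  specs
}

# canonical rendering of one key variable, vectorised over records
render_key_var <- function(records, var) {
  switch(var,
    age_at_death = ifelse(is.na(records$age_at_death), NA_character_,
                          as.character(records$age_at_death)),
    sex = c(male = "M", female = "F")[records$sex],
    ucod = records$ucod,
    dmb = ifelse(is.na(records$dmb), NA_character_, as.character(records$dmb)),
    filn = records$filn,
    death_date = ifelse(is.na(records$death_date), NA_character_,
                        format(records$death_date, "%Y-%m-%d")),
    stopf("unknown key variable: %s", var)
  )
}

#' Build the concatenated match key for a stage
#'
#' The stage's key variables, in fixed order (age, sex, UCOD, dmb, filn,
#' death date), canonically rendered and joined with `"|"` (a character
#' barred from every field).  A record missing any key variable gets `NA`:
#' it sits out the pass (missingness is never a wildcard).  The stage-3b
#' pool restriction is applied separately in [run_pass()], not here.
#'
#' @param records harmonized record data frame.
#' @param spec a [stage_spec()].
#' @return character vector of keys, `NA` where the record is ineligible.
#' @export
build_stage_key <- function(records, spec) {
  vars <- LINKAGE_VARIABLES[LINKAGE_VARIABLES %in% spec$key_variables]
  parts <- lapply(vars, function(v) render_key_var(records, v))
  key <- do.call(paste, c(parts, sep = "|"))
  missing_any <- Reduce(`|`, lapply(parts, is.na))
  key[missing_any] <- NA_character_
  key
}
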