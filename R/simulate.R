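# Synthetic dual-registry generator.  A ground-truth decedent universe is
# drawn per state-year stratum; veterans may additionally surface in the
# gold registry (MDR-like), every decedent may surface in the surveillance
# registry (NVDRS-like, subject to partial reporting).  Field values agree
# between the two emissions of a decedent until discrepancy and missingness
# injection, and a truth file records the correct links.

SEX_LEVELS <- c("male", "female")
AGE_BANDS <- c("17-39", "40-64", "65+")

# rough English surname-initial frequencies; collisions within a stratum
# are the natural source of duplicate groups
FILN_FREQ <- c(A = 4, B = 9, C = 9, D = 5, E = 3, F = 4, G = 5, H = 7,
               I = 1, J = 3, K = 4, L = 5, M = 9, N = 3, O = 2, P = 6,
               Q = 0.3, R = 5, S = 10, T = 5, U = 0.4, V = 1.5, W = 6,
               X = 0.1, Y = 0.7, Z = 0.5)

SUICIDE_UCOD_POOL <- c("X60", "X61", "X62", "X63", "X64", "X65", "X66",
                       "X67", "X68", "X69", "X70", "X71", "X72", "X73",
                       "X74", "X75", "X76", "X78", "X80", "X81", "X82",
                       "X83", "X84")
SUICIDE_UCOD_WT <- c(2, 1, 1, 1, 2, 1, 1, 1, 1, 1, 20, 2, 8, 4, 28, 1, 1,
                     2, 3, 2, 1, 1, 1)
UNDET_UCOD_POOL <- c("Y10", "Y11", "Y12", "Y14", "Y15", "Y16", "Y17",
                     "Y19", "Y20", "Y21", "Y22", "Y23", "Y24", "Y25",
                     "Y26", "Y28", "Y29", "Y30", "Y31", "Y33", "Y34")
UNDET_UCOD_WT <- c(8, 4, 10, 20, 3, 1, 1, 4, 2, 2, 2, 1, 1, 1, 1, 1, 1,
                   3, 2, 2, 6)
OTHER_UCOD_POOL <- c("X85", "X91", "X93", "X94", "X95", "Y04", "W32",
                     "W33", "W34")
AUX_MCOD_POOL <- c("T360", "T391", "T402", "T404", "T426", "T438", "T449",
                   "T509", "T58", "T71", "R090", "R99", "S019", "S119",
                   "T141", "J960", "I469", "F102", "F329")

#' Construct a simulation configuration
#'
#' The constructor's own defaults describe a *noise-free* single-stratum
#' world (no missingness, no discrepancies, full reporting and coverage,
#' a perfect military indicator): every optional mechanism must be turned
#' on explicitly.  [default_study_config()] returns the calibrated
#' study-scale configuration.
#'
#' @param seed integer RNG seed; same seed + config give byte-identical
#'   output tables.
#' @param states,years stratum grid (2-letter codes x calendar years).
#' @param decedents_per_stratum integer, or named integer vector keyed by
#'   stratum label for per-stratum sizes.
#' @param veteran_fraction probability a decedent is a veteran.
#' @param suicide_fraction probability of manner suicide (vs undetermined)
#'   among in-scope deaths.
#' @param other_manner_fraction fraction of surveillance records with an
#'   out-of-scope manner (exercises eligibility filtering; such decedents
#'   never enter the gold registry).
#' @param sex_mix named probabilities of male sex, `veteran` and
#'   `nonveteran`.
#' @param age_weights list of length-3 weights over bands 17-39 / 40-64 /
#'   65+ for `veteran` and `nonveteran`; age uniform within band
#'   (65+ capped at 90).
#' @param missingness list with named rate vectors `nvdrs`
#'   (`ucod, death_date, dmb, filn, age_at_death, sex`) and `mdr`
#'   (`date_of_birth, filn, ucod, death_date, sex`), a scalar
#'   `joint_dmb_filn` (probability dmb and filn go missing *together*;
#'   marginal rates are preserved), and `stratum_overrides`: a named list
#'   (state code or stratum label) of per-stratum replacements.
#' @param discrepancy named per-variable probabilities that a
#'   surveillance value disagrees with truth
#'   (`ucod, death_date, dmb, filn`).
#' @param date_shift two-component death-date shift: `p_small` of shifts
#'   are within `small_max` days, the rest up to `large_max`.
#' @param indicator_model list: `p_yes_veteran` 2x3 matrix (sex x age
#'   band) or scalar, `p_yes_nonveteran` named by sex or scalar,
#'   `p_unknown` scalar.
#' @param partial_reporting named numeric vector of sampling fractions,
#'   keyed by state code or stratum label; unlisted strata report fully.
#' @param mdr_undercoverage named vector `base` and `age65` (added for
#'   decedents 65+): probability a true veteran is absent from the gold
#'   registry.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       states = "AA",
                       years = 2015L,
                       decedents_per_stratum = 1000L,
                       veteran_fraction = 0.13,
                       suicide_fraction = 0.87,
                       other_manner_fraction = 0,
                       sex_mix = c(veteran = 0.95, nonveteran = 0.76),
                       age_weights = list(veteran = c(0.19, 0.42, 0.39),
                                          nonveteran = c(0.38, 0.47, 0.15)),
                       missingness = list(),
                       discrepancy = c(ucod = 0, death_date = 0, dmb = 0,
                                       filn = 0),
                       date_shift = list(p_small = 0.8, small_max = 30,
                                         large_max = 180),
                       indicator_model = list(p_yes_veteran = 1,
                                              p_yes_nonveteran = 0,
                                              p_unknown = 0),
                       partial_reporting = numeric(),
                       mdr_undercoverage = c(base = 0, age65 = 0)) {
  nv0 <- c(ucod = 0, death_date = 0, dmb = 0, filn = 0, age_at_death = 0,
           sex = 0)
  md0 <- c(date_of_birth = 0, filn = 0, ucod = 0, death_date = 0, sex = 0)
  miss <- list(
    nvdrs = replace(nv0, names(missingness$nvdrs %||% numeric()),
                    missingness$nvdrs %||% numeric()),
    mdr = replace(md0, names(missingness$mdr %||% numeric()),
                  missingness$mdr %||% numeric()),
    joint_dmb_filn = missingness$joint_dmb_filn %||% 0,
    stratum_overrides = missingness$stratum_overrides %||% list()
  )
  ind <- indicator_model
  if (length(ind$p_yes_veteran) == 1L) {
    ind$p_yes_veteran <- matrix(ind$p_yes_veteran, 2, 3,
                                dimnames = list(SEX_LEVELS, AGE_BANDS))
  }
  if (is.null(names(ind$p_yes_nonveteran))) {
    ind$p_yes_nonveteran <- c(male = ind$p_yes_nonveteran[[1]],
                              female = ind$p_yes_nonveteran[[1]])
  }
  cfg <- structure(list(
    seed = as.integer(seed), states = states, years = as.integer(years),
    decedents_per_stratum = decedents_per_stratum,
    veteran_fraction = veteran_fraction,
    suicide_fraction = suicide_fraction,
    other_manner_fraction = other_manner_fraction,
    sex_mix = sex_mix, age_weights = age_weights,
    missingness = miss, discrepancy = discrepancy,
    date_shift = date_shift, indicator_model = ind,
    partial_reporting = partial_reporting,
    mdr_undercoverage = mdr_undercoverage
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!length(cfg$states) || !length(cfg$years)) {
    stopf("states and years must be non-empty")
  }
  probs <- c(cfg$veteran_fraction, cfg$suicide_fraction,
             cfg$other_manner_fraction, cfg$sex_mix,
             cfg$missingness$nvdrs, cfg$missingness$mdr,
             cfg$missingness$joint_dmb_filn, cfg$discrepancy,
             cfg$indicator_model$p_yes_veteran,
             cfg$indicator_model$p_yes_nonveteran,
             cfg$indicator_model$p_unknown, cfg$partial_reporting,
             cfg$mdr_undercoverage)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stopf("all configured probabilities must lie in [0, 1]")
  }
  if (any(unlist(cfg$decedents_per_stratum) < 0)) {
    stopf("decedents_per_stratum must be non-negative")
  }
  jm <- cfg$missingness$joint_dmb_filn
  if (jm > min(cfg$missingness$nvdrs[c("dmb", "filn")]) && jm > 0) {
    stopf("joint_dmb_filn may not exceed either marginal dmb/filn rate")
  }
  if (max(cfg$indicator_model$p_yes_veteran) +
      cfg$indicator_model$p_unknown > 1 ||
      max(cfg$indicator_model$p_yes_nonveteran) +
      cfg$indicator_model$p_unknown > 1) {
    stopf("indicator probabilities exceed 1 in some cell")
  }
  invisible(cfg)
}

#' Study-calibrated default simulation configuration
#'
#' Emulates the 2012-2018 surveillance conditions the package's analyses
#' assume: 8 states x 7 years at 900 decedents per stratum (about 50,000
#' surveillance records); surveillance missingness of UCOD 5.44%, death
#' date 4.26%, dmb 12%, filn 10%, age/sex under 1%; gold-registry
#' missingness at or below 0.25% per variable; a high-missingness state
#' ("CO") whose strata jointly omit dmb and filn for about half of
#' records; a partial-reporting state ("PA", 80% sampling, 2016-2018);
#' a military-history indicator whose yes-probability for veterans varies
#' by sex and age band (males 0.79/0.83/0.93, females 0.55/0.62/0.75,
#' about 0.86 overall for males and 0.62 for females), with a small
#' false-positive rate among non-veterans and 5% unknown; and gold
#' undercoverage of veterans rising for ages 65+.
#'
#' @param seed integer RNG seed.
#' @return a `sim_config`.
#' @export
default_study_config <- function(seed = 1L) {
  sim_config(
    seed = seed,
    states = c("AZ", "CO", "GA", "KY", "MA", "OR", "PA", "VA"),
    years = 2012:2018,
    decedents_per_stratum = 900L,
    veteran_fraction = 0.13,
    suicide_fraction = 0.87,
    other_manner_fraction = 0.02,
    missingness = list(
      nvdrs = c(ucod = 0.0544, death_date = 0.0426, dmb = 0.12,
                filn = 0.10, age_at_death = 0.005, sex = 0.002),
      mdr = c(date_of_birth = 0.0024, filn = 0.001, ucod = 0,
              death_date = 0, sex = 0),
      joint_dmb_filn = 0,
      stratum_overrides = list(
        CO = list(nvdrs = c(dmb = 0.55, filn = 0.50),
                  joint_dmb_filn = 0.45))
    ),
    discrepancy = c(ucod = 0.01, death_date = 0.008, dmb = 0.004,
                    filn = 0.004),
    indicator_model = list(
      p_yes_veteran = matrix(c(0.79, 0.83, 0.93,
                               0.55, 0.62, 0.75),
                             nrow = 2, byrow = TRUE,
                             dimnames = list(SEX_LEVELS, AGE_BANDS)),
      p_yes_nonveteran = c(male = 0.055, female = 0.012),
      p_unknown = 0.05),
    partial_reporting = c("PA-2016" = 0.8, "PA-2017" = 0.8,
                          "PA-2018" = 0.8),
    mdr_undercoverage = c(base = 0.03, age65 = 0.07)
  )
}

stratum_param <- function(keys, strata, states) {
  # resolve a named per-stratum parameter: exact stratum label wins,
  # then bare state code; absent -> NA
  out <- rep(NA_real_, length(strata))
  if (!length(keys)) return(out)
  hit <- match(strata, names(keys))
  out[!is.na(hit)] <- keys[hit[!is.na(hit)]]
  hit2 <- match(states, names(keys))
  fill <- is.na(out) & !is.na(hit2)
  out[fill] <- keys[hit2[fill]]
  out
}

age_band_of <- function(age) {
  cut(age, c(16, 39, 64, Inf), labels = AGE_BANDS)
}

#' Generate the two registries and their ground-truth links
#'
#' Every decedent yields at most one surveillance row (dropped under
#' partial reporting) and, if a veteran with in-scope manner, at most one
#' gold row (dropped under undercoverage).  Linked rows share true field
#' values before discrepancy and missingness injection; the truth table
#' lists exactly the decedents present in both outputs.  The gold
#' registry's surveillance-registry counterpart of every MDR MCOD set is
#' a superset by construction, so true pairs always satisfy MCOD
#' containment.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_registries` with `mdr` and `nvdrs` raw
#'   tables (pre-harmonization schema, the gold table still carrying
#'   `date_of_birth`), `truth` (`mdr_record_id, nvdrs_record_id,
#'   stratum`), and the `config`.
#' @export
simulate_registries <- function(config) {
  validate_sim_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  grid <- expand.grid(state = config$states, year = config$years,
                      stringsAsFactors = FALSE)
  grid$stratum <- stratum_label(grid$state, grid$year)
  nps <- config$decedents_per_stratum
  grid$n <- if (length(nps) == 1L && is.null(names(nps))) {
    rep(as.integer(nps), nrow(grid))
  } else {
    found <- nps[grid$stratum]
    as.integer(ifelse(is.na(found), 0L, found))
  }
  n <- sum(grid$n)
  idx <- rep(seq_len(nrow(grid)), grid$n)

  d <- data.frame(state = grid$state[idx], year = grid$year[idx],
                  stratum = grid$stratum[idx], stringsAsFactors = FALSE)
  d$veteran <- stats::runif(n) < config$veteran_fraction
  u_manner <- stats::runif(n)
  d$manner <- ifelse(u_manner < config$other_manner_fraction, "other",
                     ifelse(stats::runif(n) < config$suicide_fraction,
                            "suicide", "undetermined"))
  # gold registry is a suicide/undetermined query: other-manner deaths
  # never enter it, so they carry no veteran flag of consequence
  p_male <- ifelse(d$veteran, config$sex_mix[["veteran"]],
                   config$sex_mix[["nonveteran"]])
  d$sex <- ifelse(stats::runif(n) < p_male, "male", "female")

  aw <- config$age_weights
  band_idx <- integer(n)
  vet <- d$veteran
  if (any(vet)) {
    band_idx[vet] <- sample.int(3L, sum(vet), replace = TRUE,
                                prob = aw$veteran)
  }
  if (any(!vet)) {
    band_idx[!vet] <- sample.int(3L, sum(!vet), replace = TRUE,
                                 prob = aw$nonveteran)
  }
  lo <- c(17L, 40L, 65L)[band_idx]
  hi <- c(39L, 64L, 90L)[band_idx]
  d$age <- lo + floor(stats::runif(n) * (hi - lo + 1L))

  d$filn <- sample(names(FILN_FREQ), n, replace = TRUE, prob = FILN_FREQ)
  d$death_date <- as.Date(sprintf("%d-01-01", d$year)) +
    floor(stats::runif(n) * days_in_year(d$year))

  # date of birth consistent with target age (completed years) and a
  # day-of-month of birth; February capped at 28 to dodge leap years
  bm <- sample.int(12L, n, replace = TRUE)
  mlen <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  bd <- 1L + floor(stats::runif(n) * mlen[bm])
  dlt <- as.POSIXlt(d$death_date)
  passed <- (bm < dlt$mon + 1L) | (bm == dlt$mon + 1L & bd <= dlt$mday)
  by <- d$year - d$age - as.integer(!passed)
  d$dob <- as.Date(sprintf("%04d-%02d-%02d", by, bm, bd))
  d$dmb <- bd

  d$ucod <- NA_character_
  su <- d$manner == "suicide"
  un <- d$manner == "undetermined"
  ot <- d$manner == "other"
  if (any(su)) d$ucod[su] <- sample(SUICIDE_UCOD_POOL, sum(su),
                                    replace = TRUE, prob = SUICIDE_UCOD_WT)
  if (any(un)) d$ucod[un] <- sample(UNDET_UCOD_POOL, sum(un),
                                    replace = TRUE, prob = UNDET_UCOD_WT)
  if (any(ot)) d$ucod[ot] <- sample(OTHER_UCOD_POOL, sum(ot), replace = TRUE)

  a1 <- sample(AUX_MCOD_POOL, n, replace = TRUE)
  a2 <- sample(AUX_MCOD_POOL, n, replace = TRUE)
  a3 <- sample(AUX_MCOD_POOL, n, replace = TRUE)
  extra <- sample(AUX_MCOD_POOL, n, replace = TRUE)
  k <- sample.int(3L, n, replace = TRUE)
  mcod_mdr <- paste(d$ucod, a1)
  w <- k >= 2L
  mcod_mdr[w] <- paste(mcod_mdr[w], a2[w])
  w <- k == 3L
  mcod_mdr[w] <- paste(mcod_mdr[w], a3[w])
  mcod_nv <- mcod_mdr
  w <- stats::runif(n) < 0.5
  mcod_nv[w] <- paste(mcod_nv[w], extra[w])

  # registry presence
  rep_frac <- stratum_param(config$partial_reporting, d$stratum, d$state)
  rep_frac[is.na(rep_frac)] <- 1
  nvdrs_present <- stats::runif(n) < rep_frac
  uc <- config$mdr_undercoverage[["base"]] +
    ifelse(d$age >= 65L, config$mdr_undercoverage[["age65"]], 0)
  mdr_present <- d$veteran & d$manner != "other" & stats::runif(n) >= uc

  # military-history indicator
  sex_i <- match(d$sex, SEX_LEVELS)
  pm <- config$indicator_model$p_yes_veteran
  p_yes <- ifelse(d$veteran, pm[cbind(sex_i, band_idx)],
                  config$indicator_model$p_yes_nonveteran[sex_i])
  u <- stats::runif(n)
  p_unk <- config$indicator_model$p_unknown
  mil <- ifelse(u < p_yes, "yes", ifelse(u < p_yes + p_unk, "unknown", "no"))

  mdr <- build_mdr_raw(d[mdr_present, , drop = FALSE], mcod_mdr[mdr_present],
                       config)
  nvdrs <- build_nvdrs_raw(d[nvdrs_present, , drop = FALSE],
                           mcod_nv[nvdrs_present], mil[nvdrs_present],
                           config)

  link <- mdr_present & nvdrs_present
  truth <- data.frame(
    mdr_record_id = mdr$record_id[match(which(link), which(mdr_present))],
    nvdrs_record_id = nvdrs$record_id[match(which(link), which(nvdrs_present))],
    stratum = d$stratum[link],
    stringsAsFactors = FALSE
  )

  # deterministic shuffle so row order carries no information
  mdr <- mdr[sample.int(nrow(mdr)), , drop = FALSE]
  nvdrs <- nvdrs[sample.int(nrow(nvdrs)), , drop = FALSE]
  rownames(mdr) <- rownames(nvdrs) <- NULL

  structure(list(mdr = mdr, nvdrs = nvdrs, truth = truth, config = config),
            class = "sim_registries")
}

miss_mask <- function(n, rate) stats::runif(n) < rate

build_mdr_raw <- function(d, mcod, config) {
  n <- nrow(d)
  r <- config$missingness$mdr
  out <- data.frame(
    record_id = sprintf("MDR-%06d", seq_len(n)),
    state = d$state, year = d$year,
    death_date = format(d$death_date, "%Y-%m-%d"),
    date_of_birth = format(d$dob, "%Y-%m-%d"),
    sex = d$sex, ucod = d$ucod, filn = d$filn,
    veteran_flag = rep(TRUE, n),
    stringsAsFactors = FALSE
  )
  out$death_date[miss_mask(n, r[["death_date"]])] <- NA
  out$date_of_birth[miss_mask(n, r[["date_of_birth"]])] <- NA
  out$sex[miss_mask(n, r[["sex"]])] <- NA
  out$ucod[miss_mask(n, r[["ucod"]])] <- NA
  out$filn[miss_mask(n, r[["filn"]])] <- NA
  cbind(out, mcod_expand(mcod))
}

nvdrs_rates <- function(d, config) {
  # per-record missingness rates, with per-stratum overrides
  base <- config$missingness$nvdrs
  n <- nrow(d)
  rates <- matrix(rep(base, each = n), nrow = n,
                  dimnames = list(NULL, names(base)))
  joint <- rep(config$missingness$joint_dmb_filn, n)
  ov <- config$missingness$stratum_overrides
  for (key in names(ov)) {
    hit <- d$stratum == key | d$state == key
    if (!any(hit)) next
    for (v in names(ov[[key]]$nvdrs %||% numeric())) {
      rates[hit, v] <- ov[[key]]$nvdrs[[v]]
    }
    if (!is.null(ov[[key]]$joint_dmb_filn)) {
      joint[hit] <- ov[[key]]$joint_dmb_filn
    }
  }
  list(rates = rates, joint = joint)
}

build_nvdrs_raw <- function(d, mcod, mil, config) {
  n <- nrow(d)
  dd <- d$death_date
  ucod <- d$ucod
  dmb <- d$dmb
  filn <- d$filn

  # discrepancy injection (values disagree with truth but stay present)
  dr <- config$discrepancy
  w <- miss_mask(n, dr[["death_date"]])
  if (any(w)) {
    ds <- config$date_shift
    small <- stats::runif(sum(w)) < ds$p_small
    mag <- ifelse(small,
                  1L + floor(stats::runif(sum(w)) * ds$small_max),
                  ds$small_max + 1L +
                    floor(stats::runif(sum(w)) * (ds$large_max - ds$small_max)))
    dd[w] <- dd[w] + mag * sample(c(-1L, 1L), sum(w), replace = TRUE)
  }
  w <- miss_mask(n, dr[["ucod"]])
  if (any(w)) {
    su <- w & d$manner == "suicide"
    un <- w & d$manner == "undetermined"
    ucod[su] <- sample(SUICIDE_UCOD_POOL, sum(su), replace = TRUE)
    ucod[un] <- sample(UNDET_UCOD_POOL, sum(un), replace = TRUE)
  }
  w <- miss_mask(n, dr[["dmb"]])
  if (any(w)) dmb[w] <- 1L + (dmb[w] - 1L + sample.int(27L, sum(w), TRUE)) %% 28L
  w <- miss_mask(n, dr[["filn"]])
  if (any(w)) {
    shift <- sample.int(25L, sum(w), replace = TRUE)
    filn[w] <- LETTERS[1L + (match(filn[w], LETTERS) - 1L + shift) %% 26L]
  }

  out <- data.frame(
    record_id = sprintf("NV-%06d", seq_len(n)),
    state = d$state, year = d$year,
    death_date = format(dd, "%Y-%m-%d"),
    age_at_death = d$age, dmb = dmb, sex = d$sex, filn = filn,
    ucod = ucod, manner = d$manner, military_history = mil,
    stringsAsFactors = FALSE
  )

  # missingness: joint dmb/filn component preserves the configured
  # marginal rates (residual rate (r - j) / (1 - j) applied independently)
  mr <- nvdrs_rates(d, config)
  rates <- mr$rates
  j <- mr$joint
  both <- stats::runif(n) < j
  resid <- function(r) ifelse(j < 1, pmax(r - j, 0) / (1 - j), 0)
  dmb_miss <- both | miss_mask(n, resid(rates[, "dmb"]))
  filn_miss <- both | miss_mask(n, resid(rates[, "filn"]))
  out$dmb[dmb_miss] <- NA
  out$filn[filn_miss] <- NA
  out$ucod[miss_mask(n, rates[, "ucod"])] <- NA
  out$death_date[miss_mask(n, rates[, "death_date"])] <- NA
  out$age_at_death[miss_mask(n, rates[, "age_at_death"])] <- NA
  out$sex[miss_mask(n, rates[, "sex"])] <- NA
  cbind(out, mcod_expand(mcod))
}

#' Write simulated registries, truth links and a config echo to disk
#'
#' @param sim a `sim_registries` from [simulate_registries()].
#' @param dir output directory (created if absent).
#' @return named vector of the four file paths, invisibly.
#' @export
write_registries <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_registries"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mdr = file.path(dir, "mdr.csv"),
             nvdrs = file.path(dir, "nvdrs.csv"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "config.yaml"))
  utils::write.csv(sim$mdr, paths[["mdr"]], row.names = FALSE, na = "")
  utils::write.csv(sim$nvdrs, paths[["nvdrs"]], row.names = FALSE, na = "")
  utils::write.csv(sim$truth, paths[["truth"]], row.names = FALSE, na = "")
  cfg <- sim$config
  cfg$indicator_model$p_yes_veteran <-
    as.list(as.data.frame(cfg$indicator_model$p_yes_veteran))
  # named atomic vectors must become lists or YAML drops their names
  yamlify <- function(x) {
    if (is.list(x)) lapply(x, yamlify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(yamlify(unclass(cfg)), paths[["config"]])
  invisible(paths)
}
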