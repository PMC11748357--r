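# Independent oracles and fixture builders used across the suite.

# Brute-force completed-age oracle: counts birthday anniversaries falling
# on or before the reference date (assumes day of birth <= 28).
oracle_age <- function(dob, dod) {
  dob <- as.Date(dob)
  dod <- as.Date(dod)
  b <- as.POSIXlt(dob)
  years <- (b$year + 1901):(as.POSIXlt(dod)$year + 1900)
  ann <- as.Date(sprintf("%04d-%02d-%02d", years, b$mon + 1, b$mday))
  sum(ann <= dod)
}

# One harmonized record row with overridable fields.
make_rec <- function(record_id, source = "MDR", state = "AA", year = 2015L,
                     death_date = as.Date("2015-06-15"), age = 50L,
                     sex = "male", dmb = 10L, filn = "K", ucod = "X70",
                     mcod = "X70 T71", manner = "suicide",
                     military_history = NA_character_, veteran_flag = NA) {
  data.frame(record_id = record_id, source = source, state = state,
             year = as.integer(year), death_date = as.Date(death_date),
             age_at_death = as.integer(age), sex = sex,
             dmb = as.integer(dmb), filn = filn, ucod = ucod, mcod = mcod,
             manner = manner, military_history = military_history,
             veteran_flag = veteran_flag, stringsAsFactors = FALSE)
}

make_recs <- function(...) {
  do.call(rbind, list(...))
}

# Brute-force all-pairs comparator for a single pass: applies the same
# field-equality and missingness rules pair by pair, then keeps the pairs
# whose records each match exactly one counterpart (unique-key matches).
oracle_pass <- function(mdr_pool, nvdrs_pool, spec) {
  vars <- spec$key_variables
  nm <- nrow(mdr_pool)
  nn <- nrow(nvdrs_pool)
  hit <- matrix(FALSE, nm, nn)
  for (i in seq_len(nm)) {
    for (j in seq_len(nn)) {
      if (mdr_pool$state[i] != nvdrs_pool$state[j] ||
          mdr_pool$year[i] != nvdrs_pool$year[j]) next
      if (identical(spec$nvdrs_pool_restriction, "dmb_filn_missing") &&
          !(is.na(nvdrs_pool$dmb[j]) && is.na(nvdrs_pool$filn[j]))) next
      ok <- TRUE
      for (v in vars) {
        a <- mortlink:::render_key_var(mdr_pool[i, ], v)
        b <- mortlink:::render_key_var(nvdrs_pool[j, ], v)
        if (is.na(a) || is.na(b) || a != b) { ok <- FALSE; break }
      }
      hit[i, j] <- ok
    }
  }
  uniq <- which(hit & outer(rowSums(hit) == 1, colSums(hit) == 1, `&`),
                arr.ind = TRUE)
  list(
    matches = data.frame(
      mdr_record_id = mdr_pool$record_id[uniq[, 1]],
      nvdrs_record_id = nvdrs_pool$record_id[uniq[, 2]],
      stringsAsFactors = FALSE),
    dup_mdr = mdr_pool$record_id[rowSums(hit) > 0 &
                                   !seq_len(nm) %in% uniq[, 1]],
    dup_nvdrs = nvdrs_pool$record_id[colSums(hit) > 0 &
                                       !seq_len(nn) %in% uniq[, 2]]
  )
}

# Random pools over tiny alphabets (lots of collisions and missingness)
# for stress-testing pass/oracle equivalence.
random_pools <- function(n_mdr, n_nvdrs, seed) {
  set.seed(seed)
  draw <- function(n, source, prefix) {
    na_or <- function(x, p_na = 0.2) {
      x[runif(n) < p_na] <- NA
      x
    }
    data.frame(
      record_id = sprintf("%s%04d", prefix, seq_len(n)),
      source = source,
      state = sample(c("AA", "BB"), n, replace = TRUE),
      year = sample(2014:2015, n, replace = TRUE),
      death_date = na_or(as.Date("2015-03-01") + sample(0:4, n, TRUE)),
      age_at_death = na_or(sample(40:43, n, TRUE)),
      sex = na_or(sample(c("male", "female"), n, TRUE), 0.1),
      dmb = na_or(sample(1:4, n, TRUE), 0.3),
      filn = na_or(sample(c("A", "B"), n, TRUE), 0.3),
      ucod = na_or(sample(c("X70", "X74", "Y21"), n, TRUE)),
      mcod = paste(sample(c("X70", "X74", "Y21"), n, TRUE),
                   sample(c("T71", "T509", "R99"), n, TRUE)),
      manner = "suicide",
      military_history = if (source == "NVDRS")
        sample(c("yes", "no", "unknown"), n, TRUE) else NA_character_,
      veteran_flag = if (source == "MDR") TRUE else NA,
      stringsAsFactors = FALSE
    )
  }
  list(mdr = draw(n_mdr, "MDR", "M"), nvdrs = draw(n_nvdrs, "NVDRS", "N"))
}

pair_key <- function(df) {
  sort(paste(df$mdr_record_id, df$nvdrs_record_id))
}
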