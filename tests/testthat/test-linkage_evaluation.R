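test_that("match rates reproduce printed-arithmetic conventions", {
  expect_equal(match_rate(22019, 24685), 89.20)
  expect_equal(match_rate(70, 89), 78.65)
  expect_equal(match_rate(0, 100), 0.00)
  # scale invariance over integer multiples
  for (k in c(1L, 2L, 7L)) {
    expect_equal(match_rate(k * 70, k * 89), 78.65)
  }
  expect_warning(na_rate <- match_rate(0, 0), "undefined")
  expect_true(is.na(na_rate))
})

test_that("half-up rounding is used, not banker's rounding", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(pct(1, 8), 12.50)
})

test_that("stratum profiles apply the completeness rule and partial-reporting list", {
  nv <- make_recs(
    # stratum 1: 12% of records missing both dmb and filn -> incomplete
    do.call(rbind, lapply(1:25, function(i) {
      r <- make_rec(sprintf("a%d", i), source = "NVDRS", state = "AA")
      if (i <= 3) { r$dmb <- NA_integer_; r$filn <- NA_character_ }
      r
    })),
    # stratum 2: clean but on the partial-reporting list -> incomplete
    make_rec("b1", source = "NVDRS", state = "BB"),
    # stratum 3: clean, fully reported -> complete
    make_rec("c1", source = "NVDRS", state = "CC")
  )
  prof <- profile_strata(nv, partial_reporting = "BB-2015")
  prof <- prof[order(prof$stratum), ]
  expect_equal(prof$complete, c(FALSE, FALSE, TRUE))
  expect_equal(prof$prop_missing_2plus[1], 0.12)
  expect_true(prof$partial_reporting[2])
  # exactly at the 10% threshold: kept (exclusion is strictly greater) but flagged
  nv10 <- do.call(rbind, lapply(1:20, function(i) {
    r <- make_rec(sprintf("d%d", i), source = "NVDRS", state = "DD")
    if (i <= 2) { r$dmb <- NA_integer_; r$filn <- NA_character_ }
    r
  }))
  p10 <- profile_strata(nv10)
  expect_true(p10$complete)
  expect_true(p10$at_threshold)
})

test_that("tier shares recount the match audit and sum to 100 with the unmatched share", {
  cfg <- default_study_config(seed = 8)
  cfg$decedents_per_stratum <- 120L
  sim <- simulate_registries(cfg)
  mdr <- filter_eligible(harmonize_mdr(sim$mdr))
  nv <- filter_eligible(harmonize_nvdrs(sim$nvdrs))
  res <- run_linkage(mdr, nv)
  prof <- profile_strata(nv, names(cfg$partial_reporting))
  for (restrict in c(FALSE, TRUE)) {
    bd <- stage_breakdown(res, mdr, restrict, prof)
    expect_equal(bd$tier, c("exact", "probable", "possible", "unmatched"))
    expect_lt(abs(sum(bd$pct) - 100), 0.021)
    # recount oracle from the match audit table
    scope <- if (restrict) res$matches$stratum %in%
      prof$stratum[prof$complete] else rep(TRUE, nrow(res$matches))
    expect_equal(bd$n[bd$tier == "exact"],
                 sum(res$matches$tier[scope] == "exact"))
    expect_equal(bd$n[bd$tier == "possible"],
                 sum(res$matches$tier[scope] == "possible"))
  }
  # all matches at stage 1 => exact share equals the overall share
  res1 <- run_linkage(mdr, nv, default_stage_specs()["S1"])
  bd1 <- stage_breakdown(res1, mdr)
  expect_equal(bd1$pct[bd1$tier == "exact"],
               match_rate(nrow(res1$matches), nrow(mdr)))
  # no matches at all
  bd0 <- stage_breakdown(run_linkage(mdr, nv[0, ]), mdr)
  expect_equal(bd0$pct, c(0, 0, 0, 100))
})

test_that("restricting to complete strata never worsens mean missingness", {
  cfg <- default_study_config(seed = 14)
  cfg$decedents_per_stratum <- 200L
  nv <- filter_eligible(harmonize_nvdrs(simulate_registries(cfg)$nvdrs))
  prof <- profile_strata(nv, names(cfg$partial_reporting))
  # the completeness filter targets the variables with heterogeneous
  # missingness across strata (dmb/filn and the 2-plus share)
  mvars <- c("miss_dmb", "miss_filn", "prop_missing_2plus")
  overall <- colMeans(prof[mvars])
  complete <- colMeans(prof[prof$complete, mvars])
  expect_true(all(complete <= overall + 1e-12))
})

test_that("concordance buckets match a brute-force recount and use an inclusive 30-day window", {
  m <- make_recs(
    make_rec("m1", death_date = as.Date("2015-01-01")),
    make_rec("m2", age = 30L, death_date = as.Date("2015-01-01")),
    make_rec("m3", age = 31L, death_date = as.Date("2015-01-01"))
  )
  nv <- make_recs(
    make_rec("n1", source = "NVDRS", death_date = as.Date("2015-01-31")), # +30: within
    make_rec("n2", source = "NVDRS", age = 30L,
             death_date = as.Date("2015-02-01")),                        # +31: over
    make_rec("n3", source = "NVDRS", age = 31L, death_date = NA)         # missing
  )
  res <- run_linkage(m, nv)
  expect_true(all(res$matches$stage_id == "S2d"))
  cr <- concordance_report(res, m, nv)
  s2d <- cr[cr$stage_id == "S2d", ]
  expect_equal(s2d$n[s2d$category == "date_within_30d"], 1L)
  expect_equal(s2d$n[s2d$category == "date_over_30d"], 1L)
  expect_equal(s2d$n[s2d$category == "date_missing"], 1L)
  expect_equal(s2d$pct, rep(33.33, 3))

  # randomized run: buckets equal brute-force recomputation from raw records
  pools <- random_pools(80, 100, 3)
  res2 <- run_linkage(pools$mdr, pools$nvdrs)
  cr2 <- concordance_report(res2, pools$mdr, pools$nvdrs)
  for (st in intersect(c("S2a", "S3b"), cr2$stage_id)) {
    sel <- res2$matches$stage_id == st
    nu <- pools$nvdrs$ucod[match(res2$matches$nvdrs_record_id[sel],
                                 pools$nvdrs$record_id)]
    expect_equal(cr2$n[cr2$stage_id == st & cr2$category == "ucod_missing"],
                 sum(is.na(nu)))
  }
})

test_that("missingness profiling reports counts and 2-dp percentages by source", {
  cfg <- sim_config(seed = 2, decedents_per_stratum = 500L,
                    missingness = list(nvdrs = c(ucod = 0.2)))
  sim <- simulate_registries(cfg)
  both <- rbind(harmonize_mdr(sim$mdr), harmonize_nvdrs(sim$nvdrs))
  pm <- profile_missingness(both)
  row <- pm[pm$source == "NVDRS" & pm$variable == "ucod", ]
  expect_equal(row$n_missing, sum(is.na(harmonize_nvdrs(sim$nvdrs)$ucod)))
  expect_equal(row$pct, pct(row$n_missing, row$n_total))
  expect_true(all(pm$pct[pm$source == "MDR"] == 0))
  # printed-arithmetic conventions at study scale
  expect_equal(pct(9246, 170038), 5.44)
  expect_equal(pct(7237, 170038), 4.26)
  expect_equal(pct(0, 1000), 0.00)
})
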