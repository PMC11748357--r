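test_that("Wilson interval matches the frozen closed-form value and inverts the score test", {
  ci <- wilson_ci(50, 100)
  expect_equal(round(ci$lower, 4), 0.4038)
  expect_equal(round(ci$upper, 4), 0.5962)
  # independent characterization: each endpoint p solves
  # (phat - p)^2 = z^2 p (1 - p) / n
  z <- qnorm(0.975)
  for (case in list(c(50, 100), c(3, 17), c(85, 100), c(4164, 5061))) {
    x <- case[1]; n <- case[2]; phat <- x / n
    ci <- wilson_ci(x, n)
    for (p in c(ci$lower, ci$upper)) {
      expect_equal((phat - p)^2, z^2 * p * (1 - p) / n, tolerance = 1e-9)
    }
  }
  # degenerate ends stay inside [0, 1]
  expect_gte(wilson_ci(0, 20)$lower, 0)
  expect_lte(wilson_ci(20, 20)$upper, 1)
  # interval width shrinks with n at fixed phat
  w <- function(n) diff(unlist(wilson_ci(n / 2, n)))
  expect_true(w(100) > w(400) && w(400) > w(1600))
})

test_that("Clopper-Pearson agrees with the exact binomial test", {
  ref <- binom.test(37, 120)$conf.int
  ci <- clopper_pearson_ci(37, 120)
  expect_equal(ci$lower, ref[1])
  expect_equal(ci$upper, ref[2])
})

test_that("metric arithmetic: sensitivity, PPV and zero-denominator handling", {
  t0 <- data.frame(manner = "all", grouping = "overall", level = "overall",
                   n_mdr_veterans = 100L, n_linked_yes = 85L,
                   n_linked_no = 5L, n_linked_unknown = 0L,
                   n_unlinked_yes = 10L, n_unlinked_no = 200L,
                   n_unlinked_unknown = 5L, stringsAsFactors = FALSE)
  m <- metrics_from_table(t0)
  g <- function(metric) m[m$metric == metric, ]
  expect_equal(g("sensitivity")$estimate, 85.00)
  expect_equal(g("ppv")$estimate, pct(85, 95))
  expect_equal(g("npv")$estimate, pct(200, 205))
  expect_equal(g("specificity")$estimate, pct(200, 215))
  expect_equal(g("accuracy")$estimate, pct(85 + 200, 305))
  expect_true(all(m$ci_low <= m$estimate & m$estimate <= m$ci_high))
  # PPV with the printed-arithmetic convention: 40 of 50 yes-records linked
  t1 <- t0; t1$n_linked_yes <- 40L; t1$n_unlinked_yes <- 10L
  m1 <- metrics_from_table(t1)
  expect_equal(m1$estimate[m1$metric == "ppv"], 80.00)
  # empty stratum: every denominator zero -> NA, never 0/0 = 0
  t2 <- t0; t2[4:10] <- 0L
  m2 <- metrics_from_table(t2)
  expect_true(all(is.na(m2$estimate)))
})

test_that("a perfect indicator with noise-free linkage scores 100% everywhere", {
  cfg <- sim_config(seed = 6, decedents_per_stratum = 2000L,
                    veteran_fraction = 0.2,
                    indicator_model = list(p_yes_veteran = 1,
                                           p_yes_nonveteran = 0,
                                           p_unknown = 0))
  sim <- simulate_registries(cfg)
  mdr <- filter_eligible(harmonize_mdr(sim$mdr))
  nv <- filter_eligible(harmonize_nvdrs(sim$nvdrs))
  res <- run_linkage(mdr, nv)
  prof <- profile_strata(nv)
  mets <- metrics_from_table(build_validity_tables(res, mdr, nv, prof))
  filled <- mets[!is.na(mets$estimate) & mets$n > 0, ]
  expect_true(all(filled$estimate == 100))
})

test_that("validity bookkeeping: cells partition the in-scope records", {
  cfg <- default_study_config(seed = 23)
  cfg$decedents_per_stratum <- 150L
  sim <- simulate_registries(cfg)
  mdr <- filter_eligible(harmonize_mdr(sim$mdr))
  nv <- filter_eligible(harmonize_nvdrs(sim$nvdrs))
  res <- run_linkage(mdr, nv)
  prof <- profile_strata(nv, names(cfg$partial_reporting))
  vt <- build_validity_tables(res, mdr, nv, prof)
  keep <- prof$stratum[prof$complete]
  n_nv_scope <- sum(stratum_label(nv$state, nv$year) %in% keep)
  n_mdr_scope <- sum(stratum_label(mdr$state, mdr$year) %in% keep)
  ov <- vt[vt$manner == "all" & vt$grouping == "overall", ]
  nv_cells <- ov$n_linked_yes + ov$n_linked_no + ov$n_linked_unknown +
    ov$n_unlinked_yes + ov$n_unlinked_no + ov$n_unlinked_unknown
  expect_equal(nv_cells, n_nv_scope)
  expect_equal(ov$n_mdr_veterans, n_mdr_scope)
  # sum over the six counts equals unmatched gold records plus all
  # surveillance records in scope
  linked_in_scope <- sum(res$matches$stratum %in% keep)
  expect_equal(ov$n_mdr_veterans - (ov$n_linked_yes + ov$n_linked_no +
                                      ov$n_linked_unknown),
               n_mdr_scope - linked_in_scope)
  # manner rows nest inside 'all'; sex rows drop missing-sex records only
  su <- vt[vt$manner == "suicide" & vt$grouping == "overall", ]
  un <- vt[vt$manner == "undetermined" & vt$grouping == "overall", ]
  expect_equal(su$n_mdr_veterans + un$n_mdr_veterans, ov$n_mdr_veterans)
  sx <- vt[vt$manner == "all" & vt$grouping == "sex", ]
  nv_scope <- nv[stratum_label(nv$state, nv$year) %in% keep, ]
  expect_equal(sum(sx$n_linked_yes + sx$n_linked_no + sx$n_linked_unknown +
                     sx$n_unlinked_yes + sx$n_unlinked_no +
                     sx$n_unlinked_unknown),
               sum(!is.na(nv_scope$sex)))
})

test_that("accuracy equals a brute-force record-by-record agreement recount", {
  cfg <- default_study_config(seed = 19)
  cfg$decedents_per_stratum <- 150L
  sim <- simulate_registries(cfg)
  mdr <- filter_eligible(harmonize_mdr(sim$mdr))
  nv <- filter_eligible(harmonize_nvdrs(sim$nvdrs))
  res <- run_linkage(mdr, nv)
  prof <- profile_strata(nv, names(cfg$partial_reporting))
  mets <- metrics_from_table(build_validity_tables(res, mdr, nv, prof))
  acc <- mets[mets$manner == "all" & mets$grouping == "overall" &
                mets$metric == "accuracy", ]
  keep <- prof$stratum[prof$complete]
  scope <- nv[stratum_label(nv$state, nv$year) %in% keep, ]
  linked <- scope$record_id %in% res$matches$nvdrs_record_id
  correct <- ifelse(linked, scope$military_history == "yes",
                    scope$military_history == "no")
  expect_equal(acc$estimate, pct(sum(correct), nrow(scope)))
})
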