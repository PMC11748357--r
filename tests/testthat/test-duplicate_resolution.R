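specs <- default_stage_specs()

group_of <- function(mdr, nvdrs) {
  list(stratum = "AA-2015", key = "k",
       mdr_ids = mdr$record_id, nvdrs_ids = nvdrs$record_id)
}

test_that("unique MCOD containment resolves a two-candidate group", {
  m <- make_rec("m1", mcod = "X70 T71")
  nv <- make_recs(
    make_rec("a", source = "NVDRS", mcod = "X70 T71 R99"),
    make_rec("b", source = "NVDRS", mcod = "X70")
  )
  out <- resolve_group(group_of(m, nv), m, nv, specs$S2d)
  expect_true(out$resolved)
  expect_equal(out$nvdrs_id, "a")
  expect_equal(out$resolution, "mcod_rule")
})

test_that("with MCOD uninformative, the closer death date wins at stage 2d", {
  m <- make_rec("m1", mcod = "X70 T71", death_date = as.Date("2015-06-15"))
  nv <- make_recs(
    make_rec("a", source = "NVDRS", mcod = "X70 T71 R99",
             death_date = as.Date("2015-06-17")),
    make_rec("b", source = "NVDRS", mcod = "X70 T71 T509",
             death_date = as.Date("2015-07-30"))
  )
  # both candidates satisfy containment -> Rule 1 cannot single one out
  out <- resolve_group(group_of(m, nv), m, nv, specs$S2d)
  expect_true(out$resolved)
  expect_equal(out$nvdrs_id, "a")
  expect_equal(out$resolution, "field_review_rule")
})

test_that("exact agreement on the relaxed variable resolves before date distance", {
  m <- make_rec("m1", mcod = "X70 T71", ucod = "X70")
  nv <- make_recs(
    make_rec("a", source = "NVDRS", mcod = "X70 T71", ucod = "X74"),
    make_rec("b", source = "NVDRS", mcod = "X70 T71", ucod = "X70")
  )
  out <- resolve_group(group_of(m, nv), m, nv, specs$S2a)
  expect_true(out$resolved)
  expect_equal(out$nvdrs_id, "b")
  expect_equal(out$resolution, "field_review_rule")
})

test_that("the military indicator breaks remaining ties only via a unique 'yes'", {
  m <- make_rec("m1", mcod = "X70", death_date = as.Date("2015-06-15"))
  nv <- make_recs(
    make_rec("a", source = "NVDRS", mcod = "", military_history = "yes",
             death_date = NA),
    make_rec("b", source = "NVDRS", mcod = "", military_history = "no",
             death_date = NA)
  )
  out <- resolve_group(group_of(m, nv), m, nv, specs$S2d)
  expect_true(out$resolved)
  expect_equal(out$nvdrs_id, "a")
  expect_equal(out$resolution, "military_rule")

  # two 'yes' candidates: no resolution
  nv2 <- nv; nv2$military_history <- "yes"
  expect_false(resolve_group(group_of(m, nv2), m, nv2, specs$S2d)$resolved)
})

test_that("all reviewed surveillance fields missing means unresolved", {
  m <- make_rec("m1", mcod = "X70 T71")
  nv <- make_recs(
    make_rec("a", source = "NVDRS", mcod = "", death_date = NA,
             military_history = "unknown"),
    make_rec("b", source = "NVDRS", mcod = "", death_date = NA,
             military_history = "unknown")
  )
  expect_false(resolve_group(group_of(m, nv), m, nv, specs$S2d)$resolved)
})

test_that("two gold candidates for one surveillance record: containment applies, the indicator cannot", {
  mm <- make_recs(
    make_rec("m1", mcod = "X70 T71"),
    make_rec("m2", mcod = "X70 T509")
  )
  nv <- make_rec("a", source = "NVDRS", mcod = "X70 T71 R99",
                 military_history = "yes")
  out <- resolve_group(group_of(mm, nv), mm, nv, specs$S2d)
  expect_true(out$resolved)
  expect_equal(out$mdr_id, "m1")
  expect_equal(out$resolution, "mcod_rule")

  # indicator is an NVDRS attribute: with >1 gold candidate and no other
  # evidence, the group stays unresolved even though the indicator is 'yes'
  mm2 <- make_recs(
    make_rec("m1", mcod = "X70 T71", death_date = NA),
    make_rec("m2", mcod = "X70 T71", death_date = NA)
  )
  nv2 <- make_rec("a", source = "NVDRS", mcod = "X70 T71",
                  military_history = "yes", death_date = NA)
  expect_false(resolve_group(group_of(mm2, nv2), mm2, nv2, specs$S2d)$resolved)
})

test_that("resolution is invariant to candidate order", {
  m <- make_rec("m1", mcod = "X70 T71", death_date = as.Date("2015-06-15"))
  nv <- make_recs(
    make_rec("a", source = "NVDRS", mcod = "X70 T71 R99",
             death_date = as.Date("2015-06-13")),
    make_rec("b", source = "NVDRS", mcod = "X70",
             death_date = as.Date("2015-06-30")),
    make_rec("c", source = "NVDRS", mcod = "X70",
             death_date = as.Date("2015-08-01"))
  )
  for (perm in list(1:3, 3:1, c(2, 3, 1))) {
    nvp <- nv[perm, ]
    g <- group_of(m, nvp)
    out <- resolve_group(g, m, nvp, specs$S2d)
    expect_true(out$resolved)
    expect_equal(out$nvdrs_id, "a")
  }
})

test_that("unresolved group members are released and can match in later passes", {
  # two surveillance candidates collide at S2a (ucod dropped); neither is
  # resolvable; the true partner of each then matches at a later pass
  m <- make_rec("m1", ucod = "X70", mcod = "")
  nv <- make_recs(
    make_rec("a", source = "NVDRS", ucod = NA, mcod = "",
             military_history = "unknown"),
    make_rec("b", source = "NVDRS", ucod = NA, mcod = "",
             military_history = "unknown")
  )
  specs_sub <- default_stage_specs()
  p <- run_pass(m, nv, specs_sub$S2a)
  expect_equal(nrow(p$matches), 0L)
  expect_equal(nrow(p$groups), 1L)
  expect_false(p$groups$resolved)
  expect_equal(nrow(p$mdr_remaining), 1L)
  expect_equal(nrow(p$nvdrs_remaining), 2L)
})

test_that("resolution shares are reported as percentages of resolved groups", {
  fake <- list(matches = data.frame(
    resolution = c(rep("mcod_rule", 15), rep("military_rule", 5),
                   rep("field_review_rule", 3), rep("unique_key", 100)),
    stringsAsFactors = FALSE))
  s <- summarize_resolutions(fake)
  expect_equal(s$pct[s$method == "mcod_rule"], 65.22)
  expect_equal(s$pct[s$method == "military_rule"], 21.74)
  expect_equal(s$pct[s$method == "field_review_rule"], 13.04)
  expect_equal(sum(s$n), 23L)
  empty <- summarize_resolutions(list(matches = data.frame(
    resolution = rep("unique_key", 4), stringsAsFactors = FALSE)))
  expect_identical(nrow(empty), 0L)
})

test_that("ground-truth-correct resolution when true MCOD containment is unique", {
  # a duplicate engineered from the generator's containment guarantee:
  # truth pair shares MCOD superset; decoy record has a different MCOD
  m <- make_rec("m1", ucod = NA, mcod = "X74 T509")
  nv <- make_recs(
    make_rec("true", source = "NVDRS", ucod = NA, mcod = "X74 T509 R99"),
    make_rec("decoy", source = "NVDRS", ucod = NA, mcod = "X74 T71")
  )
  out <- resolve_group(group_of(m, nv), m, nv, specs$S2a)
  expect_true(out$resolved)
  expect_equal(out$nvdrs_id, "true")
})
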