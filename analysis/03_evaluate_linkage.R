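#!/usr/bin/env Rscript
# Step 3 — evaluate linkage success.
#
# Profiles state-year strata (missingness, partial reporting, the
# completeness rule), computes match rates overall / by tier / by
# stratum, and runs the concordance diagnostics for the passes that
# relaxed UCOD (2a, 3b) and death date (2d).

suppressPackageStartupMessages(library(mortlink))

cfg <- yaml::read_yaml("results/registries/config.yaml")
mdr <- filter_eligible(read_registry("results/registries/mdr.csv", "MDR"))
nvdrs <- filter_eligible(read_registry("results/registries/nvdrs.csv", "NVDRS"))
matches <- read.csv("results/linkage/matches.csv", stringsAsFactors = FALSE)
result <- list(matches = matches)

profiles <- profile_strata(nvdrs, names(cfg$partial_reporting))
cat(sprintf("%d of %d state-year strata are complete (full reporting and <=10%% of records missing 2+ linkage variables)\n",
            sum(profiles$complete), nrow(profiles)))

bd_all <- stage_breakdown(result, mdr)
bd_complete <- stage_breakdown(result, mdr, TRUE, profiles)
cat("\nAll strata, share of gold records by tier:\n")
print(bd_all, row.names = FALSE)
cat("\nComplete strata only:\n")
print(bd_complete, row.names = FALSE)

rates <- state_year_match_rates(result, mdr)
cat(sprintf("\nPer-stratum match rate: mean %.2f%%, range %.2f-%.2f%%\n",
            mean(rates$pct), min(rates$pct), max(rates$pct)))

conc <- concordance_report(result, mdr, nvdrs)
cat("\nConcordance of relaxed variables among linked pairs:\n")
print(conc, row.names = FALSE)

missy <- profile_missingness(rbind(mdr, nvdrs))
cat("\nMissingness of linkage variables by source (%):\n")
print(missy, row.names = FALSE)

dir.create("results/evaluation", recursive = TRUE, showWarnings = FALSE)
write.csv(profiles, "results/evaluation/strata_profiles.csv", row.names = FALSE)
write.csv(rbind(cbind(scope = "all", bd_all),
                cbind(scope = "complete", bd_complete)),
          "results/evaluation/tier_breakdown.csv", row.names = FALSE)
write.csv(rates, "results/evaluation/state_year_rates.csv", row.names = FALSE)
write.csv(conc, "results/evaluation/concordance.csv", row.names = FALSE)
write.csv(missy, "results/evaluation/missingness.csv", row.names = FALSE)
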