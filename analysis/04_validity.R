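#!/usr/bin/env Rscript
# Step 4 — validity of the surveillance military-history indicator.
#
# Within complete state-year strata, cross-tabulates the indicator
# against linked Veteran status and reports sensitivity, specificity,
# accuracy, PPV and NPV with 95% Wilson confidence intervals, overall
# and stratified by manner of death, sex and age band.

suppressPackageStartupMessages(library(mortlink))

cfg <- yaml::read_yaml("results/registries/config.yaml")
mdr <- filter_eligible(read_registry("results/registries/mdr.csv", "MDR"))
nvdrs <- filter_eligible(read_registry("results/registries/nvdrs.csv", "NVDRS"))
matches <- read.csv("results/linkage/matches.csv", stringsAsFactors = FALSE)
result <- list(matches = matches)
profiles <- profile_strata(nvdrs, names(cfg$partial_reporting))

tables <- build_validity_tables(result, mdr, nvdrs, profiles)
metrics <- metrics_from_table(tables, ci_method = "wilson")

show <- metrics[metrics$grouping == "overall",
                c("manner", "metric", "estimate", "ci_low", "ci_high")]
cat("Indicator validity, overall by manner of death (%):\n")
print(show, row.names = FALSE)

sens <- metrics[metrics$metric == "sensitivity" & metrics$manner == "all",
                c("grouping", "level", "estimate", "ci_low", "ci_high")]
cat("\nSensitivity by stratum (both manners):\n")
print(sens, row.names = FALSE)

dir.create("results/validity", recursive = TRUE, showWarnings = FALSE)
write.csv(metrics, "results/validity/validity.csv", row.names = FALSE)
cat("\nWritten results/validity/validity.csv\n")
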