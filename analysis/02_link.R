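#!/usr/bin/env Rscript
# Step 2 — run the three-stage, seven-pass deterministic linkage.
#
# Harmonizes both registries (deriving dmb and age from the gold
# registry's date of birth, which is then dropped), restricts to eligible
# suicide/undetermined deaths aged 17+, and links within state-year
# strata with progressively relaxed concatenated keys.  Duplicate groups
# are arbitrated by the MCOD / relaxed-field / military-indicator
# cascade.  Writes the match audit trail under results/linkage/.

suppressPackageStartupMessages(library(mortlink))

mdr <- filter_eligible(read_registry("results/registries/mdr.csv", "MDR"))
nvdrs <- filter_eligible(read_registry("results/registries/nvdrs.csv", "NVDRS"))
cat(sprintf("Eligible records: %d gold, %d surveillance\n",
            nrow(mdr), nrow(nvdrs)))

result <- run_linkage(mdr, nvdrs)
print(result)
cat("\nDuplicate-group resolutions:\n")
print(summarize_resolutions(result), row.names = FALSE)

dir.create("results/linkage", recursive = TRUE, showWarnings = FALSE)
write.csv(result$matches, "results/linkage/matches.csv", row.names = FALSE)
write.csv(result$stage_counts, "results/linkage/stage_counts.csv",
          row.names = FALSE)
write.csv(result$duplicates, "results/linkage/duplicates.csv",
          row.names = FALSE, na = "")
write.csv(data.frame(record_id = result$unmatched_mdr),
          "results/linkage/unmatched_mdr.csv", row.names = FALSE)
write.csv(data.frame(record_id = result$unmatched_nvdrs),
          "results/linkage/unmatched_nvdrs.csv", row.names = FALSE)

# ground-truth audit, possible only in the synthetic world
truth <- read.csv("results/registries/truth.csv", stringsAsFactors = FALSE)
tp <- paste(truth$mdr_record_id, truth$nvdrs_record_id)
lp <- paste(result$matches$mdr_record_id, result$matches$nvdrs_record_id)
cat(sprintf("\nGround truth: %s%% of true links recovered; %s%% of reported pairs are false\n",
            pct(sum(tp %in% lp), length(tp)),
            pct(sum(!lp %in% tp), length(lp))))
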