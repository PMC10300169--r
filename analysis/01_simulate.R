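#!/usr/bin/env Rscript
# Stage 1: generate the matched case-control lipidomics cohort.
#
# Writes subjects.csv / lipids.csv / truth.json under results/run/cohort.
# The truth sidecar records the generating blocks and the planted effects;
# removing it makes the run indistinguishable from a real-data analysis.

source(file.path("analysis", "00_config.R"))

bundle <- run_pipeline(analysis_config("simulate"))
co <- bundle$cohort

cat("\nCohort generated:\n")
print(co)
cat("cases:", sum(co$subjects$is_case),
    " controls:", sum(1 - co$subjects$is_case), "\n")
cat("stratum size distribution:\n")
print(table(table(co$subjects$stratum_id)))
cat("planted effects (log-odds per SD):\n")
print(co$truth$effects)
cat("generating composite effect:", round(co$truth$composite_sd, 3),
    "log-odds per SD of the true score\n")
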