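#!/usr/bin/env Rscript
# Stage 7: human-readable summary of the whole run.

source(file.path("analysis", "00_config.R"))

truth <- tryCatch(read_cohort(file.path(RUN_DIR, "cohort"))$truth,
                  error = function(e) NULL)
make_report(RUN_DIR, truth = truth)
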