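#!/usr/bin/env Rscript
# Stage 3: conditional-independence lipid network and walktrap clusters.
#
# PC-algorithm skeletons are learned on two random halves of the strata;
# edges present in both halves with |partial correlation| > 0.1 on the
# pooled data form the robust network, and walktrap (4-step random walks,
# maximum-modularity cut) partitions it into lipid clusters.

source(file.path("analysis", "00_config.R"))

bundle <- run_pipeline(analysis_config("network"))
net <- bundle$network

cat("\nRobust network:", length(net$nodes), "lipids,",
    nrow(net$edges), "edges,", max(net$partition), "walktrap clusters\n")
cat("cluster sizes:\n")
print(table(net$partition))

# how well do detected clusters align with the generating blocks?
co <- bundle$cohort
truth <- co$truth$clusters[net$nodes]
purity <- vapply(split(truth, net$partition),
                 function(v) max(table(v)) / length(v), 0)
cat("majority-block purity by cluster (weighted mean ",
    round(stats::weighted.mean(purity, table(net$partition)), 3), "):\n",
    sep = "")
print(round(purity, 2))
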