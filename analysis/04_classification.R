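#!/usr/bin/env Rscript
# Stage 4 — MRMR + linear-SVM classification.
#
# The five study analyses on the cohort feature table: three two-class
# contrasts and the three-region multiclass run as one-vs-rest and
# one-vs-one, each on the top-25 MRMR features (selected within each
# training fold) with C chosen from the six-value grid by mean CV
# validation accuracy.

library(stnerp)

tab <- read_feature_table("scratch/features.csv")
dir.create("results", showWarnings = FALSE)

cls <- full_pipeline_classification(tab, pipeline_config(), seed = 1)
write.csv(cls$summary, "results/classification.csv", row.names = FALSE)

conf <- cls$runs$multiclass_ovr$confusion
write.csv(as.data.frame.matrix(conf), "results/confusion_ovr.csv")

print(cls$summary[, c("analysis", "c", "accuracy_train",
                      "accuracy_test", "accuracy_test_sd")])
message("multiclass OvR confusion (rows = truth):")
print(conf)
message("wrote results/classification.csv")
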