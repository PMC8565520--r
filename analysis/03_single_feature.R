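#!/usr/bin/env Rscript
# Stage 3 — single-feature biomarker analysis.
#
# For the three reporting features (medial fronto-central, right
# fronto-central and medial occipital-parietal max-peak latency in the
# 50-100 ms window) and their region contrasts: independent t-test plus
# the 5-fold cross-validated ROC cutoff model.

library(stnerp)

tab <- read_feature_table("scratch/features.csv")
dir.create("results", showWarnings = FALSE)

cases <- list(
  list(pair = c("ZI", "VMR"), loc = "medial_fronto_central"),
  list(pair = c("ZI", "DLR"), loc = "right_fronto_central"),
  list(pair = c("DLR", "VMR"), loc = "medial_occipital_parietal"))

rows <- lapply(cases, function(cs) {
  r <- single_feature_report(tab, cs$pair, cs$loc, "middle", "max_latency",
                             k = 5, seed = 1)
  data.frame(
    contrast = paste(cs$pair, collapse = "_vs_"), location = cs$loc,
    window = "middle", kind = "max_latency",
    t = r$t_test$t, p = r$t_test$p, df = r$t_test$df,
    auc_full = r$roc$auc, cutoff = r$roc$cutoff,
    precision_test = r$cv$test$mean["precision"],
    recall_test = r$cv$test$mean["recall"],
    accuracy_test = r$cv$test$mean["accuracy"],
    auc_test = r$cv$test$mean["auc"],
    accuracy_test_sd = r$cv$test$sd["accuracy"],
    auc_test_sd = r$cv$test$sd["auc"], row.names = NULL)
})
out <- do.call(rbind, rows)
write.csv(out, "results/single_feature.csv", row.names = FALSE)
print(out[, c("contrast", "location", "t", "p", "auc_test", "accuracy_test")])
message("wrote results/single_feature.csv")
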