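#!/usr/bin/env Rscript
# Relative quantification of the bundle's paired QMSP measurements: compute
# each sample's methylated-target/ACTB level, calibrate tumors to their
# paired normals, and apply the at-least-twofold hypermethylation rule.
# Also demonstrates the treatment-effect report used for demethylating-agent
# experiments (percent of control and fold change).

library(methfunnel)

cq <- read_cq_table("results/bundle/qmsp_cq.csv")
levels <- lapply(cq, relative_level)

ids <- sub("_[TN]$", "", names(levels))
calls <- do.call(rbind, lapply(unique(ids), function(p) {
  tum <- levels[[paste0(p, "_T")]]
  nor <- levels[[paste0(p, "_N")]]
  fold <- calibrated_fold(tum, nor)
  data.frame(pair = p, tumor_level = tum$level, normal_level = nor$level,
             fold = as.numeric(fold),
             hypermethylated = call_hypermethylation_qmsp(fold))
}))

dir.create("results/qpcr", showWarnings = FALSE, recursive = TRUE)
write.table(calls, "results/qpcr/qmsp_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("QMSP: %d / %d tumor/normal pairs called hypermethylated (>= 2-fold)\n",
            sum(calls$hypermethylated), nrow(calls)))

# demethylating-treatment reporting format
eff <- treatment_effect(treated = c(0.27, 0.29, 0.30), control = c(1.0, 0.98, 1.02))
cat(sprintf("Example treatment effect: methylation at %.2f%% of control (fold %.3f, sd %.3f)\n",
            eff$percent_of_control, eff$fold_change, eff$sd_fold))
cat("Calls written to results/qpcr/qmsp_calls.tsv\n")
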