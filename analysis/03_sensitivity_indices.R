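#!/usr/bin/env Rscript
# Sensitivity indices on the gated exams: pointwise maps, mean sensitivity,
# hill-of-vision volume sensitivity, hemifield means, and the cyan-red
# difference summaries and classifications.
suppressPackageStartupMessages(library(scotoperim))

records <- read_exam_table("results/cohort")
res <- run_pipeline(records, n_boot = 0)
i1 <- res$indices[res$indices$session == "test1", ]

write.csv(res$indices, "results/indices.csv", row.names = FALSE)
write.csv(res$pointwise, "results/pointwise.csv", row.names = FALSE)
write.csv(res$comparisons, "results/comparisons.csv", row.names = FALSE)

cat("Median indices by group and color (test1, gated exams):\n")
for (grp in unique(i1$group)) for (col in unique(i1$color)) {
  v <- i1[i1$group == grp & i1$color == col, ]
  cat(sprintf("  %-14s %-10s MS %5.1f dB   VS %7.1f dB*deg^2  (n=%d)\n",
              grp, sub("_.*", "", col), median(v$mean_sensitivity),
              median(v$volume_sensitivity), nrow(v)))
}
cat("\nHemifield means (patients, test1): temporal vs nasal\n")
chm <- i1[i1$group == "choroideremia", ]
for (col in unique(chm$color)) {
  v <- chm[chm$color == col, ]
  pc <- paired_comparison(v$temporal_mean, v$nasal_mean)
  cat(sprintf("  %-10s temporal %.1f dB, nasal %.1f dB (Wilcoxon p = %.3g)\n",
              sub("_.*", "", col), median(v$temporal_mean),
              median(v$nasal_mean), pc$p_value))
}
cat("\nGroup and color comparisons (Mann-Whitney / Wilcoxon):\n")
print(res$comparisons, row.names = FALSE)

# per-locus cyan-red difference classes for one example patient, at the
# 0 / 4 / 13 dB variability allowances
rec1 <- Filter(function(r) r$group == "choroideremia", records)[[1]]
dm <- pointwise_difference(normalize_eye(rec1$exams[["scotopic.cyan_505nm.test1"]]),
                           normalize_eye(rec1$exams[["scotopic.red_627nm.test1"]]))
healthy_cy <- lapply(Filter(function(r) r$group == "healthy", records),
                     function(r) r$exams[["scotopic.cyan_505nm.test1"]])
norm <- normative_pointwise(healthy_cy)
for (thr in c(0, 4, 13)) {
  cl <- classify_difference(dm, thr, normative = norm)
  cat(sprintf("\nDifference classes at +/-%g dB for %s:\n", thr,
              rec1$subject_id))
  print(table(cl$class))
}
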