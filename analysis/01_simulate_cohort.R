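#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 21 healthy controls and 20
# choroideremia patients, each with dark-adapted cyan and red exams on the
# 37-locus radial grid; the first 10 patients repeat both exams (test2).
# Writes the exam exchange files under results/cohort/.
suppressPackageStartupMessages(library(scotoperim))

seed <- 20240930L
config <- cohort_config(seed = seed) # study-sized defaults
records <- simulate_cohort(config)

dir.create("results", showWarnings = FALSE)
write_exam_table(records, "results/cohort")

n_exams <- sum(vapply(records, function(r) length(r$exams), integer(1)))
cat(sprintf("Simulated %d subjects (%d exams) with seed %d\n",
            length(records), n_exams, seed))
cat(sprintf("Scotopic tests: %d; repeat-testing patients: %d\n",
            n_exams, config$n_retest_choroideremia))
cat("Exam tables written to results/cohort/\n")
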