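#!/usr/bin/env Rscript
# Composite repetition outcome: scale-maximum normalisation of the two
# instruments, averaging, then OLS adjustment for age and months
# post-stroke. The adjusted residual is the outcome for all modelling.
source(file.path("analysis", "00_config.R"))

subj <- read.table(file.path(RES, "cohort", "subjects.tsv"),
                   sep = "\t", header = TRUE)
comp <- composite_repetition(subj$score_a, subj$score_b)
adj <- adjust_covariates(comp, subj$age, subj$months_post)
print(adj)
cat(sprintf("instrument correlation r = %.3f; mean composite %.2f\n",
            intertest_correlation(subj$score_a, subj$score_b), mean(comp)))
write.table(data.frame(subject_id = subj$subject_id, composite = comp,
                       adjusted = adj$residuals),
            file.path(RES, "behavior.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
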