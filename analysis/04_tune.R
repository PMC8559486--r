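#!/usr/bin/env Rscript
# 70/30 split and keepX tuning on the training set by repeated 5-fold
# cross-validation (50 repeats) under mean absolute error.
source(file.path("analysis", "00_config.R"))

X <- as.matrix(read.table(file.path(RES, "features.tsv"), sep = "\t",
                          header = TRUE, row.names = 1, check.names = FALSE))
beh <- read.table(file.path(RES, "behavior.tsv"), sep = "\t", header = TRUE)
y <- beh$adjusted
split <- split_cohort(nrow(X), 0.7, seed = SEED)
tuning <- tune_keepX(X[split$train_indices, ], y[split$train_indices],
                     spls_config(seed = SEED))
print(tuning)
write.table(tuning$cv_table, file.path(RES, "cv_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(as.character(tuning$keepX), file.path(RES, "keepX.txt"))
cat(sprintf("training on %d subjects, held-out test %d\n",
            length(split$train_indices), length(split$test_indices)))
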