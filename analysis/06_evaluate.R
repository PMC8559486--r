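#!/usr/bin/env Rscript
# Nested models from the VIP-ranked candidates (all / top 10 / top 2),
# trained on the training set, evaluated on the held-out test set by
# one-tailed correlation; full-cohort refit report; feature clustering;
# severity-group connectivity summaries.
source(file.path("analysis", "00_config.R"))

X <- as.matrix(read.table(file.path(RES, "features.tsv"), sep = "\t",
                          header = TRUE, row.names = 1, check.names = FALSE))
beh <- read.table(file.path(RES, "behavior.tsv"), sep = "\t", header = TRUE)
y <- beh$adjusted
cand <- read.table(file.path(RES, "candidates.tsv"), sep = "\t", header = TRUE)
split <- split_cohort(nrow(X), 0.7, seed = SEED)

subsets <- nested_models(cand)
ev <- evaluate_nested_models(X, y, split, subsets)
print(ev$table, row.names = FALSE)
write.table(ev$table, file.path(RES, "nested_models.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sizes <- vapply(subsets, length, 1L)
best <- subsets[[which(sizes == min(10L, max(sizes)))[1]]]
refit <- final_refit_report(X, y, best)
write.table(refit, file.path(RES, "final_refit.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("full-cohort refit, top rows:\n")
print(head(refit, 5), row.names = FALSE, digits = 3)

if (nrow(cand) >= 2) {
  cl <- cluster_features(X[, cand$edge], linkage = "average", n_clusters = 4)
  write.table(data.frame(edge = names(cl$labels), cluster = cl$labels),
              file.path(RES, "feature_clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sev <- cut(beh$composite, quantile(beh$composite, c(0, 1/3, 2/3, 1)),
             labels = c("severe", "moderate", "mild"), include.lowest = TRUE)
  gs <- group_summary(X, as.character(sev), cand$edge,
                      group_order = c("mild", "moderate", "severe"))
  write.table(gs, file.path(RES, "group_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("clustered %d candidates into %d groups\n",
              nrow(cand), length(unique(cl$labels))))
}
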