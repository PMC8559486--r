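#!/usr/bin/env Rscript
# Vectorise the per-subject connectivity matrices into the subjects x
# edges feature table, apply the mean-connectivity >= 1 threshold, and
# force-include the cross-group SLF edge set.
source(file.path("analysis", "00_config.R"))

mats <- read_cohort_matrices(file.path(RES, "cohort"))
fm_full <- build_feature_matrix(mats)
forced <- slf_edge_set(atlas)
fm <- threshold_and_force(fm_full, mean_threshold = 1, forced = forced)
write_feature_matrix(fm, RES)

cat(sprintf("edge universe %d -> kept %d (%d threshold survivors, %d forced SLF)\n",
            ncol(fm_full$values), ncol(fm$values),
            sum(fm$survived_threshold), sum(fm$forced_slf)))
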