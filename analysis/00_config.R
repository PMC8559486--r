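# Shared settings for the analysis scripts. Everything downstream is a
# deterministic function of this seed.
library(connlsm)
SEED <- 1L
RES <- file.path("results")
dir.create(RES, recursive = TRUE, showWarnings = FALSE)
atlas <- generate_atlas(25L, seed = SEED)   # reference 25-region atlas
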