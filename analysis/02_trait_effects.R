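#!/usr/bin/env Rscript

# Subsampled pooled-SD effect sizes for the eleven personality instruments
# (thirteen scores: Big Five, self-esteem, narcissism and its two facets,
# stress, locus of control, satisfaction with life, loneliness). Negative
# effect sizes mean women score higher.

suppressPackageStartupMessages(library(gendernet))

model <- read_cohort("results/cohort")
coh <- filter_active(model$cohort)
labels <- gender_labels(coh)
traits <- model$traits[match(coh$participants$id, model$traits$id), ]
feats <- traits[setdiff(names(traits), "id")]
rownames(feats) <- traits$id

eff <- effect_size_table(feats, labels, n_subsamples = 1000, seed = 2026)
eff <- eff[order(eff$mean_r), ]
dir.create("results", showWarnings = FALSE)
write.csv(eff, "results/trait_effects.csv", row.names = FALSE)

cat("trait effect sizes (male minus female, pooled-SD units):\n")
for (i in seq_len(nrow(eff)))
  cat(sprintf("  %-22s %+.3f [%+.3f, %+.3f]%s\n", eff$indicator[i],
              eff$mean_r[i], eff$p5[i], eff$p95[i],
              ifelse(isTRUE(eff$significant[i]), " *", "")))
cat("(* = 5-95% subsample percentile band excludes zero)\n")
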