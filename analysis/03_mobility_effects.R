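#!/usr/bin/env Rscript

# Mobility indicators: weekly location entropy (nats) and unique-location
# counts, averaged per participant, then compared between genders with the
# same subsampled effect-size machinery used for traits.

suppressPackageStartupMessages(library(gendernet))

model <- read_cohort("results/cohort")
coh <- filter_active(model$cohort)
labels <- gender_labels(coh)

mob <- mobility_indicator_table(coh, model$locations)
write.csv(cbind(id = rownames(mob), mob), "results/mobility_indicators.csv",
          row.names = FALSE, na = "")

eff <- effect_size_table(mob, labels, n_subsamples = 1000, seed = 2027)
write.csv(eff, "results/mobility_effects.csv", row.names = FALSE)

cat("mobility effect sizes (negative = women higher):\n")
for (i in seq_len(nrow(eff)))
  cat(sprintf("  %-22s %+.3f [%+.3f, %+.3f]%s\n", eff$indicator[i],
              eff$mean_r[i], eff$p5[i], eff$p95[i],
              ifelse(isTRUE(eff$significant[i]), " *", "")))
by_g <- split(mob$location_entropy, labels[rownames(mob)])
cat(sprintf("mean location entropy: women %.3f nats, men %.3f nats\n",
            mean(by_g$F, na.rm = TRUE), mean(by_g$M, na.rm = TRUE)))
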