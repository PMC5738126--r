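#!/usr/bin/env Rscript

# Assemble the participant x indicator feature table, drop participants
# with more than two of the five feature categories entirely missing, and
# fill the remaining holes with overlap-distance 7-nearest-neighbour
# imputation.

suppressPackageStartupMessages(library(gendernet))

model <- read_cohort("results/cohort")
coh <- filter_active(model$cohort)

mob <- mobility_indicator_table(coh, model$locations)
net <- network_indicator_table(coh, model$networks)
asm <- assemble_features(coh, model$traits, mob, net)

cat(sprintf("feature table: %d participants x %d indicators (%.1f%% cells missing)\n",
            nrow(asm$features), ncol(asm$features),
            100 * mean(is.na(asm$features))))
filt <- category_filter(asm$features)
cat(sprintf("category filter removed %d participants\n",
            nrow(asm$features) - nrow(filt)))
imp <- knn_impute(filt, k = 7)
log <- attr(imp, "imputation_log")
cat(sprintf("imputed %d cells for %d participants\n", nrow(log),
            length(unique(log$id))))

write.csv(cbind(id = rownames(imp), imp), "results/features_complete.csv",
          row.names = FALSE)
write.csv(log, "results/imputation_log.csv", row.names = FALSE)
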