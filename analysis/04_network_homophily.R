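#!/usr/bin/env Rscript

# Network stage: per-participant structural indicators (degree, same-gender
# fraction, betweenness, interaction entropy, text volume), effect sizes
# for the behavioural ones, call-duration statistics by ordered gender
# pair, and gender-label permutation tests for dyad/triad homophily with
# the topology held fixed.

suppressPackageStartupMessages(library(gendernet))

model <- read_cohort("results/cohort")
coh <- filter_active(model$cohort)
labels <- gender_labels(coh)

net <- network_indicator_table(coh, model$networks)
write.csv(cbind(id = rownames(net), net), "results/network_indicators.csv",
          row.names = FALSE, na = "")

behav <- net[, c("call_entropy", "facebook_interaction_entropy",
                 "proximity_entropy", "text_n_texts")]
eff <- effect_size_table(behav, labels, n_subsamples = 1000, seed = 2028)
write.csv(eff, "results/network_effects.csv", row.names = FALSE)
cat("interaction-behaviour effect sizes (negative = women higher):\n")
for (i in seq_len(nrow(eff)))
  cat(sprintf("  %-30s %+.3f%s\n", eff$indicator[i], eff$mean_r[i],
              ifelse(isTRUE(eff$significant[i]), " *", "")))

dur <- call_duration_stats(model$networks$call$events,
                           gender_labels(model$cohort))
cat(sprintf(paste0("mean call duration (s): M->F %.1f, F-F %.1f, ",
                   "F->M %.1f, M-M %.1f\n"),
            dur[["MF"]], dur[["FF"]], dur[["FM"]], dur[["MM"]]))

# permutation homophily tests; 2E permutations for the sparse channels,
# a 500-draw sample on the triangle-rich weekly proximity graph
homo <- list()
for (job in list(list(ch = "proximity", weeks = 0, n_perm = 500),
                  list(ch = "facebook_friend", weeks = 0:3, n_perm = NULL),
                  list(ch = "call", weeks = 0:3, n_perm = NULL))) {
  g <- aggregate_graph(model$networks[[job$ch]], coh, weeks = job$weeks)
  ht <- homophily_test(g, n_perm = job$n_perm, seed = 2029)
  cat(sprintf("%s (%d edges, %d permutations):\n", job$ch, ht$n_edges,
              ht$n_perm))
  for (ind in c("sgf_F", "sgf_M", "dyad_FF", "triad_FFF", "triad_MMM"))
    cat(sprintf("  %-10s z = %+7.2f  p(greater) = %.4f\n", ind,
                ht$z[[ind]], ht$p_greater[[ind]]))
  homo[[job$ch]] <- list(channel = job$ch, n_edges = ht$n_edges,
                          n_perm = ht$n_perm, observed = as.list(ht$observed),
                          z = as.list(ht$z),
                          p_greater = as.list(ht$p_greater))
}
jsonlite::write_json(homo, "results/homophily.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
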