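#!/usr/bin/env Rscript
# Orthographic neighborhoods of the 24 novel-noun stimuli in the toy
# lexicon: which stimuli have close real-word neighbors, and how strongly
# gender conditions plural class within each neighborhood. Also a small
# item-level KL-divergence comparison between production distributions of
# two synthetic cohorts, the comparison used to score predictive models
# against speaker data.

library(pluralinfo)

lex <- load_lexicon(system.file("extdata", "toy_lexicon_synthetic.csv",
                                package = "pluralinfo"))
dir.create("results", showWarnings = FALSE)

hoods <- neighborhood_table(wug_stimuli(), lex)
write.csv(hoods, "results/neighborhoods.csv", row.names = FALSE)
cat("Stimuli with no neighbors in the toy lexicon:",
    sum(hoods$n_neighbors == 0), "of", nrow(hoods), "\n")
with_nb <- hoods[hoods$n_neighbors > 0, ]
print(with_nb, row.names = FALSE, digits = 3)
cat("\nMean neighborhood MI/H over stimuli with neighbors:",
    round(mean(with_nb$ratio), 3),
    "(toy lexicon; the corresponding full-lexicon statistic needs a",
    "complete lexical database)\n")

# item-level KL divergence between a gender-conditioning cohort (reference)
# and a gender-ignoring cohort, pooled over participants
ref <- generate_cohort(120, strategy_mixture(lexicon = 1), "exp1", seed = 7)
obs <- generate_cohort(120, strategy_mixture(ignore = 1), "exp1", seed = 8)
kl <- sapply(wug_stimuli(), function(it) {
  p <- table(factor(ref$plural_class[ref$item == it],
                    levels = plural_classes()))
  q <- table(factor(obs$plural_class[obs$item == it],
                    levels = plural_classes()))
  kl_divergence(as.vector(p), as.vector(q), smoothing = 1e-6)
})
write.csv(data.frame(item = names(kl), kl_bits = as.vector(kl)),
          "results/item_kl.csv", row.names = FALSE)
cat("\nItem-level KL divergence, conditioning vs ignoring cohorts:",
    sprintf("median %.3f bits (range %.3f-%.3f)\n", median(kl), min(kl),
            max(kl)))
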