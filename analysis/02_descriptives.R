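#!/usr/bin/env Rscript
## Step 2 — conflict descriptives and housing-condition contrasts.
##
## Reads the benchmark coding sheet written by step 1 and reports: how many
## aggressions form causally connected sequences (4-min rule), the context
## and intensity composition, per-individual aggression rates with the
## exact paired indoor-vs-outdoor test, the intensity and mesh contrasts,
## and the directed aggression network. Tables land in results/.

suppressMessages(library(pcmc))

setup <- read_study_setup("results/data/benchmark_setup.yml")
log <- read_coding_sheet("results/data/benchmark.csv", setup)

seg <- segment_conflicts(log)
s <- attr(seg, "summary")
cat(sprintf("%d aggressions: %d distinct, %d in %d sequences (sizes %s)\n",
            nrow(log$aggressions), s$n_distinct, s$n_in_sequences,
            length(s$sequence_sizes),
            paste(sort(s$sequence_sizes), collapse = "/")))

ctx <- summarize_contexts(log)
readr::write_csv(ctx, "results/contexts.csv")
by_ctx <- tapply(ctx$n, ctx$context, sum)
cat("contexts:", paste(names(by_ctx), by_ctx, collapse = ", "), "\n")

rates <- aggression_rates(log)
readr::write_csv(rates$rates, "results/rates.csv")
cat(sprintf("rate medians: indoor %.3f/h vs outdoor %.3f/h\n",
            rates$medians[["indoor"]], rates$medians[["outdoor"]]))
print(rates$test)

ct <- condition_intensity_test(log)
cat(sprintf("high-intensity indoors vs outdoors: OR = %.2f, p = %.3f ",
            ct$pooled$or_cmle, ct$pooled$p))
cat(sprintf("(influence control p = %.3f)\n", ct$influence$p))
m <- mesh_effect_test(log)
cat(sprintf("mesh (separated dyads) effect: p = %.3f\n", m$p))

net <- aggression_network(log)
readr::write_csv(net$edges, "results/network.csv")
top <- net$totals[which.max(net$totals$n), ]
cat(sprintf("most frequent aggressor: %s (%d conflicts, %.0f%%)\n",
            top$aggressor, top$n, 100 * top$share))
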