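#!/usr/bin/env Rscript
## Step 1 — build the study data.
##
## Writes two datasets under results/data/:
##   benchmark.csv / benchmark_setup.yml  — the deterministic benchmark log
##     whose analysis results are known by construction (the package's
##     study-scale regression standard);
##   simulated.csv / simulated_setup.yml  — one seeded draw from the
##     stochastic generator under its default (study-like) conditions.
## Later steps read the benchmark sheet back from disk, so the whole
## workflow also exercises the coding-sheet reader.

suppressMessages(library(pcmc))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

bench <- study_fixture_log()
stopifnot(nrow(validate_log(bench)) == 0)
write_coding_sheet(bench, file.path(out, "benchmark.csv"))
write_study_setup(bench$setup, file.path(out, "benchmark_setup.yml"))
cat(sprintf("benchmark: %d aggressions, %d affiliations, %d interventions\n",
            nrow(bench$aggressions), nrow(bench$affiliations),
            nrow(bench$interventions)))

sim <- simulate_log(simulation_config(seed = 20120301))
stopifnot(nrow(validate_log(sim)) == 0)
write_coding_sheet(sim, file.path(out, "simulated.csv"))
write_study_setup(sim$setup, file.path(out, "simulated_setup.yml"))
cat(sprintf("simulated:  %d aggressions, %d affiliations (seed 20120301)\n",
            nrow(sim$aggressions), nrow(sim$affiliations)))
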