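#!/usr/bin/env Rscript
## Step 5 — third-party interventions and the affiliative contact
## typology.
##
## Tabulates interventions outside the male sexual-coercion context, tests
## the housing-condition effect on intervention probability (with an
## influence control over interveners), summarises the coercion context
## separately, and builds the behaviour-type composition of post-conflict
## vs control victim-bystander contacts with the contact-sitting
## association test. Writes results/interventions.csv and
## results/typology.csv.

suppressMessages(library(pcmc))

setup <- read_study_setup("results/data/benchmark_setup.yml")
log <- read_coding_sheet("results/data/benchmark.csv", setup)

tab <- tabulate_interventions(log)
print(tab)
readr::write_csv(tab$by_intervener, "results/interventions.csv")
ict <- intervention_condition_test(log)
cat(sprintf("intervention probability indoors vs outdoors: OR = %.2f, p = %.3f\n",
            ict$pooled$or_cmle, ict$pooled$p))
cat(sprintf("  influence control (interveners): p = %.3f\n", ict$influence$p))

print(coercion_summary(log))

pairs <- build_pcmc_pairs(log)
ct <- collect_window_contacts(log, pairs, "third_party")
typ <- behaviour_type_table(ct$pc, ct$mc)
readr::write_csv(tibble::as_tibble(typ), "results/typology.csv")
cat(sprintf("contacts: %d in PC windows, %d in MC windows\n",
            attr(typ, "pc_total"), attr(typ, "mc_total")))
print(utils::head(as.data.frame(typ), 4))
cs <- type_association_test(ct$pc, ct$mc, "contact_sitting")
cat(sprintf("contact sitting PC vs MC: OR = %.2f, p = %.4g\n",
            cs$pooled$or_cmle, cs$pooled$p))
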