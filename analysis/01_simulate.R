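#!/usr/bin/env Rscript
# Stage 1: build the toy gazetteer world and simulate the occurrence data
# set with planted, labelled contamination.
#
# Study conditions: 5 groups (4 terrestrial, 1 marine) x 20 species,
# log-normal records per species (median 10, heavy tail), 5% contamination
# per issue type, seed 42.

suppressMessages(library(occfiltr))

seed <- 42L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- simulation_spec(
  seed = seed, n_groups = 5, realms = c(rep("terrestrial", 4), "marine"),
  n_species = 20,
  contamination = stats::setNames(rep(0.05, 14),
                                  names(simulation_spec()$contamination)))

gaz <- make_toy_gazetteer()
sim <- simulate_occurrences(spec, gaz, seed = seed)

write_gazetteer(gaz, file.path(out, "gazetteer"))
write_occurrences(sim$records, file.path(out, "occurrences_raw.csv"))
write.table(sim$truth, file.path(out, "truth_synthetic.tsv"), sep = "\t",
            quote = FALSE, na = "", row.names = FALSE)
write.table(sim$ranges, file.path(out, "ranges_synthetic.tsv"), sep = "\t",
            quote = FALSE, na = "", row.names = FALSE)
ref <- make_reference_assessments(sim$records, sim$truth)
write.table(ref, file.path(out, "reference_synthetic.tsv"), sep = "\t",
            quote = FALSE, na = "", row.names = FALSE)

n_planted <- sum(!is.na(sim$truth$issue))
cat(sprintf("Simulated %d records for %d species in %d groups (seed %d).\n",
            nrow(sim$records), length(unique(sim$records$species)),
            spec$n_groups, seed))
cat(sprintf("Planted %d contaminated records (%.1f%%) across %d issue types.\n",
            n_planted, 100 * n_planted / nrow(sim$records),
            length(unique(na.omit(sim$truth$issue)))))
cat("Artifacts written under", out, "\n")
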