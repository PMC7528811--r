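#!/usr/bin/env Rscript
# Stage 2: run the 13 quality tests on the raw records, classify flagged
# records as erroneous or unfit, write the clean data set, and score the
# flags against the planted ground truth.

suppressMessages(library(occfiltr))

dat <- "results/data"
out <- "results"
records <- read_occurrences(file.path(dat, "occurrences_raw.csv"))
gfile <- function(l) file.path(dat, "gazetteer", paste0(l, ".geojson"))
gaz <- load_gazetteer(land = gfile("land"),
                      country_centroids = gfile("country_centroids"),
                      province_centroids = gfile("province_centroids"),
                      capitals = gfile("capitals"), urban = gfile("urban"),
                      institutions = gfile("institutions"))
truth <- read.table(file.path(dat, "truth_synthetic.tsv"), header = TRUE,
                    sep = "\t", na.strings = "", stringsAsFactors = FALSE)

cfg <- filter_config(realms = stats::setNames(
  c(rep("terrestrial", 4), "marine"), sprintf("group%02d", 1:5)))
report <- run_filters(records, cfg, gaz)
clean <- filtered_dataset(records, report)

flags_out <- as.data.frame(report)
for (nm in setdiff(names(flags_out), "record_id"))
  flags_out[[nm]] <- as.integer(flags_out[[nm]])
write.table(flags_out, file.path(out, "flags.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_occurrences(clean, file.path(out, "occurrences_clean.csv"))

fs <- summarize_flags(report, records)
fs_out <- fs
for (nm in names(fs_out)) if (is.double(fs_out[[nm]]))
  fs_out[[nm]] <- round(fs_out[[nm]], 4)
write.table(fs_out, file.path(out, "flag_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

sc <- score_against_truth(report, truth)
write.table(sc, file.path(out, "flag_scores.tsv"), sep = "\t",
            quote = FALSE, na = "", row.names = FALSE)

tot <- fs[fs$group == "Total", ]
cat(sprintf("Flagged %.1f%% of %d records (%.1f%% erroneous, %.1f%% unfit);\n",
            tot$pct_flagged, tot$n_records, tot$pct_erroneous, tot$pct_unfit))
cat(sprintf("%d clean records remain.\n", nrow(clean)))
planted <- sc[sc$n_planted > 0, ]
cat(sprintf("Recovery of planted contamination: sensitivity %.3f-%.3f, specificity %.3f-%.3f over %d tests.\n",
            min(planted$sensitivity), max(planted$sensitivity),
            min(planted$specificity), max(planted$specificity),
            nrow(planted)))
cat("Per-group flag percentages written to results/flag_summary.tsv\n")
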