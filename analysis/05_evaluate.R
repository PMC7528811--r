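#!/usr/bin/env Rscript
# Stage 5: agreement of the automated assessments (raw and filtered) with
# the synthetic reference categories, and the median per-group change of
# EOO and AOO caused by filtering.

suppressMessages(library(occfiltr))

records <- read_occurrences("results/data/occurrences_raw.csv")
a_raw <- read.table("results/assessments_raw.tsv", header = TRUE, sep = "\t",
                    na.strings = "", stringsAsFactors = FALSE)
a_filt <- read.table("results/assessments_filtered.tsv", header = TRUE,
                     sep = "\t", na.strings = "", stringsAsFactors = FALSE)
ref <- read.table("results/data/reference_synthetic.tsv", header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)

cmp_filt <- compare_with_reference(a_filt, ref)
cmp_raw <- compare_with_reference(a_raw, ref)

groups <- stats::setNames(records$group_id, records$species)
groups <- groups[!duplicated(names(groups))]
chg <- range_change(a_raw, a_filt, groups)
chg_out <- chg
for (nm in names(chg_out)) if (is.double(chg_out[[nm]]))
  chg_out[[nm]] <- round(chg_out[[nm]], 4)
write.table(chg_out, "results/range_change.tsv", sep = "\t", quote = FALSE,
            na = "", row.names = FALSE)

eval_tbl <- data.frame(
  metric = c("match_pct_filtered", "match_pct_raw", "n_compared_filtered",
             "n_compared_raw", "median_eoo_change_pct",
             "median_aoo_change_pct"),
  value = round(c(cmp_filt$match_pct, cmp_raw$match_pct, cmp_filt$n_compared,
                  cmp_raw$n_compared,
                  median(chg$median_eoo_change_pct, na.rm = TRUE),
                  median(chg$median_aoo_change_pct, na.rm = TRUE)), 4))
write.table(eval_tbl, "results/evaluation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Agreement with reference (threatened vs not): filtered %.1f%%, raw %.1f%% (n = %d species).\n",
            cmp_filt$match_pct, cmp_raw$match_pct, cmp_filt$n_compared))
cat("Median range change per group after filtering:\n")
print(chg_out, row.names = FALSE)
cat(sprintf("Across groups: median EOO change %.1f%%, median AOO change %.1f%%.\n",
            median(chg$median_eoo_change_pct, na.rm = TRUE),
            median(chg$median_aoo_change_pct, na.rm = TRUE)))
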