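#!/usr/bin/env Rscript
# Stage 4: preliminary Criterion B conservation assessment (EOO, AOO,
# locations, category) for every species, on the raw and the filtered data.

suppressMessages(library(occfiltr))

records <- read_occurrences("results/data/occurrences_raw.csv")
clean <- read_occurrences("results/occurrences_clean.csv")
th <- criterion_b_thresholds()

a_raw <- assess_all(records, th)
a_filt <- assess_all(clean, th)

wr <- function(df, f) {
  for (nm in names(df)) if (is.double(df[[nm]])) df[[nm]] <- round(df[[nm]], 4)
  write.table(df, file.path("results", f), sep = "\t", quote = FALSE,
              na = "", row.names = FALSE)
}
wr(a_raw, "assessments_raw.tsv")
wr(a_filt, "assessments_filtered.tsv")

for (lab in c("raw", "filtered")) {
  a <- if (lab == "raw") a_raw else a_filt
  tab <- table(factor(a$category, levels = c("CR", "EN", "VU", "NT_proxy")))
  thr <- sum(tab[c("CR", "EN", "VU")])
  cat(sprintf("%s data: %d species assessed, %d possibly threatened (%.1f%%): CR=%d EN=%d VU=%d.\n",
              lab, nrow(a), thr, 100 * thr / nrow(a),
              tab[["CR"]], tab[["EN"]], tab[["VU"]]))
}
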