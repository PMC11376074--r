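#!/usr/bin/env Rscript
# Stage 2: score every chromatogram on the 0-4 biodegradation scale.
#
# Reads the per-sample traces written by stage 1, applies peak detection,
# alkane/isoprenoid assignment, the UCM index and the rule set, and writes
# a per-sample score table. Finishes by reporting agreement with the
# generator's planted degrees.

suppressPackageStartupMessages(library(alkylotroph))

man <- jsonlite::read_json("results/study/manifest.json")

rows <- lapply(man$samples, function(s) {
  ch <- read_chromatogram(file.path("results/study", s$chromatogram),
                          sample_id = s$sample_id)
  sc <- score_chromatogram(ch)
  data.frame(sample_id = s$sample_id, oilfield = s$oilfield,
             degree = ifelse(sc$indeterminate, NA_integer_, sc$degree),
             ucm_index = round(sc$ucm_index, 4),
             c17_pr = round(sc$diagnostics$c17_pr_ratio, 3),
             c18_ph = round(sc$diagnostics$c18_ph_ratio, 3),
             true_degree = s$truth$degradation_degree)
})
scores <- do.call(rbind, rows)
write.table(scores, "results/scores.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

agree <- mean(scores$degree == scores$true_degree, na.rm = TRUE)
cat(sprintf("scored %d samples; agreement with planted degree: %.1f%%\n",
            nrow(scores), 100 * agree))
cat(sprintf("degraded (degree >= 1): %.1f%%\n",
            100 * mean(scores$degree >= 1, na.rm = TRUE)))
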