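#!/usr/bin/env Rscript

# Round-level composition analytics on the valid 15-mers: normalized
# residue frequencies per round, chemical-class aggregation, positional
# count matrices, and per-residue deltas against the unsorted library.

suppressPackageStartupMessages(library(biopanr))
dir.create("results/composition", recursive = TRUE, showWarnings = FALSE)

labels <- c("unsorted", "round1", "round4")
profiles <- lapply(labels, function(label) {
  rec <- read.delim(sprintf("results/extract/%s_records.tsv", label),
                    na.strings = "NA")
  composition(select_15mers(rec), label)
})

# frequency + delta table (percent / percentage points)
cmp <- compare_rounds(profiles)
write.table(cmp, "results/composition/residue_frequencies.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
key <- c("G", "P", "S", "C", "M", "H")
message("per-residue frequencies (%) and deltas vs unsorted (points):")
print(cmp[cmp$residue %in% key, ], digits = 3)

# chemical-class aggregation per round
scheme <- aa_class_scheme()
agg <- t(vapply(profiles, class_aggregate, numeric(5), scheme = scheme))
rownames(agg) <- labels
write.table(data.frame(round = rownames(agg), 100 * agg,
                       check.names = FALSE),
            "results/composition/class_aggregate.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("chemical-class percentages by round:")
print(round(100 * agg, 2))

# positional residue counts (20 x 15) per round
for (i in seq_along(labels)) {
  write.table(profiles[[i]]$positional_counts,
              sprintf("results/composition/%s_positional_counts.tsv",
                      labels[i]),
              sep = "\t", quote = FALSE, col.names = NA)
}
message("wrote results/composition/")
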