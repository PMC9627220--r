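#!/usr/bin/env Rscript
# Step 5 -- cross-endpoint overlaps: which candidate constituents recur
# across assays, for the synthetic run and for the published QYSLD
# consensus sets (pure set algebra on the printed lists).

suppressPackageStartupMessages(library(specfx))

js <- jsonlite::fromJSON("results/screen_report.json")
cons <- lapply(js$endpoints, function(e) unlist(e$consensus))
cons <- cons[lengths(cons) > 0 | TRUE]
ov <- shared_across_effects(cons)
cat("Synthetic run: pairwise consensus overlaps\n")
print(ov$pairwise[ov$pairwise$n > 0, ], row.names = FALSE)
cat("Peaks shared by all endpoints:",
    if (length(ov$all)) paste(ov$all, collapse = ", ") else "none", "\n\n")
write.table(ov$pairwise, "results/overlaps_synthetic.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

sets <- qysld_consensus_sets()
cat("Published QYSLD consensus sets (sizes):",
    paste(sprintf("%s=%d", names(sets), lengths(sets)), collapse = ", "),
    "\n")
ovq <- shared_across_effects(sets)
cat("DPPH & viability:",
    paste(ovq$pairwise_sets[["dpph:viability"]], collapse = ", "), "\n")
cat("FRAP & wound & invasion:",
    paste(intersect_per_effect(sets$frap, sets$wound, sets$invasion),
          collapse = ", "), "\n")
cat("Shared by all six assays:",
    if (length(ovq$all)) paste(ovq$all, collapse = ", ") else "none", "\n")
write.table(ovq$pairwise, "results/overlaps_published.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
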