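#!/usr/bin/env Rscript
# Step 1 -- simulate the study: ten decoction batches profiled over seventy
# common LC-MS peaks, six bioassay endpoints driven by planted active peaks.
# Writes the peak matrix, raw effect table, and the planted truth.

suppressPackageStartupMessages(library(specfx))

seed <- 2026
dir.create("results", showWarnings = FALSE)

spec <- synthetic_spec(seed = seed)
d <- gen_spectrum_effect(spec)

cat("Simulated", nrow(d$matrix$areas), "batches x", ncol(d$matrix$areas),
    "peaks; internal standard", d$matrix$is_peak, "\n")
cat("Planted active sets:\n")
for (e in names(d$truth$active_sets))
  cat(sprintf("  %-10s %s\n", e, paste(d$truth$active_sets[[e]],
                                       collapse = ", ")))

# peak matrix as delimited text
write.table(data.frame(batch = rownames(d$matrix$areas), d$matrix$areas,
                       check.names = FALSE),
            "results/peak_matrix.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
# per-batch peak tables in the exchange format, as an instrument would emit
tabs <- as_peak_tables(d$matrix, rt_jitter = 0.02, seed = seed)
dir.create("results/peak_tables", showWarnings = FALSE)
for (t in tabs)
  write_peak_table(t, file.path("results/peak_tables",
                                paste0(t$sample[1], ".tsv")))
write.table(d$effects_raw, "results/effects_raw.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
jsonlite::write_json(d$truth$active_sets, "results/truth.json",
                     auto_unbox = FALSE)
# legacy similarity-software export
write_legacy_fingerprint(d$matrix, path = "results/fingerprint_legacy.txt")
cat("Wrote results/peak_matrix.tsv, results/peak_tables/, ",
    "results/effects_raw.tsv, results/truth.json\n")
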