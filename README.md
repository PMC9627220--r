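# specfx — spectrum-effect relationship screening for herbal fingerprints

Herbal preparations are mixtures; bioassays measure the whole mixture.
**specfx** screens for the constituents that drive activity by correlating a
chromatographic fingerprint — integrated areas of the common LC-MS peaks
across preparation batches ("spectrum") — with bioassay outcomes on the same
batches ("effects"). It is aimed at analysts running fingerprint-based
quality and activity studies of multi-component preparations (ten-ish
batches, tens of common peaks, several assay endpoints).

The pipeline:

1. **Fingerprint construction & QC** — retention-time matching of per-batch
   peak tables into a common-peak matrix; relative retention time / relative
   peak area against an internal standard with %RSD/CV; a serial-dilution
   linearity screen (peaks with calibration R² < 0.99 are dropped);
   uncentered-cosine similarity of each batch to the mean reference
   fingerprint; a legacy two-block TXT export.
2. **Effect endpoints** — DPPH scavenging rate and 4PL IC50, FRAP linear
   calibration, wound-healing rate, transwell counts; all endpoints are
   orientation-normalised to "larger = more active" activities.
3. **Three screening statistics per endpoint** —
   * Deng's grey relational degree
     `ξᵢ(k) = (Dmin + ρ·Dmax) / (Dᵢ(k) + ρ·Dmax)`, `rᵢ = mean ξᵢ(k)`
     with ρ = 0.5, selecting `r > 0.8`;
   * NIPALS PLS1 with Wold's VIP
     (`VIPⱼ = √(p·Σₐ SSYₐ(wⱼₐ/‖wₐ‖)² / Σₐ SSYₐ)`), leave-one-out Q² for
     the component count, selecting `VIP > 1` with positive coefficient;
   * a p-3-1 backpropagation network ensemble with mean impact values
     (±10% input perturbation), selecting `MIV > 0`.
4. **Consensus** — the exact three-way intersection per endpoint, plus
   cross-endpoint overlap set algebra and a deterministic JSON report.
5. **A seeded synthetic generator** with planted active peaks
   (log-normal areas, a shared extraction factor among co-extracted
   actives) grades end-to-end recovery against known truth.

## Worked example

```r
library(specfx)

d   <- gen_spectrum_effect(synthetic_spec(seed = 2026))  # 10 batches x 70 peaks
fail <- paste0("P", c(3, 11, 27, 31, 33, 40, 41, 45, 53, 57, 69))
lin <- linearity_screen(gen_calibration(d$matrix, failing_peaks = fail))
m   <- restrict_peaks(d$matrix, lin)                     # 59 retained peaks
scr <- run_screen(m, d$effects, seed = 2026)
print(scr)
recovery_metrics(scr$endpoints$frap$consensus, d$truth, "frap")
```

prints (abridged):

```
Spectrum-effect screen over 59 peaks
  ...
  wound      GRA  7 | PLSR  7 | MIV 21 -> consensus  7: P2, P8, P42, P47, P51, P56, P68
  migration  GRA  5 | PLSR  8 | MIV 19 -> consensus  5: P7, P9, P39, P66, P70
  ...
  endpoint n_selected n_planted n_hit recall precision
1     frap          8         8     8      1         1
```

Each endpoint line shows how many peaks each statistic nominated and their
intersection — the consensus candidates for that assay. `recovery_metrics()`
grades a selection against the generator's planted truth: here all eight
planted FRAP-active peaks were recovered with no false positives. Across the
six endpoints of this run the consensus reached mean recall 0.83 and mean
precision 0.93 (planted peaks dropped by the linearity screen are
unrecoverable by design and count as misses).

The `analysis/` directory holds the same workflow as numbered narrative
scripts (`01_simulate.R` … `05_consensus_overlaps.R`), each writing its
tables under `results/`.

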