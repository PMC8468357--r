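# radrepro

Reproducibility analysis of radiomic features under manual versus
semi-automatic tumour segmentation.

## What it does

When a tumour is delineated on an MR volume by different observers — or by
the same observer on different days — every radiomic feature computed from
the segmented region inherits some of that delineation noise. `radrepro`
implements the complete computational chain for quantifying this effect on
hepatocellular-carcinoma-like phantoms:

* **Synthetic study generation** — MR-like 3D volumes with ellipsoidal
  tumours in two stage groups (diameters 3.7 ± 0.7 cm and 8.9 ± 3.4 cm),
  smooth observer-specific boundary noise for the manual arm, and seeded
  flood-fill segmentation for the semi-automatic arm; the default design
  yields 30 subjects × (4 manual + 2 observers × 2 sessions) = 240 masks.
* **Flood-fill segmentation** — seeded region growing with an intensity
  tolerance around the seed-mean reference, faces/edges/corners
  connectivity, and a neighbourhood-mean leak check that stops growth
  through thin intensity bridges; plus a deterministic cleanup step
  (largest component, hole filling).
* **662 radiomic features** per (volume, mask) pair: 14 shape, and on the
  original image plus eight undecimated Coiflet-1 wavelet channels
  (`LLL` … `HHH`), 18 first-order and 54 texture features from gray-level
  co-occurrence (24), run-length (16) and dependence (14) matrices, with
  13-direction 3D aggregation.
* **ICC analysis** — per-feature intraclass correlation from two-way ANOVA
  mean squares:

  `ICC(A,1) = (MS_R − MS_E) / (MS_R + (k−1) MS_E + (k/n)(MS_C − MS_E))`

  for inter-observer agreement and
  `ICC(C,1) = (MS_R − MS_E) / (MS_R + (k−1) MS_E)` for intra-observer
  consistency, reproducibility banding (high ≥ 0.8 > medium ≥ 0.5 > low),
  and a Wilcoxon rank-sum comparison of the two methods' ICC vectors.

Everything is seeded: a configuration object plus one integer reproduces
every volume, mask, feature value and report byte-for-byte.

## Worked example

```r
library(radrepro)

des <- study_design(n_subjects = 6L, dims = c(32L, 32L, 32L),
                    size_mean_low = 2.0, size_sd_low = 0.3,
                    size_mean_high = 3.2, size_sd_high = 0.3,
                    rng_seed = 42L)
study    <- generate_study(des)
features <- extract_study_features(study, feature_config())
report   <- summarize_reproducibility(features)
print(report)
```

```
Reproducibility report (662 features)

  manual    mean ICC = 0.577 +/- 0.294 (662 features, 0 undefined)
  semiauto  mean ICC = 0.959 +/- 0.087 (662 features, 0 undefined)

  Reproducibility groups:
    manual    high 193 (29.2%), medium 238 (36.0%), low 231 (34.9%)
    semiauto  high 626 (94.6%), medium 30 (4.5%), low 6 (0.9%)

  Wilcoxon rank-sum (semiauto vs manual): W = 419702.0, p = 7.94e-183 (semiauto > manual)
```

Each of the 48 masks contributed a 662-entry feature vector; for every
feature and method the subjects × raters matrix went through the two-way
ANOVA and the agreement ICC. With 2 mm manual boundary noise against 1 mm
semi-automatic seed jitter, the flood-fill arm's features are markedly
more reproducible (mean ICC 0.96 vs 0.58 here), and almost all of its
features land in the high-reproducibility band — the qualitative pattern
such segmentation studies report on clinical data.

A study can also be persisted and driven from the shell through the thin
CLI at `inst/cli/radrepro.R` (`generate`, `segment`, `extract`, `analyze`,
`run-all`), reading and writing NIfTI volumes/masks, a CSV feature table
and a JSON + Markdown report.

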