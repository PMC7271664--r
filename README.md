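# callotex

Texture-based localization of disease effects in the mid-sagittal
corpus callosum (CC).

Group studies often report *that* a patient group's CC texture differs
from controls. callotex implements a framework that also answers
*where* the alteration concentrates along the anterior–posterior axis
and *how localized* it is, using only a grayscale mid-sagittal image
and a CC mask per subject:

1. **Uniform Local Binary Patterns (LBP)** — each pixel's 8 circular
   neighbors at radius 1 are thresholded at the center gray value; the
   58 patterns with at most two circular bit transitions keep distinct
   labels, the rest pool into one. Small square ROIs (5×5 controls,
   4×4 patients), tiled exhaustively inside the mask, are summarized
   by the **energy** and **entropy** of their LBP label histograms.
2. **Vertical parcellation** — the CC's horizontal extent is cut into
   five sub-regions by the Witelson (1/3, 1/6, 1/6, 2/15, 1/5) or
   Hofer–Frahm (1/6, 1/3, 1/6, 1/12, 1/4) width fractions; each ROI
   belongs to the sub-region holding its center pixel.
3. **Per-ROI LOSO SVM and CCR** — a polynomial-kernel SVM separates
   each disease class from controls under leave-one-subject-out
   cross-validation; the **Correct Classification Ratio (CCR)** is the
   fraction of a subject's ROIs classified correctly, per sub-region.
4. **Array of Importance (AI)** — ranking each subject's five CCRs
   descending, the top sub-region per subject (with its CCR) marks
   where that subject's texture is most distinguishable.
5. **Scatter Index (SI)** — the core statistic. From the AI's
   sub-region occurrence frequencies `f`: `FSD = sd(f)`,
   `FCV = FSD / mean(f)`, `SI = exp(-FCV)`,
   `%SI = (SI − 0.135) × 100`. `SI → 1` means the alteration is
   scattered over the whole CC; `SI` near its one-hot minimum
   (`exp(−2) ≈ 0.135` for five regions, population denominator) means
   a single dominant site.
6. **Differential diagnosis** — disease pairs are discriminated from
   per-subject top CCRs (sensitivity/specificity/precision/recall/
   F-score/accuracy/AUC, plus a t-test).

A seeded phantom generator (`cohort_spec()` / `generate_cohort()`)
produces CC-shaped masks with smoothed-noise textures and a known
altered sub-region per disease subject, so the whole chain is testable
end to end without MRI data.

## Worked example

Simulate a control group and a "PSP-like" group whose texture
alteration sits in sub-regions 3–4 (with Hofer–Frahm probabilities
0.05/0.45/0.5 over regions 2–4), then recover that localization:

```r
library(callotex)

spec <- cohort_spec(n_per_class = 6, image_size = c(48, 96),
                    classes = c("HC", "PSP"),
                    localization = c(0, 0.05, 0.45, 0.5, 0), seed = 7)
cohort <- generate_cohort(spec)
res <- run_pipeline(cohort$subjects,
                    run_config(feature = "energy", stride = 3))

res$per_class$PSP$ai
#>   subject_id top_region   top_ccr
#> 1     PSP_01          4 1.0000000
#> 2     PSP_02          4 0.6666667
#> 3     PSP_03          3 0.6000000
#> 4     PSP_04          3 0.7600000
#> 5     PSP_05          4 0.9000000
#> 6     PSP_06          4 1.0000000

round(res$per_class$PSP$key$frequencies, 2)
#>   R1   R2   R3   R4   R5
#> 0.00 0.00 0.33 0.67 0.00

res$per_class$PSP$scatter
#> Scatter Index (sample denominator)
#>   FSD 0.2981  FCV 1.4907  SI 0.2252  %SI 9.02
```

Every subject's most discriminable sub-region lands in regions 3–4 —
exactly where the generator planted the alteration — and the low SI
flags the effect as localized. Dispersion statistics can also be
computed directly from published occurrence-fraction tables:

```r
frac <- read_frequencies(system.file("extdata",
          "ai_region_fractions.csv", package = "callotex"))
print(scatter_table(frac, mode = "sample"), digits = 3)
#>   group   scheme   fsd   fcv    si pct_si
#> 1 PD_NC    hofer 0.100 0.500 0.607   47.2
#> 2 PD_NC witelson 0.127 0.637 0.529   39.4
#> 3   MSA    hofer 0.190 0.952 0.386   25.1
#> 4   MSA witelson 0.209 1.046 0.351   21.6
#> 5   PSP    hofer 0.252 1.262 0.283   14.8
#> 6   PSP witelson 0.242 1.212 0.298   16.3
```

The pattern is the framework's headline finding: dispersion shrinks
monotonically from cognitively normal Parkinson's disease (PD-NC,
scattered) through multiple system atrophy (MSA) to progressive
supranuclear palsy (PSP, tightly localized in the posterior body /
isthmus).

A command-line front end with `simulate` / `features` / `scatter` /
`pipeline` subcommands is installed at
`system.file("cli", "callotex.R", package = "callotex")`.

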