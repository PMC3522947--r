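# veinLDC

Local Directional Codes (LDC) for finger-vein biometrics in R.

Finger-vein recognition images the subdermal vessel network by
near-infrared transillumination: hemoglobin absorbs NIR light, so vessels
appear as dark curvilinear shadows on brighter tissue. Instead of
segmenting that network — a fragile step that can ruin recognition when
it goes wrong — the LDC descriptor codes, at every interior pixel, the
local gradient orientation as an integer. For a grayscale image *X* the
axis-aligned variant (LDC-00) takes the neighbor differences

```
v_v = X(i, j+1) − X(i, j−1)        (right − left)
v_h = X(i−1, j) − X(i+1, j)        (top − bottom)
```

maps them to a full-circle angle `θ′ = atan2(v_h, v_v) + π ∈ [0, 2π]`,
and quantizes into `T` dominant orientations by nearest sector:

```
t = ⌊ θ′ / (2π/T) + 1/2 ⌋ mod T,     t ∈ {0, …, T−1}
```

(`T = 8` by default, sector centers at `t·π/4`). The diagonal variant
(LDC-45) uses the 45°-rotated differences. A `W × H` image becomes a
`(W−2) × (H−2)` code map; two maps are compared by the fraction of
positions with equal codes (`Score = Σ Mt / CodeNum ∈ [0, 1]`).

The package provides:

* **Preprocessing** — RGB→gray (`0.299R + 0.587G + 0.114B`), Sobel-based
  region-of-interest detection, bilinear size normalization to 96×64,
  min–max gray normalization (`preprocessImage()` and the individual
  stages).
* **Descriptor** — `extractCodeMap()` in both variants, any `T ≥ 2`,
  with lossless PGM/CSV serialization.
* **Matching** — `matchScore()`, exact per-position agreement.
* **Evaluation** — biometric verification (`runVerification()`: ROC,
  EER, FAR at zero FRR, FRR at zero FAR; genuine = all within-class
  pairs, imposter = first-6 cross-class pairs) and closed-set
  identification (`runIdentification()`: ranks, CMC, rank-one rate),
  plus an EER-vs-`T` sweep (`sweepT()`).
* **Synthetic data** — a fully seeded generator (`generateDatabase()`)
  emulating a multi-session vein collection: per-class spline vessel
  networks with per-sample jitter, brightness, blur and noise, so the
  whole pipeline is testable without any private capture database.
* **CLI** — `system.file("exec", "ldc", package = "veinLDC")` with
  subcommands `extract`, `match`, `verify`, `identify`, `sweep-t`,
  `synth`.

## Worked example

```r
library(veinLDC)

# a small seeded synthetic database: 8 fingers, 6 captures each, 96 x 64
db <- generateDatabase(syntheticConfig(nClasses = 8, nSamples = 6,
                                       masterSeed = 3))
db
#> VeinDatabase: 8 classes, 6 samples/class, images 96 x 64

cm1 <- extractCodeMap(getSample(db, 1, 1), "00", T = 8)
cm1
#> CodeMap LDC-00: 62 x 94 codes, T = 8
#>   code histogram: 435 594 1257 667 434 580 1244 617

# same finger, different capture vs. different finger
matchScore(cm1, extractCodeMap(getSample(db, 1, 2), "00", T = 8))
#> MatchResult: score 0.2270 over 5828 positions
matchScore(cm1, extractCodeMap(getSample(db, 2, 1), "00", T = 8))
#> MatchResult: score 0.1428 over 5828 positions

runVerification(db, "00", T = 8, k = 6)
#> VerificationReport: 120 genuine, 1008 imposter scores
#>   EER 0.0397 | FAR@zeroFRR 0.1280 | FRR@zeroFAR 0.1333

runIdentification(db, "00", nProbes = 4, templateSeed = 1)
#> IdentificationReport: 32 probes, 8 ranks
#>   rank-one rate 0.9688 | lowest perfect rank 2
```

Reading the numbers: a genuine pair agrees at 22.7 % of positions, an
imposter pair at 14.3 % — close to the 1/T = 12.5 % chance floor, since
two unrelated vessel patterns share only their flat background. The
threshold sweep over all 1,128 pair scores crosses at an equal error
rate of 4 % on this toy database, and 31 of 32 identification probes
rank their own finger first.

Code maps larger than `T` codes deserve emphasis: the score of two
independent random maps concentrates near `1/T`, so raising `T`
separates the genuine and imposter distributions until per-sector
statistics become too thin — `sweepT(db, c(2, 4, 8, 16))` shows the
trade-off.

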