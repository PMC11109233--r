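# emodraw

Quantifying how people *color* their emotions. When participants are asked
to draw anger, happiness, sadness and fear on a blank digital canvas, the
color composition of the drawings carries systematic signal: anger is
painted red, happiness yellow, sadness blue, fear black and dark. `emodraw`
is an R package for the full analysis pipeline behind that kind of study:

1. **Pixel classification** — each pixel of an 8-bit RGB drawing is
   converted to HSV on the OpenCV scale (H in 0–180, S and V in 0–255) and
   assigned to one of nine named, inclusive HSV ranges (red twice, at both
   ends of the hue circle, plus yellow, green, blue, purple, gray, black,
   white). White is the blank canvas; overlaps are resolved by a fixed
   precedence (black, white, gray, then the chromatic hues) so dark
   ambiguous pixels are always called black.
2. **Seven per-image metrics** — prominent color; per-color percentages of
   the classified drawn pixels (they always total 100); number of colors
   used (share > 1%); mean saturation and brightness over drawn pixels;
   color fill (drawn area / canvas); image coverage (fill plus interior
   blank holes, via border flood-fill).
3. **Depiction-style annotations** — ingestion of human-coded style labels
   (facial, body language, symbolic, narrative, abstract) with Cohen's and
   Fleiss' kappa for inter-rater agreement, plus per-emotion prevalence
   tables.
4. **Inference** — chi-square and one-way ANOVA comparisons across
   emotions, and a multinomial logistic regression classifying the drawn
   emotion from prominence dummies, saturation, brightness, color count,
   fill, coverage and the style indicators. The fitter is a Newton–Raphson
   maximizer of the multinomial log-likelihood with step-halving
   (log-likelihood never decreases), reporting the likelihood-ratio
   chi-square, Nagelkerke pseudo-R²
   `[1 − exp(2(L0−L1)/n)] / [1 − exp(2 L0/n)]`, a percentile bootstrap
   over case resamples, and the in-sample observed-by-predicted
   classification table.
5. **Synthetic drawing generator** — seeded cohorts of raster drawings
   with pixel-exact ground truth whose population moments are calibrated
   to published per-emotion statistics, so the entire pipeline is testable
   without participant data.

## Worked example

```r
library(emodraw)

# a calibrated synthetic cohort: 20 participants x 4 emotions
profiles <- lapply(default_emotion_profiles(), calibrate_profile)
cohort <- generate_cohort(profiles, n_per_emotion = 20, seed = 1,
                          dir = "cohort")

# extract the seven metrics from the PNGs on disk
ex <- extract_cohort("cohort")
head(ex$features[, c("source_id", "prominent_color", "pct_red",
                     "saturation_pct", "color_fill_pct")])
#>        source_id prominent_color     pct_red saturation_pct color_fill_pct
#> 1     p001_anger             red  97.6034324       84.28870      24.894714
#> 2      p001_fear           black   0.7971580       67.62183      17.610168
#> 3 p001_happiness          yellow  18.3066362       41.03229       2.000427
#> 4   p001_sadness            gray  14.0047962       54.56251      15.907288
#> 5     p002_anger             red 100.0000000       94.15839      18.724060
#> 6      p002_fear           black   0.8747493       11.00495      27.386475

# cross-emotion statistics + the multinomial-logit classifier
bundle <- analyze_features(ex$features, styles = cohort$styles)
bundle$fit_stats$overall_pct_correct      # 92.5 (in-sample, n = 80)
bundle$prominent$percent["anger", "red"]  # 75: share of red-prominent anger
save_report(bundle, "report")             # CSV + JSON bundle
```

Each row is one drawing: `p001_anger` was painted almost entirely in red
(97.6% of its drawn pixels), at high saturation, covering a quarter of the
canvas; the fear drawings lean on black. On this small synthetic cohort the
classifier recovers the emotion of 92.5% of drawings in-sample (chance is
25%); small cohorts of near-ideal synthetic drawings separate more cleanly
than real participant data.

A thin command-line front end with `simulate` / `extract` / `analyze`
subcommands ships at `inst/scripts/emodraw`.

Real drawings are analyzed the same way: point `extract_cohort()` at a
directory of JPEG/PNG files named `<participant>_<emotion>.<ext>` and join
your rater annotation CSV (header
`source_id,facial,body,symbolic,narrative,abstract`).

## Vignette

`vignettes/emodraw-methods.Rmd` documents the measurement model, the
palette precedence rules, the generator's calibration procedure and its
known limitations.
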