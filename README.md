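# freshir

Chemometric analysis of single-fibre FTIR microspectra for assessing fish
freshness.

## What it is for

Fish processors receive fillets at unknown postmortem age, and
conventional assays (pH, protein solubility, proteolysis) change too
little over two weeks on ice to date them. Mid-infrared absorbance
spectra of single muscle fibres do change: nucleic-acid bands (PO₂⁻
stretch at 1176 and 1247 cm⁻¹) decay after death, while amide III and
antiparallel β-sheet bands (1186, 1205, 1490, 1670 cm⁻¹) gain relative
weight. `freshir` implements the full chemometric chain that exploits
this:

1. **Pre-processing** — iterative polynomial ("ModPoly") baseline
   correction (order 5, ≤ 200 iterations), cropping to the 900–1780 cm⁻¹
   fingerprint, vector normalisation.
2. **PC-DA biomarker discovery** — linear discriminant analysis on
   principal-component scores, Mahalanobis group-membership
   probabilities, and the discriminant **contribution vector**
   `f = Σ_k w_k ℓ_k` (canonical weight × PC loading, summed over PCs):
   the canonical axis back-projected to wavenumber space, whose signed
   extrema mark freshness (positive) and aging (negative) biomarkers. It
   satisfies, for every spectrum `x`, the identity
   `canonical_score(x) = f · (x − mean)` (up to the grand-mean offset),
   which the tests enforce to 1e-8.
3. **Day prediction** — RBF-kernel SVM under stratified, seeded 10-fold
   cross-validation with a fold-pooled confusion matrix; exact t-SNE for
   visualisation.
4. **Marker statistics** — peak intensities, ratios against the
   1186 cm⁻¹ amide III reference, one-way ANOVA + Tukey HSD, and
   correlation of band intensities with physicochemical replicates via a
   seeded random tripartition.
5. **Synthetic data** — a seeded generator of single-fibre spectra
   (Gaussian bands with day-dependent amplitudes, hierarchical fish/fibre
   heterogeneity, baseline drift, noise, global thickness scale) plus a
   surrogate physicochemical table, so the whole chain is testable
   offline.

## Worked example

```r
library(freshir)

cfg <- default_scenario("paper_effects")   # 7 days x 3 fish x 39 fibres
spectra <- generate_spectra(cfg)           # 819 spectra, 600-2500 cm-1
pre <- preprocess(spectra, preprocess_config())

## biomarkers separating day 0 from day 7
model <- fit_pcda(pre, groups = c(0, 7))
model
#> <PCDAModel> groups D0/D7 | K = 6 PCs | 1 canonical axis(es) | n = 117+117
head(extract_biomarkers(f1_vector(model), top_fraction = 0.5), 6)
#>   wavenumber       score associated_group
#> 1       1176  0.26470295                0
#> 2       1670 -0.23471101                7
#> 3       1552  0.17922852                0
#> 4       1634  0.12123826                0
#> 5       1490 -0.09574109                7
#> 6       1204 -0.09396813                7

## predict the postmortem day from spectra alone
svm_cv(pre, folds = 10, seed = 42)
#> <CVReport> 10-fold CV | overall accuracy 100.0%
#> per-class accuracy (%):
#>   0   1   3   5   7   9  15
#> 100 100 100 100 100 100 100

## the freshness marker: 1176 cm-1 intensity, day 0 vs day 7
corrected <- preprocess(spectra, preprocess_config(normalise = FALSE))
pk <- peak_intensity(corrected, 1176)
mean(pk$intensity[corrected$meta$day == 0]) /
  mean(pk$intensity[corrected$meta$day == 7])
#> 1.93
```

The top extrema of the contribution vector land on the injected
differential bands with the expected signs (1176/1553/1635 positive →
fresh; 1670/1490/1205 negative → aged), every day class is predicted
correctly out-of-fold, and the 1176 cm⁻¹ peak is recovered close to the
two-fold day-0/day-7 contrast the generator encodes (measurement within a
±5 cm⁻¹ window on baseline-corrected spectra slightly dilutes the exact
factor 2).

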