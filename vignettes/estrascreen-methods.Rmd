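---
title: "Models and methods behind estrascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind estrascreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estrascreen)
```

`estrascreen` quantifies growth phenotypes of yeast strain collections in
which a β-estradiol-titratable synthetic promoter replaces each native
promoter. This vignette documents the models the package implements, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design choices made where the underlying procedures
are genuinely open.

## The measurement model

### Colony quantification

A plate image is a grayscale matrix carrying a regular 16×24 or 32×48
colony lattice on a smooth background. `detect_grid()` first flattens
smooth background trends by subtracting per-column and per-row 10th
percentiles (colonies never reach down to the 10th percentile of an image
line, the background always does), thresholds at median + 3·MAD of the
flattened image, and projects the foreground mask onto each axis. The
grid pitch is the argmax of the projection autocorrelation over the lag
window implied by the expected grid dimension; the phase maximizes the
summed (lightly smoothed) profile over the candidate comb. Each center is
then refined by a local centroid and the set is regularized by a
mass-weighted linear fit of center against grid index. Three gates
protect against degenerate inputs: a minimum foreground fraction (0.5%;
an adaptive threshold leaves about 0.1% on pure noise), a minimum
foreground concentration at the lattice positions (1.2× the profile
mean), and a maximum median deviation of occupied centroids from the
fitted lattice (0.15 pitch). A uniform or noise-only image fails loudly.
Because early-timepoint images legitimately carry almost no signal, the
pipeline detects each plate's grid once on its final (fullest) image and
reuses it for earlier timepoints.

`measure_colonies()` scores each grid cell as the number of pixels above
an adaptive local threshold: within a window spanning two grid pitches
around the cell, the threshold sits halfway between the 10th and 99.5th
intensity percentiles; a window with less than 0.08 contrast (on the
[0, 1] intensity scale) is scored 0 rather than thresholding noise. The
quantile construction makes raw sizes exactly invariant to constant
intensity offsets.

### Size normalization

`normalize_sizes()` works per plate image, in the order plate →
positional → competition:

1. divide by the plate's median measurable interior colony size;
2. divide by a spatial surface — a 7×7-cell moving median smoothed by a
   9×9 moving mean — and by row/column median factors. The mean filter
   exists because windowed medians jitter with per-colony biology;
   dividing by an unsmoothed median surface would partially divide out
   real strain effects. Row/column factors are applied only when the
   median deviates from 1 by more than ~2 standard errors of that median
   (1.2533·MAD/√n): genuine row artifacts (failed pin rows, agar ridges)
   are large, while median jitter on plates with real per-colony spread
   is of the same size as a smooth-gradient residual and must not be
   divided out of a quiet plate;
3. cap colonies that have ≥3 dead (size < 0.1) neighbors at the local
   live median — colonies fed by the nutrients of dead neighbors
   otherwise read as spuriously fit;
4. flag perimeter colonies (`edge_flag`) and exclude them from downstream
   statistics. Perimeter positions carry the wild-type reference strain,
   so they still receive normalized values for reference scaling.

The interior median of normalized sizes is re-scaled to exactly 1, and
the whole chain is invariant to global rescaling of a plate's sizes. A
plate image with under half its interior measurable is flagged
low-quality but *not* excluded: that state is expected at early
timepoints and on no-inducer plates full of inducer-dependent strains.

### Growth curves and AUGC

`build_curves()` pools replicate colonies per (strain, medium, dose) and
fits a LOESS smoother (degree 2, span 0.5 by default) over the pooled
points, clipping negatives to 0; groups with fewer than three distinct
timepoints are flagged unsmoothable and carry per-time replicate means.
The span sets the smoother's resolution: at span 0.5 over a 48-h series
the effective window is ~24 h, which tracks logistic growth at rates up
to ~0.25/h within 5%; steeper curves are attenuated at the knee (the
dose–response integral is barely affected, but users smoothing very fast
growth should lower the span).

AUGC is the trapezoid integral of the smoothed curve over the common time
window of all curves, divided by the same-plate wild-type reference AUGC
at the same dose (the scaling actually applied is recorded in the matrix
attributes; a missing reference falls back to the per-dose median with a
warning). AUGC is used because it integrates lag, rate and capacity
without committing to a parametric growth model. Replicates are pooled
before integration; the replicate count is reported per cell.

## Dose-response behaviors

`cluster_profiles()` clusters strain AUGC profiles with the Chebyshev
(L∞) metric — the distance is the single dose of largest disagreement,
which separates behaviors that agree at most doses but diverge at the
extremes — under average linkage, cut at k = 5 by default. Linkage is not
dictated by the clustering metric itself; average linkage matches the
package's other hierarchical steps. Missing cells are imputed from the
nearest dose; strains are processed in `strain_id` order and clusters are
renumbered by decreasing mean profile at the lowest dose, so results are
invariant to input order and reproducible. `label_behavior()` then reads
each cluster mean: profiles never rising above 0.2 of the reference are
non-functional; profiles starting below 0.2 are inducer-dependent
(dependent-toxic when they fall > 30% from their peak at high dose);
profiles starting high are constitutive (constitutive-toxic with the same
fall). Both thresholds are configurable; an unreadable profile is labeled
`unclassified`, never silently forced.

## Per-strain scores

* **Aux score** = (G_M1/G_M0)/(G_R1/G_R0) on total growth over
  {YNB, SC} × {0, 1 nM}. Nonpositive totals are floored to a configurable
  pseudogrowth (default 1 unit) and flagged; the score is invariant to
  per-strain rescaling of growth units.
* **Toxicity**: after removing the top 2% / bottom 4% of either axis, an
  OLS line y = m·x + b relates growth at 100 nM to growth at 0 nM;
  y_corr = (y − b)/m maps the induced measurement back to the uninduced
  scale, and the score is the perpendicular distance to the diagonal
  |x − y_corr|/√2, with the toxic call requiring distance > 2000 *and*
  y_corr < x. The printed description of this correction admits two
  readings; mapping the 100 nM measurement onto the 0 nM scale is the
  only one under which the subsequent diagonal-distance test measures an
  inducer effect, and is what the package implements. The 2000-unit
  threshold is tied to colony sizes on the scale of high-resolution plate
  scans; the generator's default carrying capacity (10,000 px) puts
  simulated screens on that scale. A non-positive fitted slope aborts.
* **Reversibility**: ratio = growth without / growth with inducer;
  ≤ 0.55 reversible, ≤ 0.75 partially reversible, > 0.75 not reversible,
  boundaries inclusive exactly as printed.
* **Dependence**: AUGC(0)/max(AUGC) with configurable cutoffs (≥ 0.75
  constitutive, ≤ 0.25 dependent, otherwise partial; max below an
  absolute floor is no-growth). These cutoffs are declared package
  defaults — the source procedure names the classes but no thresholds.
* **SDL**: per replicate screen, score = log2(size at 1000 nM / size at
  0 nM), interaction called when the score is below −0.08 in *all*
  replicates. The −0.08 cutoff is printed without a scale; a raw ratio
  can never be negative, so the package scores on log2 by default and
  offers ratio − 1 as the alternative.

## BAR-seq

Reads carry `[GCACCAGGAACCATATA][12-nt barcode][GATCCGCTCGCACCG]`.
`count_reads()` locates the upstream flank (≤1 mismatch, ±2 positions),
extracts the barcode, verifies the downstream flank under the same
tolerance, and assigns the read to the unique strain within 2 Hamming
mismatches; reads within budget of two or more strains are ambiguous and
discarded, never fractionally assigned. Flank tolerances are separate
from the barcode budget. Assignment is provably unambiguous when the
index's minimum pairwise distance is ≥ 2·max_mismatch + 1 = 5, which the
generator guarantees and `build_index()` checks (warning otherwise). Per
sample, assigned + ambiguous + unassigned = total is asserted. The
per-read scan is compiled (Rcpp) with an exact-match shortcut that is
only enabled when the index separation makes it sound.

`fitness_log2fc()` floors counts at the 5th percentile of the pooled
time-zero distribution (depletion below sequencing background is not
measurable; the quantile is configurable, 0 disables), divides by the
wild-type spike-in count per sample, and normalizes to the time-zero
samples on the log2 scale — i.e. by the geometric mean of the t0 ratios,
so each strain's t0 columns average to exactly 0 and the wild-type row is
identically 0. The spike-in fraction itself (3% in the generator) never
enters the math. `cluster_fitness()` clusters profiles by 1 − Pearson
correlation with average linkage and annotates cluster means by condition
arm (depleted only in minimal medium without inducer → auxotroph-like;
depleted in induced arms → overexpression-toxic-like). Correlation
distance is scale-free, which has a known blind spot: strains with flat
(neutral) profiles have no defined direction, so in noisy data the
neutral cloud does not form a tight cluster — pattern recovery holds for
planted, non-degenerate signals, and the per-cluster condition
annotations (not cluster membership alone) are what should be interpreted
on real data.

## The synthetic-data generator

The generator exists so that every stage is testable against known truth.
Its defaults encode the screen conditions the package models: the 12-dose
grid (0, 0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30, 100, 300, 1000 nM), imaging
every 2 h to 48 h, SC and YNB media, quadruplicate colonies, a 3%
wild-type spike-in, and the archetype mix observed for essential-gene
promoter alleles (constitutive 33%, constitutive-toxic 9.2%,
non-functional 4.2%, dependent-toxic 4.7%, dependent 49%).

Growth is logistic, A(t) = K_eff/(1 + ((K_eff − A0)/A0)e^{−rt}), with
K = 10,000 px, A0 = 50 px, r = 0.35/h, and
K_eff = K · f_ind(dose) · f_tox(dose): a Hill induction response
(EC50 = 1 nM, coefficient 1.2 — saturating around 10–100 nM) gates
dependent archetypes and, on YNB only, auxotroph-flagged strains;
a Hill toxicity response (midpoint 30 nM, coefficient 2) scales capacity
down by the strain's toxicity effect (drawn from 0.5–0.9 for toxic
archetypes); non-functional promoters keep 2% leak. No generative growth
model is prescribed by the screens themselves — any parameterization
reproducing the five archetype shapes would do; this one is the package's
choice and lives entirely in `sim_config()`. Measured sizes carry
multiplicative log-normal noise (default relative SD 0.05); the noise
structure of real colony sizes is not documented anywhere, so log-normal
is a declared modeling assumption. Native expression is drawn
log-normally with low medians for constitutive archetypes and high for
dependent ones, reflecting that promoter leak rescues only lowly
expressed genes — this is what gives the expression–growth association
statistics real signal to find.

Plate rendering draws colonies as domed intensity disks at lattice
positions (the carrying capacity maps to the largest disk that fits the
pitch), over a background with a configurable left-to-right gradient
(default 0.05) and Gaussian pixel noise (default 0.02), written as
16-bit grayscale TIFF; the exact rendered pixel count per colony is
recorded as ground truth. Pooled runs start strains at log-normal
abundances (sdlog 1.2, the wide spread of real pooled libraries), deplete
auxotroph-like strains in the uninduced YNB arm and toxic strains in the
induced arms linearly in time to at most −1 log2 unit, sample reads
multinomially, and inject independent per-base substitution errors
(default 0.5%). Substitution-only errors keep the assignment oracle
exact; indel robustness is out of scope, as is demultiplexing (samples
are generated pre-demultiplexed) and any attempt to model pinning
robotics, aging or ploidy.

What passing tests therefore show: the pipeline recovers truth under
archetype-shaped logistic growth, smooth plate artifacts, log-normal size
noise, and substitution-only sequencing error. What they cannot show:
robustness to real-image pathologies (condensation, reflections, grid
warping), non-multiplicative size noise, indels, or chimeric reads.

## Determinism and problem sizes

All randomness flows from one integer seed through named per-stage
substreams (`stage_seed()`), so any stage can be re-run independently and
the full pipeline reproduces byte-identical artifacts (asserted via md5
checksums in the run manifest). The test suite exercises the guarantees
at these sizes, chosen to make the statistical assertions sharp while the
whole suite stays desk-scale: 8 rendered 384-format plates for
quantification recovery; 500 strains × 12 doses for archetype recovery
(adjusted Rand index ≥ 0.9 at noise SD 0.05); 5,000 strains with 5%
planted toxicity for the toxicity caller's sensitivity ≥ 0.9 and
false-discovery proportion ≤ 0.1; and 1,000 strains × 10^6 reads per
sample for BAR-seq (exact counts at zero error, oracle-identical
assignment at 0.5% error, planted log2FC RMSE ≤ 0.1 for strains with t0
counts ≥ 200).

## Known limitations

* Grid detection assumes an axis-aligned lattice; rotation and lens
  distortion are not modeled or corrected.
* The adaptive colony threshold assumes colonies brighter than
  background and under ~50% local foreground; fully confluent plates
  will underestimate sizes.
* LOESS smoothing attenuates growth knees sharper than the span's
  resolution (see above).
* Correlation-distance fitness clustering cannot group flat profiles in
  noise (see above).
* The toxicity distance threshold is an absolute size-unit quantity; data
  on a different imaging scale need a rescaled threshold.
* Real-data headline counts from any particular screen (numbers of toxic
  genes, cluster fractions, published correlations) depend on the
  original images and sequencing runs and are not reproduced by the
  synthetic suite.
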