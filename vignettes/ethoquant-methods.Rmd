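---
title: "Methods: quantification models and design choices in ethoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification models and design choices in ethoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethoquant)
```

ethoquant packages the quantitative core of an in vitro ethanol-exposure
workflow on differentiated neuroblastoma cultures: fixed-threshold
segmentation and colocalization readouts for multi-channel
immunocytochemistry (ICC), live/dead viability ratios, ddCt relative qPCR
quantification with reference-gene stability selection, physiological
ethanol unit conversions, and an assumption-gated statistical routing
layer. A seeded synthetic-data generator supplies ground-truthed inputs so
that every stage is testable without microscope or thermocycler data.

## Image quantification model

Each microscope field is a set of co-registered single-channel intensity
rasters (one marker per channel, e.g. PV, NLGN2, a neurexin isoform).
Preprocessing, in order:

1. optional isotropic resize (bilinear for intensities, nearest-neighbour
   for a provided composite mask);
2. per-image min-max normalization to $[0,1]$ (a constant image maps to
   zeros rather than dividing by zero);
3. gamma correction $x \mapsto x^{\gamma}$ with $\gamma = 0.8$ by default
   (values below 1 brighten mid-tones);
4. scaling to the 8-bit range with clipping and rounding.

The mapping is monotone, so the subsequent fixed global threshold induces
the same ordering of pixels as the raw data. Segmentation takes a pixel as
positive when strictly above the channel's threshold ("suprathreshold");
the strict reading makes threshold 255 give an empty mask and threshold 0
on a rendered binary image reproduce it exactly, and the inclusive
alternative is one configuration flag away
(`segmentation_params(threshold_mode = "ge")`).

**Thresholds are required configuration with no default.** The threshold is
the pipeline's key free parameter; a silent default would manufacture
results. All parameters (`resize_factor`, `gamma`, `thresholds`) are fixed
per batch and must be held constant across every field being compared —
cross-image comparability rests on that constancy, since normalization is
per-image.

Per-field readouts:

* **percent area** per channel: $100 \cdot |M_c| / N_\mathrm{px}$;
* **merged denominator**: a provided composite mask verbatim, else the
  pixelwise union of the channel masks;
* **overlap** of a target mask with each comparison mask: the AND-area,
  reported relative to the merged area (prevalence in the multi-label
  scene) and relative to the target's own area (fraction of target signal
  coincident with the comparison marker);
* **membership map**: per-pixel count of channel memberships, color-coded
  for pixels in exactly two, three, or four channels (2–4 channels
  supported).

Zero denominators (an empty merged or target mask) make a metric
*undefined*, carried as `NA` — never coerced to 0, which would fabricate a
measurement. Fields within a well are technical replicates:
`aggregate_fields()` returns the mean and sample standard deviation per
metric, excluding undefined values pairwise and recording the contributing
field count, and these well-level means are the units of statistical
analysis. The live/dead ratio divides the green (calcein, live) percent
area by the red (ethidium homodimer, dead) percent area; an empty red mask
flags the ratio undefined rather than erroring.

The package deliberately stops at area-based metrics: no per-cell instance
segmentation, no Manders/Pearson coefficient suite. A marker-restricted
metric (e.g. "overlap within PV-positive signal") is the target-referenced
overlap with that marker as target.

## Synthetic image fields

`generate_field()` renders each cell as a Gaussian-profile disc: intensity
$I_0 e^{-d^2 / (2\sigma^2)}$ truncated to zero outside radius $r$, with
$\sigma = r$. The boundary pixel therefore sits at $I_0 e^{-1/2} \approx
0.61 I_0$; this profile width is a deliberate choice — a sharper profile
(e.g. $\sigma = r/2$, boundary at $0.135 I_0$) leaves disc-edge pixels
statistically inseparable from background at the noise levels the tests
exercise (additive Gaussian noise up to 10% of the dynamic range), making
ground-truth recovery impossible for any threshold. With $\sigma = r$, any
threshold strictly between the noise ceiling and the boundary intensity
recovers the true mask to within a handful of edge pixels.

Colocalization between two channels is produced by co-placing a controlled
subset of disc centers: `coloc = c("a|b" = f)` shares
$\mathrm{round}(f\,n_\mathrm{cells})$ centers between the channels. With
equal radii the realized area-overlap fraction of either channel equals the
shared-cell fraction up to whole-pixel rasterization, so requests are
honored within ±0.02. Centers are placed by rejection sampling with a
minimum separation of $2 r_{\max} + 3$ pixels, so cells never touch within
or across channels except by co-placement; requests that cannot be placed
(too many shared cells per channel, or densities the field cannot hold)
raise explicit infeasibility errors rather than degrading silently.
Randomness is governed by a single master seed: placement under the master
seed, per-channel noise under substreams derived as
$\mathrm{seed} + 7919\,i$, giving bit-identical output for identical seeds.

Ground truth records the true masks, per-channel area fractions, pairwise
overlap fractions (as fractions of field pixels, so overlap can never
exceed either channel's area fraction), and per-channel cell counts.
`generate_live_dead()` reuses the machinery for the viability assay:
`round(live_fraction * n_cells)` cells in the green channel, the remainder
in red, masks disjoint by construction.

What the generator does *not* emulate: point-spread-function realism,
3-D stacks, photobleaching, illumination gradients, cell-shape variation,
or within-channel overlapping cells. Passing recovery tests therefore
demonstrates the correctness of the measurement chain, not robustness to
every artifact of real micrographs; thresholds for real batches must still
be chosen against real staining controls.

## ddCt quantification and reference-gene stability

For each target gene, $\Delta C_t = C_t^{\mathrm{target}} -
C_t^{\mathrm{hk}}$ is computed per biological replicate, pairing wells
within (status, dose, replicate); rows missing either side are dropped with
a warning, never imputed. Two calibrator conventions are supported, both
using a *mean* calibrator $\Delta C_t$:

* **cross-status**: the 0 mM undifferentiated group calibrates every group,
  so that group's fold change is 1 and differentiation effects are read
  directly;
* **within-status**: each status's own 0 mM group calibrates it, isolating
  dose effects within status.

Per replicate, $\mathrm{FC} = E^{-\Delta\Delta C_t}$ with amplification
efficiency $E = 2$ (the classic assumption; configurable but not estimated
— no dilution-series machinery is included). The group fold change is the
arithmetic mean of replicate fold changes, matching displays that plot
per-replicate points around bar means; `summary = "fc_of_mean"` gives the
alternative $E^{-\overline{\Delta\Delta C_t}}$. Evaluated at the calibrator
group's own mean $\Delta C_t$ the fold change is exactly 1 under either
convention, and zero-noise synthetic tables round-trip arbitrary true fold
changes exactly.

Reference-gene selection (`normfinder_stability()`) follows the
model-based variance-decomposition idea: on the Ct scale (already log2 of
quantity up to affine terms), for candidate gene $i$ in group $g$,

* the **intergroup bias** $d_{ig}$ is the gene-by-group interaction —
  how far the gene's group mean departs from its overall level after
  removing group shifts common to the whole candidate panel;
* the **intragroup variance** is estimated from replicate residuals after
  removing a per-sample effect shared across genes, with the small-panel
  unbiasedness correction (for exactly two candidates the per-sample effect
  is unidentifiable and the plain per-cell variance is used);
* the **stability value** is the mean over groups of
  $|d_{ig}| + \sqrt{\hat\sigma^2_{ig} / n_g}$; the smallest value wins,
  ties broken alphabetically with a warning.

Two properties of this estimator class are worth understanding. First, bias
is measured *against the candidate-panel consensus*: the per-group biases
of the panel sum to zero, so a gene is "stable" insofar as it agrees with
the panel average. If the competitors' biases are arranged so that a biased
gene sits at the consensus, it will (correctly, given the available
information) rank best. Second, discrimination between a biased and an
unbiased low-noise candidate is informed only by the remaining candidates;
with a three-gene panel in which the arbiter gene has replicate sd 1 Ct and
the bias at stake is 1 Ct, the arbiter's status contrast has sampling sd
$\sqrt{2/(3n)}$ Ct against a 0.5 Ct decision margin, so reliable (>95%)
selection requires on the order of $n \gtrsim 10$ replicates per cell
regardless of estimator. The selection-accuracy simulation in the test
suite accordingly uses 12 replicates per cell; at 3 replicates no method
can exceed roughly 86% on that scenario.

During exploration two variants were rejected: down-weighting noisy genes
when forming the consensus destroys identifiability (with the noisy arbiter
muted, the biased and unbiased genes become exactly symmetric), and
shrinkage of the bias terms without a separate intragroup-variance
contribution lets a high-variance gene shrink to a spuriously perfect
stability of zero.

## Ethanol dosimetry

The conversion chain, with defaults anchored to human magnetic-resonance
spectroscopy measurements of cerebral ethanol:

$$\mathrm{serum\ mM} = 1.67 \times \mathrm{brain\ mM}, \quad
\mathrm{serum\ mg/dL} = \mathrm{serum\ mM} \times 46.07 / 10,$$
$$\mathrm{blood\ mg/dL} = \mathrm{serum\ mg/dL} / 1.24, \quad
\mathrm{\%BAC} = \mathrm{blood\ mg/dL} / 1000,$$

where %BAC is grams ethanol per 100 mL blood (w/v). Tissue g/L converts to
mM as $1000\,x / 46.07$ times a brain-water normalization factor that
defaults to 1 — the conventional cortical value 0.68 g/L already lands at
~14.8 mM without further adjustment, and the factor remains a configuration
knob. Every conversion is homogeneous of degree 1 and exact along the
chain; rounding happens only at presentation. Note that published chains of
this kind are typically printed with per-step rounding, so reproducing
printed values is expected to the printed precision, not to machine
precision (e.g. the default constants give 0.217% BAC for 35 mM brain,
printed as ~0.22%).

## Assumption-gated statistics

`gate()` reproduces a fixed decision tree at $\alpha = 0.05$, recording an
audit line for every decision:

1. Shapiro–Wilk per group on the raw data (groups of fewer than 3 route
   nonparametric with a warning);
2. if normality fails and the data are strictly positive, log-transform and
   re-test; if normality still fails, route to Kruskal–Wallis;
3. Levene's test (F type, mean-centered, outliers included) on the possibly
   transformed data; heterogeneity routes to Brown-Forsythe and Welch ANOVA
   with Dunnett T3 pairwise comparisons;
4. otherwise the parametric route: one-way ANOVA with Dunnett many-to-one
   comparisons against the labeled control, or the two-way factorial with
   Sidak (within-level) or Tukey (all-pairs) cell comparisons.

Normality is remedied before variance homogeneity because the
log-transform is the designated normality remedy and itself changes the
variance structure; the tree is fixed rather than data-optimized.
Mauchly/Greenhouse–Geisser sphericity handling belongs to repeated-measures
designs and is inert for the between-subjects designs covered here. When
the log route is taken, group means are back-transformed for display and
equal geometric means of the raw data. Two-sided tests throughout.

Standard test mathematics are delegated to established implementations
(`stats::aov`, `stats::oneway.test`, `stats::shapiro.test`,
`stats::kruskal.test`, `car::leveneTest`, `multcomp::glht`, `emmeans`).
Two pieces are computed in-package from their published formulas: the
Brown-Forsythe ANOVA statistic
$F^* = \sum_i n_i(\bar y_i - \bar y)^2 / \sum_i (1 - n_i/N)s_i^2$ with
Satterthwaite denominator df, and Dunnett T3 — pairwise Welch $t$
statistics referred to the studentized maximum modulus distribution with
the family size and each pair's own Welch–Satterthwaite df, the SMM CDF
evaluated by numerical integration over the scaled-chi mixing density (the
chi density is computed on the log scale to stay finite at large df). With
one comparison the SMM reduces to the folded $t$, which the tests verify
against `pt()` directly.

Degenerate inputs (all groups constant) are flagged rather than tested;
adjusted p-values are monotone in the raw p and bounded by 1.

**Calibration harness.** `calibrate_route()` simulates each route's own
null and reports the fraction of replicates with any rejection — familywise
for post hoc families, omnibus otherwise. The suite checks each family at
2000 replicates against the band [0.03, 0.07] at $\alpha = 0.05$: the
Dunnett family on 3 groups of 3; the factorial interaction on a 2×3 design
with 5 per cell; Welch and the T3 family on 3 groups of 10 with variances
(1, 25, 1); Kruskal–Wallis on skewed groups of 10. A negative control runs
classic equal-variance ANOVA on a heteroscedastic unbalanced null, where it
exceeds the nominal level — the reason the heteroscedastic route exists.
Dunnett T3 is mildly conservative by construction (the SMM bound ignores
the positive dependence of comparisons sharing a group), which the band
accommodates.

## Numerical and interface conventions

* Rasters are numeric matrices on the 8-bit scale; 16-bit input is accepted
  and normalized per image. Fields serialize as one grayscale PNG per
  channel plus a JSON ground-truth sidecar (fractions, counts, seed — masks
  are reproducible from the seed, not stored).
* Ct tables are tidy CSVs (`gene, group, dose_mM, replicate, ct`); missing
  Ct (no amplification) rows are dropped, never imputed.
* All generators take explicit integer seeds and leave the caller's RNG
  state untouched; identical seeds give bit-identical outputs.
* Problem sizes in the shipped test suite (fields up to 256×256, 40–50
  cells, 200-field oracle sweeps, 200-table selection simulations, 2000
  replicates per calibration route) were chosen as the smallest sizes at
  which the Monte-Carlo bands are meaningfully tight.

## Known limitations

* Area-based colocalization only; no object-level statistics.
* Amplification efficiency is assumed, not estimated.
* The stability analysis quantifies candidate agreement, not absolute
  stability: with small panels an external anchor (e.g. a spike-in) is the
  only escape from the consensus relativity described above.
* The gate's routing is sequential and fixed; it does not search over
  transforms or tests, by design.
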