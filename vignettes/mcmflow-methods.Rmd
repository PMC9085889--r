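---
title: "Metabolic connectivity mapping: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic connectivity mapping: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcmflow)
```

# Scope

`mcmflow` implements the analysis chain of a simultaneous PET/MR learning
study: quantification of the cerebral metabolic rate of glucose (CMRGlu)
from functional [18F]FDG PET, cerebral blood flow (CBF) from arterial spin
labeling, BOLD preprocessing for functional connectivity, a multimodal
conjunction that defines target regions, whole-brain metabolic
connectivity mapping (MCM), repeated-measures group statistics with
permutation cluster inference, behavior coupling, and a voxel-removal
perturbation analysis. Because raw imaging data of such studies are
typically not shareable, every stage is exercisable on synthetic studies
with known ground truth; the generator is first-class, tested code.

# Quantification models

## fPET and the Patlak plot

Under a bolus-plus-infusion [18F]FDG protocol, tissue activity for an
irreversibly trapped tracer follows the Patlak relation
$C_t(t) = K_i \int_0^t C_p\,d\tau + V_0\,C_p(t)$. Plotting
$C_t/C_p$ against $\int_0^t C_p\,d\tau \,/\, C_p$ yields a line whose
slope is the influx constant $K_i$ (1/min). CMRGlu follows as
$K_i \cdot \mathrm{Glu}_{plasma} / LC \cdot 100$ (µmol/100g/min) with the
lumped constant $LC = 0.89$.

The arterial input function is assembled from seven manual samples
(3, 4, 5, 14, 25, 36, 47 min): whole-blood activity is linearly
interpolated to the frame mid-times (held at the nearest sample outside
the sampled range) and scaled by the subject's mean plasma-to-whole-blood
ratio, taken as a single subject-level constant. The running integral
uses the trapezoid rule from time zero, holding the first value
backwards. Linear interpolation cannot see the bolus peak before the
first sample at 3 min; the missed area shifts the Patlak abscissa by a
near-constant amount that loads almost entirely on the intercept, so
$K_i$ recovery from sampled blood is accurate to a few percent, while
recovery from the dense per-frame input function is exact to well below
1%. Tests assert both tolerances separately.

Baseline and task uptake are separated by a per-voxel GLM with four
regressors: the gray-matter mean time course (excluding task-activated
voxels), one linear ramp per task condition (slope 1 kBq per frame within
blocks, cumulative across repeated blocks), and the first principal
component of the six motion parameters. Time-activity curves are low-pass
filtered with a centered moving average spanning 3 min (6 frames of
30 s); the same filter is applied to the design columns, so any noise-free
linear combination of regressors is recovered exactly — filtering only
the data would bias the coefficients. The Patlak linear phase starts at
$t^* = 10$ min by default (configurable); the scan is 52 min, so 84
frames enter the fit. Task-condition influx composes the baseline slope
with the ramp coefficient $\beta$ (kBq/ml per frame) as
$K_i^{cond} = K_i^{base} + \beta / (\Delta t \cdot \overline{C_p})$
with $\Delta t$ the frame length in minutes and $\overline{C_p}$ the mean
plasma activity over the task window; the division by $\Delta t$ makes
the composition dimensionally consistent for 30-s frames.

## ASL

CBF is quantified with the single-compartment model
$$\mathrm{CBF} = \frac{\lambda\,\Delta M\,R_{1a}}
{2\alpha M_0\left[e^{-\omega R_{1a}} - e^{-(\tau+\omega) R_{1a}}\right]}$$
with $\lambda = 0.9$ ml/g, $R_{1a} = 0.67\,s^{-1}$, $\alpha = 0.8$,
post-labeling delay $\omega = 1800$ ms at the first slice (rising by a
configurable per-slice increment for 2D readouts), and labeling duration
$\tau = 1508$ ms. All times are converted to seconds once, internally;
the result is rescaled to ml/100g/min (×6000). $\Delta M$ is the
control-minus-label pairwise difference (frames pair as (2k−1, 2k);
parity configurable), $M_0$ the mean of the non-labeled frames. Voxels
below 0.8× the global mean intensity are zeroed before quantification,
and voxels with $M_0 = 0$ return 0. Task-condition maps contain resting
perfusion plus the task response, so the rest map is subtracted to
isolate task effects. A worked value anchors the implementation:
$\Delta M / M_0 = 0.01$ at slice 1 gives ≈ 118.8 ml/100g/min.

## BOLD preprocessing and activation

Framewise displacement is the Power convention: L1 sum of backward
differences of the translations plus rotations converted to displacement
on a 50 mm sphere. Frames with FD > 0.5 mm are censored together with one
frame back and two forward. Censoring precedes nuisance regression
(motion, white matter, CSF, intercept) and a zero-phase Butterworth
bandpass (two second-order passes, 0.01–0.15 Hz) applied to the retained,
re-indexed series; gap-aware filtering would be the alternative — the
order used here is a documented package choice, not an inference about
any particular study's pipeline. Activation maps come from a block-design
GLM with boxcars convolved with the canonical double-gamma HRF.

## Conjunction and MCM

Activation maps per modality are thresholded, binarized and intersected;
overlap is summarized by the Dice coefficient. Connected components use
26-connectivity (SPM-like); components below 1.0 cm³ (configurable) are
dropped, and mirror-symmetric components across the grid midplane can be
merged as left/right homologues.

MCM assigns to every source voxel $A_i$ the Fisher-z of the spatial
correlation, across target-region voxels, between (i) the voxel's
temporal-correlation pattern with the target (each Pearson r Fisher-z
transformed) and (ii) the target's CMRGlu pattern, using the
condition-matched CMRGlu map. Directionality rests on energy demands
being predominantly post-synaptic: a seed region influencing the target
leaves matched FC and CMRGlu patterns there. Numerical choices: |r| is
clipped at $1 - 10^{-7}$ before `atanh`; zero-variance target voxels
contribute z = 0 (keeping pattern length fixed across subjects) with a
warning; a constant FC pattern maps to 0 while a constant CMRGlu pattern
is an error; target voxels are excluded from the source set by default
because self-correlation inflates the spatial correlation. The spatial
correlation is Pearson on the z-values (rank-based variants were
considered and not adopted, for continuity with the temporal step). The
whole-brain map is validated against a brute-force per-voxel double loop
to 1e-10.

# Group statistics

Training effects sit in a group (between) × time (2) × condition (3)
design. The primary route forms per-subject time-2 minus time-1
differences and fits a group × condition repeated-measures ANOVA on
them — the group × condition term is then the three-way
group × time × condition interaction, and the group main effect the
group × time interaction. The direct three-factor mixed ANOVA is also
exposed; for a two-level time factor both routes coincide, which the
tests assert against a hand-written sums-of-squares oracle. The second
contrast of interest, rest vs. task, is implemented as
$d_{rest} - (d_{easy} + d_{hard})/2$ compared between groups (mean
weighting chosen over sum; only the F scale differs). Sphericity
corrections are omitted — the within factor enters the primary route only
through differences — and noted as a limitation. Post-hoc tests per
condition are the two-sample comparison of time differences (F = t²) and
paired t within groups; zero-variance differences resolve to exact
results rather than errors. Multiplicity uses Bonferroni–Holm.

Map-level inference replaces parametric FWE with a max-cluster-extent
permutation test: per-voxel two-sample t on subject difference maps,
two-sided cluster-forming threshold p < 0.001, 26-connected extents, and
a null distribution over random group-label exchanges (default 2000
permutations, seeded). The family-wise error calibration is verified by
simulation.

Behavior: fold change is reported both as the ratio of group means and
the mean of per-subject ratios (the two estimands differ under noise;
both are exposed). The normalized learning-curve AUC is the trapezoid
integral over training days divided by the day span — the mean daily
score — so a flat curve at c has AUC c. Divergence between rest and task
MCM is $(rest - task) / \mathrm{mean}(rest, task)$, which removes the
common scale while avoiding mathematical coupling with the absolute
level; associations with behavior use Spearman's rho (Pearson on average
ranks) to withstand single outliers.

# The synthetic study

The generator emulates the statistical structure the analysis assumes,
not scanner physics. Geometry is desk-scale: an axis-aligned cuboid
target ("Occ"-like) and a disjoint seed cuboid ("SN"-like) inside a
24 × 24 × 12 grid. Defaults mirror the assumed study shape: 21 training
and 20 control subjects, two scans (M1, M2), conditions rest/easy/hard,
30-s PET frames over 52 min with arterial samples at the seven stated
times, 2-s BOLD frames over 6 min, alternating ASL control/label frames.

BOLD target voxels follow
$s_v(t) = \rho w_v u(t) + \sqrt{1 - \rho^2 w_v^2}\,\varepsilon_v(t)$
with a shared latent seed series $u$, per-voxel seed-influence weights
$w_v \sim U(0.3, 1)$, and unit-variance Gaussian noise, so the FC pattern
across the target is proportional to $\rho w_v$ and the planted MCM value
rises monotonically with the coupling $\rho \in [0,1]$. Seed-region
voxels carry $u$ plus noise; everything else is white noise. The target's
true $K_i$ pattern is $0.016 + 0.006\,w_v$ (1/min) over a background of
$N(0.018, 0.002^2)$, giving CMRGlu near 11 µmol/100g/min at plasma
glucose 5.45 mmol/l — ordinary gray-matter physiology. Subject CMRGlu
patterns add 4% relative noise.

The default coupling plants the training effect: all cells at 0.3 except
the training group's second scan, where rest rises to 0.55 and hard falls
to 0.12. These effect sizes were chosen once so that the planted
between-group difference is large relative to between-subject MCM
variability (≈3 standard deviations), i.e., a clearly powered study; they
are not calibrated to any reported F value. The behavioral generator
uses a saturating-exponential learning curve (time constant 6 days over
21 days) and per-scan scores whose training-group M2/M1 group-mean ratio
equals the configured fold changes (2.7 easy, 3.1 hard) in expectation,
with 20% between-subject and 10% within-subject variability. Motion
traces are slow random walks plus isolated 1-mm translation jumps; two
spikes per 180-frame run put the expected censoring near 4.4% of frames.
ASL series invert the CBF equation at 60 ml/100g/min at rest and
66/72 ml/100g/min (easy/hard) inside the activation region; plasma input
is a gamma-variate bolus with exponential washout onto an infusion
plateau. The plasma-to-whole-blood ratio is a config constant
(default 1.0), as no value is assumed for it.

Two generator entry points carry the same statistical structure:
`generateStudy()` writes full NIfTI/TSV studies (intended for small
grids; outputs are uncompressed so fixed seeds give byte-identical
files), and `simulateMcmStudy()` produces the compact per-record
target/cluster representation that the group analysis and the
perturbation study actually consume, making 100-seed power studies cheap.
Group-level checks in the tests run on a 16 × 16 × 8 grid with 120-frame
series, and seed-replication counts (100 seeds for detection and type-I
checks, 10 replicates for behavioral folds) were fixed as part of the
validation design.

What passing tests do and do not show: the generator's noise is additive
Gaussian, spatially independent, with no physiological confounds, no
registration error, and coupling planted exactly in the assumed form —
recovery here demonstrates the correctness of the estimators and the
internal consistency of the chain, not robustness to the artifacts of
real PET/MR data.

## The focal coupling mode and the perturbation study

The voxel-removal experiment asks whether a training effect in MCM is
carried by the CMRGlu pattern or by the FC pattern. Its generator
configuration (`couplingMode = "focal"`) restricts the cell-specific
coupling to the lowest-CMRGlu half of the target, with the remaining
voxels held at a constant background coupling in every cell. Because
those carrier voxels start from weak coupling, raising their coupling
strengthens the FC–CMRGlu spatial correlation (and the hard-task decrease
weakens it), so planted directions remain the same as in the uniform
mode. Removal then proceeds in 10% steps up to 90%, ordered by ascending
group-mean CMRGlu at the first scan, by ascending mean FC with the seed
cluster, or at random (MCM z-scores averaged over 500 seeded random
selections by default); the driver map is computed once at fraction 0 and
reused so reductions are nested, and ties break by ascending voxel index.
With the carriers in the lowest-value half, value-ordered removal
abolishes the group × time F by 50% removal while 90% random removal
preserves it — the qualitative signature the experiment is designed to
detect. The recomputed F is the condition-specific group × time model
(not a refit of the full three-factor model), a documented choice where
either reading is defensible.

# Degenerate inputs and numerical conventions

Voxel indexing is 0-based x-fastest on disk and 1-based in R; affines are
carried through I/O but never used to resample — all stages require a
shared grid and refuse mismatches. Patlak requires positive plasma
activity and at least 3 frames after $t^*$; MCM requires at least 4
target voxels; reductions must leave at least 4; scrubbing must leave at
least 20 frames for cleaning. Degenerate statistical inputs (constant
values, zero-variance differences) resolve to exact limits (F = 0 or
infinite t) rather than NaN. All randomness in the package flows through
explicit seeds; fixed seeds give bit-identical studies, manifests and
perturbation curves.

# Known limitations

No registration, spatial normalization, attenuation or decay correction,
partial-volume or multi-delay ASL modeling, physiological noise, or
random-field-theory inference. The ANOVA omits sphericity corrections.
The conjunction uses externally supplied thresholds rather than
voxel-level FWE. These are outside the package's scope by design.
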