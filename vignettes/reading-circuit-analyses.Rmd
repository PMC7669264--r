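---
title: "Dissecting group hypoactivation in the developing reading circuit: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting group hypoactivation in the developing reading circuit: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Children who struggle to read show weaker fMRI responses to written words
than typical readers in a left-lateralised circuit — most reproducibly the
left occipito-temporal fusiform cortex (the visual word-form area, VWFA),
the superior temporal cortex, the precentral gyrus and, at least in Chinese
readers, the left middle frontal gyrus. A group-level reduction in mean
activation is, however, ambiguous between at least three generative
accounts:

1. **Reduced amplitude** — each poor reader activates the same site, at the
   same place, with the same run-to-run stability, but less strongly.
2. **Spatial dispersion** — each poor reader has a normal, well-organised
   response, but its anatomical location varies more across individuals,
   so voxelwise group averages are diluted.
3. **Pattern instability** — the multivoxel response pattern itself is
   unreliable from one run to the next, so there is no stable individual
   circuit to average.

The package implements the analysis battery that separates these accounts —
literature-driven sphere-ROI univariate ANOVAs with Bayes-factor
complements, individual activation-peak analysis, split-run multivoxel
pattern (MVPA) reliability, and anterior-posterior response-gradient
profiles — together with a synthetic cohort generator in which each account
can be switched on selectively, so that every claim of the form "analysis X
detects pathology Y and is blind to Z" is an executable, falsifiable
statement.

## The synthetic cohort

### Design

A cohort mirrors a two-language (Chinese, French), two-reading-ability
(typical, poor) design with 24 subjects per cell, two fMRI runs and three
visual categories (words, faces, houses) presented against fixation. For
every subject × run × condition the generator produces a beta volume, an
analytic standard-error volume, and t = beta / se, on a 3 mm isotropic grid
(the acquisition resolution). The default whole-brain bounding box is
[−78, 78] × [−112, 76] × [−70, 85] mm (53 × 63 × 52 voxels); repeated-cohort
simulation studies use a reduced 32³ grid covering the left ventral
occipito-temporal territory where all the blobs and ROIs of interest live.

### Signal model

Category-selective activation is a sum of Gaussian blobs. Words activate
the left fusiform (peak amplitude 1.0 arbitrary units, at −48 −57 −15) and
the left superior temporal cortex (0.8, at −57 −30 3); faces activate
bilateral fusiform (FFA) sites and houses bilateral medial fusiform sites.
The blob spatial sd is 5 mm, chosen so that a blob's full width at half
maximum (~12 mm) matches the extent of smoothed category-selective
activations in pediatric group maps; it was fixed before any calibration
runs and not revisited.

Per subject, each blob's amplitude is drawn from
Normal(base × group multiplier, τ²) with τ = 0.2, and its centre is
displaced by an isotropic Normal(0, jitter²I) jitter. The run-r signal is

    S_r = ρ · S + sqrt(1 − ρ²) · S ⊙ Z_r ,

where S is the subject's blob field, Z_r is white standard-normal noise and
⊙ is voxelwise multiplication: the run-specific component is proportional
to the local signal envelope, so instability degrades exactly where there
is signal to degrade. Two consequences are worth stating explicitly.
First, pattern correlations between runs inside a blob approach ρ² as
measurement noise vanishes, and the empirical within-category correlation
increases monotonically in ρ (a tested invariant). Second, the expected
run signal is ρ·S, so low reliability also lowers expected amplitude — in
the instability scenario, poor readers show both unstable patterns and
reduced mean activation. This mirrors the empirical situation (groups with
unreliable word patterns also show univariate hypoactivation) and is a
direct consequence of taking the mixing equation literally; the scenario
dissociation therefore keys instability to the MVPA interaction, which the
amplitude scenario leaves (nearly) silent, rather than to the univariate
effect.

Measurement noise is additive Gaussian (sd 0.5) smoothed to 6 mm FWHM with
an edge-renormalised separable kernel; the standard-error volume is the
analytic post-smoothing noise sd map, identical across subjects.

Reading z-scores couple to the subject's principal word-blob amplitude with
correlation α = 0.6 inside each group, then are shifted and scaled to
group profiles (typical ≈ +0.7, poor ≈ −1.7 Chinese / −2.2 French, sds
0.46–0.85) matching the published group confidence intervals at n = 24.
Sex ratios (13M/11F typical, 16M/8F poor) and ages (≈123 ± 10 months) are
fixed to the study profile. An option marks a configurable number of
French subjects as single-run, exercising the MVPA run-count exclusion.

Randomness is organised as one master seed plus per-subject substreams
derived by a counter scheme, so subject k's data are unchanged when the
cohort grows and whole cohorts are byte-reproducible (a tested invariant;
NIfTI payloads written twice are compared by checksum).

### Scenario presets

| scenario    | amplitude multiplier (poor) | jitter sd (poor) | ρ (poor) |
|-------------|------------------------------|------------------|----------|
| null        | 1.0                          | 2 mm             | 0.8      |
| amplitude   | 0.6                          | 2 mm             | 0.8      |
| dispersion  | 1.0                          | 6 mm             | 0.8      |
| instability | 1.0                          | 2 mm             | 0.2      |
| mixed       | 0.8                          | 4 mm             | 0.5      |

Typical readers always keep the baseline column (multiplier 1, jitter 2 mm,
ρ = 0.8). Manipulations apply to the word condition only; faces and houses
always run at baseline, so face-pattern analyses act as a within-cohort
negative control — as in the empirical triple interaction where instability
was specific to words.

## Analysis stages

**ROI library.** Literature ROIs are built by averaging meta-analytic foci
per region into a single centre and drawing a 6 mm sphere (9 mm for pattern
analyses, 12 mm for peak searches). The packaged foci table
(`foci_synthetic.tsv`) is a constructed stand-in with the documented
structure — 10 alphabetic-dyslexia regions plus 3 Chinese-reading regions,
with region labels (FFG, MFG, STS, PCG, SPL, pSTG, …) and plausible MNI
loci — because the exact published foci lists are not redistributable here;
users can supply their own TSV with the same columns. The bilateral FFA
ROIs are fixed spheres at (±39, −45, −18), not foci-averaged.

**Univariate stage.** Mean run-averaged betas per sphere enter a 2 × 2
language × reading-ability ANOVA per ROI, with Benjamini–Hochberg FDR
across ROIs within each effect, plus Pearson correlations between ROI
activation and reading scores.

**Bayesian stage.** Main effects and the interaction get BIC-approximate
Bayes factors (BF10 = exp(ΔBIC/2), labelled `bic_approx`): the exact
default mixture-of-g ANOVA prior of common Bayesian ANOVA software is
deliberately not reimplemented, and the approximation preserves the
qualitative support-for-the-null calls that matter here. Two-sample
comparisons use the exact JZS Bayes factor: a Cauchy(0, 0.707) prior on the
standardised effect, integrated against the noncentral-t likelihood by
adaptive quadrature (with a Cauchy-quantile trapezoid fallback when nearly
all prior mass sits against a directional restriction). Directional
alternatives (typical > poor; Chinese > French) use the half-Cauchy.
Sensitivity curves recompute BF10 over widths 0.1–1.5; the curve is called
"stable" when max/min BF10 < 10 — one order of magnitude, our
operationalisation of a Bayes factor that "stays about the same".

**Group maps.** Voxelwise one-sample, two-sample and covariate-correlation
t maps; cluster forming at voxel p < 0.001; cluster-level inference by the
permutation null of the maximum cluster size (sign flips for one-sample,
label permutations for two-sample, covariate permutation for correlation),
with corrected p = (1 + #{perm max ≥ observed}) / (1 + n_perm). This
replaces random-field-theory FWE: at these sample sizes and grids the
permutation null is exact under exchangeability and needs no smoothness
estimate. Peak "Z values" are standard-normal quantiles of the t CDF.

**Individual peaks.** Within a 12 mm sphere around the group
[words > faces+houses] peak, voxels with t ≥ 1 are candidates; the 10
strongest by t are selected (ties at the kth rank broken by ascending voxel
index; ranking by beta is available behind a flag); the unweighted centre
of mass of their coordinates gives the subject's distance to the group
peak, and the mean of their betas the subject's peak activation. Subjects
with zero candidates are flagged and excluded pairwise per ROI.

**MVPA reliability.** 9 mm ROI spheres are intersected with the group
preference mask ([words > faces+houses] for word ROIs, faces-preference
for FFA); intersections under 5 voxels exclude the ROI by name —
correlations over fewer voxels are too unstable to interpret. Per subject,
the run-1 pattern of the family's category is correlated with the run-2
pattern of each category; the between-category score is the mean of the
three Fisher-z values (words–faces, words–houses, faces–houses — the
faces–houses pair is included deliberately, mirroring the published
definition despite its asymmetry; z-transform before averaging). Subjects
with one run are excluded; with more than two runs the first two are used.
The condition (within vs between) × language × reading-ability mixed ANOVA
runs per ROI, and the fusiform word and face records combine into the
triple category × condition × reading-ability design.

**Gradient stage.** Six 6 mm spheres at y = −73 … −28 (9 mm spacing),
z = −16, |x| = 48/39/30 for words/faces/houses, per hemisphere. Sphere
means per subject enter the 2 × 2 × 6 × 2 mixed ANOVA; per-position
typical-vs-poor Welch contrasts are FDR-corrected across the six
positions. Note that with the inclusive sphere boundary (below), adjacent
chain spheres share the two boundary voxels lying on the chain axis.

## Statistical core

The mixed-design ANOVA is implemented from its definitions: within-subject
responses are projected onto orthonormal (normalised Helmert) contrast
bases per within-effect stratum, and each stratum is analysed as a
between-subjects decomposition — between effects against subjects-within-
groups, within effects and their interactions against the matching
effect × subject(group) term. On balanced designs this reproduces the
classical sums of squares exactly (tested to 1e-10 relative against an
independent decomposition on random designs). Unbalanced between cells —
which arise when single-run subjects drop out of the MVPA — use the
classical unweighted-means solution (harmonic mean cell size) with a
warning; denominator dfs remain N − g, so an 87-subject, 4-group, 2-level
within design tests within effects on 83 df. No sphericity correction is
applied by default (all within factors here have few levels; a
Greenhouse–Geisser option exists). Pearson correlations, the Fisher
r-to-z transform (inputs clipped at ±(1 − 1e-7) so identical patterns map
to a large finite z) and Benjamini–Hochberg step-up FDR are likewise
implemented from their definitions and tested against independent oracles.

Post-hoc two-group contrasts use Welch's t test — the original analysis
does not name its post-hoc method, and Welch is the conservative default
for possibly heteroscedastic cells.

## Numerical and design choices

- **Sphere membership** is inclusive (centre distance ≤ radius, with a
  1e-7 mm guard against floating-point exclusion of exact-boundary
  voxels): deterministic and matching the common neuroimaging convention.
- **Cluster connectivity** defaults to 18 (face+edge), the convention of
  the major SPM-family packages; 6 and 26 are available.
- **Ties** are always broken by ascending voxel linear index (group peaks,
  top-k selection, cluster ordering after size and peak value), making
  every map-level result deterministic.
- **Degenerate inputs**: zero-variance voxels get t = 0 (or a documented
  1e6 cap for a one-sample test of a nonzero constant) and are flagged;
  ANOVA sums of squares below 1e-12 of the response energy are treated as
  exact zeros so that constant data yield F = 0 rather than 0/0.
- **Smoothing** uses an edge-renormalised truncated-Gaussian separable
  kernel (weights rescaled to sum to one inside the grid), so constant
  fields are preserved and no signal leaks out of the volume.
- **Monte-Carlo problem sizes.** The calibration suite runs 350 null
  cohorts (ROI ANOVA type-I error) and 140 cohorts (cluster-correction
  family-wise error, 100 permutations each) on the reduced 32³ grid; the
  scenario-dissociation suite runs 75 cohorts per scenario (100 for the
  instability scenario, whose face-ROI null bound is the tightest) at the
  full n = 24/group. These sizes give Monte-Carlo standard errors of
  about one percentage point on a 5% rate and three to four points on an
  80–95% rate, adequate for the detection bands being checked, while
  keeping the whole suite tractable on one CPU. The acceptance script
  reruns the same studies at 200/100/50 cohorts, and the analysis drivers
  print a 20-cohort version of the dissociation table for quick
  inspection.

## What the simulations do and do not show

The generator reproduces the *logical structure* of the study — balanced
groups, two runs, three categories, literature ROIs over real coordinates,
reading scores with realistic group separations — but not the physics of
fMRI: no haemodynamic model, no motion or physiological artefacts, no
spatially correlated anatomy-dependent noise, no inter-subject anatomical
variability beyond blob jitter. Passing calibration and dissociation
suites therefore shows that the *analysis code* is correct and that the
inferential logic is sound under the stated generative model; it does not
validate the model against real data.

Three structural couplings deserve emphasis because they qualify the clean
three-way dissociation:

1. **Dispersion partially lowers peak amplitude.** With a 6 mm per-axis
   jitter, a subject's blob centre lies outside the 12 mm search sphere
   about a quarter of the time (the displacement magnitude is ~1.6 × 6 mm
   on average), and the selected top-10 voxels then sample the blob's
   flank — so the mean selected beta drops by some 20% at the group level
   and the peak-amplitude test fires under pure dispersion at these
   settings. Peak analysis as specified therefore rescues amplitude only
   against *moderate* dispersion (jitter small relative to the search
   radius); under strong dispersion the distance measure is the
   discriminating signal, while the amplitude measure is confounded. The
   dissociation suite reports both rates honestly rather than forcing the
   idealised pattern.
2. **Instability lowers expected amplitude** (by the factor ρ), as
   discussed above.
3. **Reduced amplitude mildly destabilises *measured* patterns.** The
   pattern correlation between runs is attenuated by measurement noise in
   proportion to noise-to-signal spatial variance; scaling a group's
   amplitude by 0.6 raises that ratio for the group even though its true
   pattern reliability ρ is untouched, so the MVPA condition × group
   interaction fires somewhat above its nominal rate under the pure
   amplitude scenario (around one cohort in five at these settings, versus
   near-ceiling under true instability). A real analysis faces exactly the
   same confound; the dissociation remains interpretable because the
   effect is an order of magnitude weaker than under genuine instability.

Other limitations: the BIC Bayes factors approximate, rather than
reproduce, default-prior ANOVA Bayes factors; the preference mask used for
MVPA is computed from the analysed cohort itself (the published procedure),
a mild circularity we keep deliberately; and inside Monte-Carlo loops the
preference mask uses the voxelwise threshold without cluster-level
correction to avoid nesting a permutation test inside every simulated
cohort — with the strong blobs simulated here the two masks are nearly
identical.

## Reproducibility

Every stage is a pure function of (inputs, configuration, seed):
`run_full_analysis()` writes provenance-stamped tables whose checksums are
identical across reruns, and the acceptance script
(`scripts/acceptance.R`) recomputes the calibration and dissociation
quantities from scratch for any seed.
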