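---
title: "Quantifying protein interactions by acceptor photobleaching: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein interactions by acceptor photobleaching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretab)
```

# Scope

`fretab` packages the quantitative analyses used to characterize a
nuclear protein-protein interaction by cell microscopy and structure
prediction: FRET acceptor-photobleaching efficiencies with quality
control and normalization, Pearson co-localization with intensity line
profiles, confidence scoring of predicted complexes (interface PAE
means, pLDDT tracks, van der Waals contacts), sequence-feature analysis
(IDR consensus calling, alignment conservation, Das–Pappu charge
classification), and exact nonparametric statistics. A synthetic
microscopy generator with known ground truth drives every stage, so the
full pipeline is testable without any external data.

# The FRET acceptor-photobleaching model

FRET (Förster resonance energy transfer) quenches a donor fluorophore
when an acceptor sits within roughly 10 nm, so it reports direct
molecular proximity. In acceptor photobleaching, the acceptor (eYFP) is
destroyed by intense illumination and the interaction is read out as
donor (eCFP) *de-quenching*: the donor gets brighter where transfer was
occurring. The efficiency estimator is

$$\mathrm{FRET}_{\mathrm{eff}} = \frac{D_{post} - D_{pre}}{D_{post}},$$

the fractional donor recovery. Bleaching is rarely complete, so the
simulator models a bleach fraction $B$: with true efficiency $E$, the
expected intensities inside the bleached region are

$$D_{pre} = D_0 (1 - E), \qquad
  D_{post} = D_0 \bigl(1 - E (1 - B)\bigr), \qquad
  A_{post} = A_{pre} (1 - B),$$

and the estimator returns the *apparent* efficiency

$$E_{app} = \frac{E B}{1 - E (1 - B)},$$

which collapses to $E$ at complete bleach ($B = 1$). This closed form is
the package's primary correctness oracle: on noiseless synthetic
acquisitions the pipeline must reproduce it to within $10^{-9}$ (in
practice it agrees to machine precision).

Sensitized emission and acceptor cross-excitation are deliberately not
simulated: the donor-based estimator does not correct for them, and a
generator that injected effects the estimator cannot see would make
ground-truth recovery impossible to interpret. For the same reason
bleaching is uniform within the bleached region and only the end state
after the bleach pulses is generated, not the bleaching kinetics.

## Per-cell protocol

One cell contributes four registered images (donor/acceptor, pre/post).
The quantification follows the acquisition protocol:

1. up to six measurement ROIs inside the bleached area are averaged —
   using several small ROIs rather than the whole region excludes
   cellular structure;
2. each ROI must exceed **60 % bleach efficiency**
   ($B_{\mathrm{eff}} = (1 - A_{post}/A_{pre}) \cdot 100$, strict
   inequality) to be used;
3. the efficiency of an unbleached reference region at least **3 µm**
   from the bleached area (edge-to-edge, enforced at panel construction)
   is subtracted from the QC-passing mean — this removes imaging drifts
   common to the whole nucleus;
4. per-cell corrected efficiencies are optionally normalized by the mean
   of a positive-control condition (a tandem donor–acceptor fusion), so
   conditions are reported on a 0–1 scale.

Six ROIs are treated as a maximum, not a requirement: cells with fewer
QC-passing ROIs are kept and `n_rois_used` is reported, while cells with
none are flagged unreportable rather than dropped silently. Negative
corrected efficiencies are preserved — the reference subtraction can
legitimately produce them, and clamping would bias negative controls
upward. The unbleached reference is a single region scored with the
identical estimator; no further background subtraction is applied.

## Synthetic-data conditions

The generator's defaults define the simulated study conditions and are
fixed once:

| parameter | default | meaning |
|---|---|---|
| `D0`, `A0` | 1000 counts | mean donor/acceptor signal per pixel |
| `background` | 20 counts | constant offset |
| `read_noise_sd` | 3 counts | Gaussian detector noise |
| `B_true` | 0.9 | acceptor bleach fraction |
| image | 128 × 128 px, 0.1 µm/px | one nucleus per image |
| ROIs | 6 circles, r = 3 px | on a hexagon inside the bleached circle |
| unbleached ROI | r = 8 px, 3.7 µm away | large, to keep the reference quiet |
| positive control | $E = 0.30$ | tandem-construct efficiency |

Photon budgets and detector settings are not stated by any acquisition
protocol at this level of detail; the values above are typical of fixed
cells on a confocal system at 16-bit depth and are documented here as
package choices. The unbleached reference is deliberately larger than
the measurement ROIs because its noise enters every cell's corrected
efficiency once and undiluted.

Noise is Poisson shot noise on the expected counts, then additive
Gaussian read noise, then the constant background. Images are kept as
floating-point expectations in memory; quantization to 16-bit unsigned
(with saturation clipping) happens only when writing TIFFs, so the
closed-form identity holds exactly in memory and integer counts
round-trip exactly through files. One top-level seed drives
deterministic per-channel sub-streams; identical seeds give
bit-identical images, and the caller's RNG state is never disturbed.

What the generator does *not* emulate — point-spread-function blur,
focus drift, spectral bleed-through, cell-to-cell expression variation,
partial co-transfection — limits what a passing test shows about real
data: recovery of ground truth here demonstrates that the estimator,
QC, correction and normalization are implemented correctly, not that
they are robust to optical artifacts the model excludes.

## Scenario presets and statistical design

`fret_scenario()` mirrors the study designs: `binary` (interacting pair
vs negative and tandem positive control), `competition` (the pair with
and without a competing third partner, generated at a 16 % relative
reduction in true efficiency), and `variant` (wildtype vs two
reduced-efficiency pathogenic variants). At the default photon budget
the competition effect is recovered within a couple of percentage
points and flagged significant with 12 cells per condition.

Conditions are compared with the Wilcoxon signed-rank test, keeping
faith with the source protocol, although cells of two conditions are
independent samples rather than natural pairs. With equal group sizes
the samples are paired by rank order (a deterministic, documented
choice recorded in every result); the unpaired rank-sum test is offered
as the statistically cleaner alternative (`test = "rank-sum"`) and is
recommended when group sizes differ. The unit of replication defaults
to the cell. For $n \le 25$ nonzero differences the two-sided p value
is exact — computed from the full sign-assignment distribution by
dynamic programming (ties handled by average ranks, doubled to stay on
an integer lattice); larger samples use the tie-corrected normal
approximation with continuity correction. Stars follow the inclusive
bands * $p \le 0.05$, ** $p \le 0.009$, *** $p \le 0.0009$. No
multiple-testing correction is applied across condition pairs, matching
the source analysis. Boxplot summaries use type-7 (linear
interpolation) quartiles and Tukey 1.5 · IQR whiskers so every printed
statistic is deterministic.

# Co-localization

The Pearson coefficient is computed over all pixels of a supplied mask
(typically the whole nucleus) with no Costes thresholding — plain
correlation is what the corresponding microscopy analysis reports, and
thresholding would change the quantity. Masks are accepted as inputs
only; the package does not segment nuclei. Intensity profiles sample
channels by bilinear interpolation along a polyline at a default step of
1 px (an undocumented detail in the original plots, fixed here as a
choice), with distances reported in µm. The co-localization simulator
draws correlated Gaussian fields inside the nucleus and maps them
affinely to intensities, so the realized correlation converges to the
target; photon noise is intentionally absent because it would attenuate
the correlation below the documented ground truth.

# Structure-prediction confidence

**PAE region means.** A predicted aligned error matrix is read from
either standard JSON dialect (nested matrix or flat
`residue1`/`residue2`/`distance` arrays — both must load to the
identical matrix) with chain ranges that partition the residue axis.
The interface score is the arithmetic mean of one rectangular block
(rows from one interval, columns from the other) — a "PAE plot area" is
one rectangle; averaging both off-diagonal rectangles is available as
an opt-in `symmetric` mode since the matrix is generally asymmetric.
Intervals are 1-based inclusive in chain-local coordinates, matching
the "aa 128–173" style used for domain boundaries.

**pLDDT.** Predicted models carry per-residue confidence in the
B-factor column; one value per residue is taken from the CA atom
(first atom for non-polymer residues). Numbering gaps are reported, not
interpolated.

**Contacts.** Two atoms are in contact when their van der Waals overlap
$r_i + r_j - d_{ij}$ is at least the cutoff, default $-0.4$ Å —
the conventional "contact" criterion (a mild negative overlap) as
opposed to a clash. The boundary is inclusive: a pair at overlap
exactly $-0.4$ Å counts, with a $10^{-9}$ Å numerical guard so exact
boundary geometries are not lost to floating point. The hydrogen-bond
allowance is 0 Å in contact mode. Pairs within one residue and
covalently bonded pairs (non-hydrogen atoms closer than 1.9 Å) are
excluded. Candidate pairs come from a cubic cell list whose edge equals
the largest possible contact distance, which is exact — it must and
does agree pair-for-pair with exhaustive search, which the tests verify
directly. Radii are the Bondi (1964) element table shipped as data and
overridable by CSV. Interface residues are reported as sorted unique
contacting residues per chain plus the minimal covering interval.

# Sequence features

**IDR consensus.** A residue is disordered when its disorder score is
strictly above 0.5 **or** its pLDDT is strictly below 50; values exactly
at the thresholds are not flagged. Runs of at least `min_len = 5`
flagged residues become segments: the source rule is stated per residue
with no smoothing, and a minimal run length suppresses single-residue
flips while remaining far below domain scale; it is configurable.

**Conservation.** The original analysis displayed an alignment viewer's
conservation track whose metric is not defined anywhere citable. The
package therefore uses a transparent stand-in: after dropping columns
where the reference sequence has a gap (so profile coordinates equal
reference residue numbers), each column scores the fraction of its
non-gap residues in the column's majority physicochemical class
(hydrophobic AVLIMFWYC, positive KRH, negative DE, polar STNQ, special
GP), with plain identity fraction as an option. The default threshold
of 0.8 is likewise a package choice — the threshold line in the source
figure carries no printed value. Profiles computed this way are
comparable to the original qualitatively, not numerically.

**Charge states.** Fractions of positive (K, R) and negative (D, E)
residues — histidine neutral at physiological pH — give FCR and NCPR
and a Das–Pappu diagram-of-states region. The region boundaries follow
the published classifier: R1 ($f_+ < 0.25$, $f_- < 0.25$), R2
(otherwise $f_+ \le 0.35$, $f_- \le 0.35$; the "Janus" boundary region
whose conformation depends on context), R3 (both $> 0.35$), R4/R5
(one-sided strong polyelectrolytes). These five predicates tile the
$(f_+, f_-)$ simplex exclusively, which the tests verify by
enumeration at 0.01 resolution.

# Numerical and degenerate-input policy

* Empty ROI masks, zero-variance channels, all-zero difference vectors,
  missing control conditions, non-square PAE matrices, unknown
  elements, and out-of-bounds intervals are hard errors with specific
  messages — never silent NA propagation.
* A cell whose ROIs all fail QC is a flagged unreportable row; a batch
  never aborts because one cell failed.
* The distance rule for the unbleached reference (≥ 3 µm edge-to-edge,
  computed from pixel centers and the physical pixel size) is enforced
  when a panel is constructed, not deep in the math.
* All 1-based inclusive interval conventions (residues, segments) are
  uniform across modules; serialized ROI coordinates are 0-based, which
  the sidecar reader and writer both honor.

# Problem sizes used in the shipped simulation studies

The test suite and the acceptance script run: a 12-point noiseless
$E \times B$ grid; 25 replicate experiments of five conditions × 3
cells (18 ROIs per condition) for stochastic recovery; 500 randomized
panels against the aggregation oracle; 100 random 500-atom sets against
the all-pairs contact oracle; 1000 random track pairs for the IDR rule;
the full 0.01-resolution charge simplex; 2000 null replicates for
signed-rank calibration; and 50 seeds for correlation recovery. These
sizes give stable estimates (the stochastic recovery MAE is ≈ 0.009
against a 0.02 requirement) while keeping a full run in well under a
minute of compute.

# Known limitations

* The estimator inherits the protocol's assumptions: no bleed-through
  or cross-excitation correction, no drift registration, no donor
  bleaching during the acceptor bleach.
* The conservation metric and threshold are stand-ins (see above).
* Whether the original unbleached reference was one region or an
  average of several is unstated; one region is assumed.
* The signed-rank test's pairing of independent cell populations is a
  faithfulness choice, not a statistical recommendation; use
  `rank-sum` for new designs.
* `interface_residues` reports contact-derived residues only; it does
  not classify interaction types (hydrophobic, polar, ...).
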