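# fretab

Quantification of protein–protein interactions in cells by **FRET
acceptor photobleaching**, with the surrounding analyses used to
characterize a nuclear interaction: co-localization metrics,
structure-prediction confidence scores, sequence-feature analysis, and
nonparametric statistics. A synthetic-microscopy generator with known
ground truth exercises the entire pipeline, so everything is testable
without downloading a single image or model.

## Who this is for

Cell biologists and image analysts quantifying binary interactions with
the eCFP/eYFP acceptor-photobleaching protocol on a confocal microscope,
and anyone scoring AlphaFold-style complex predictions (PAE interfaces,
pLDDT, van der Waals contacts) or profiling disordered, conserved, or
charged sequence regions alongside such experiments.

## The core quantities

FRET quenches the donor while the acceptor is intact; destroying the
acceptor de-quenches the donor. Per region of interest:

- **FRET efficiency** — FRET_eff = (D_post − D_pre) / D_post
- **Bleach efficiency** — Bleach_eff = (1 − A_post / A_pre) · 100, with a
  strict **> 60 %** quality-control gate
- **Per cell** — mean of up to six QC-passing ROI efficiencies inside the
  bleached area, minus the efficiency of an unbleached reference region
  ≥ 3 µm away; optionally normalized by a tandem donor–acceptor
  positive-control condition
- At partial bleach fraction B the estimator recovers the apparent
  efficiency E·B / (1 − E(1 − B)), the closed form the synthetic
  generator is validated against

Also implemented: Pearson co-localization over a mask and bilinear
intensity line profiles; PAE region means over interface blocks (1-based
inclusive intervals, both standard JSON dialects); per-residue pLDDT
extraction; van der Waals contact detection (overlap ≥ −0.4 Å,
cell-list accelerated, exact); IDR consensus calling (disorder > 0.5 OR
pLDDT < 50); MSA conservation profiling anchored to a reference
sequence; Das–Pappu FCR/NCPR charge classification; exact Wilcoxon
signed-rank tests with significance stars (* p ≤ 0.05, ** p ≤ 0.009,
*** p ≤ 0.0009) and Tukey boxplot summaries.

## Worked example

Simulate a competition experiment — an interacting pair with and without
a competing third partner (generated at a 16 % lower true efficiency) —
then quantify, normalize and test:

```r
library(fretab)

dataset <- simulate_fret_experiment(
  fret_scenario("competition", E_pair = 0.3), n_cells = 6L, seed = 42)
out <- run_fret_pipeline(dataset, control_label = "positive_control",
                         comparisons = list(c("pair", "pair_with_competitor")))

out$summary[, c("condition", "n", "mean", "median", "q1", "q3")]
#>              condition n  mean median    q1    q3
#> 1                 pair 6 1.004  0.998 0.998 1.010
#> 2 pair_with_competitor 6 0.823  0.819 0.813 0.834
#> 3     positive_control 6 1.000  0.996 0.991 1.009

out$stats[, c("condition_a", "condition_b", "test", "n_a", "W", "p_value", "stars")]
#>   condition_a          condition_b                 test n_a  W p_value stars
#> 1        pair pair_with_competitor wilcoxon-signed-rank   6 21  0.0312     *
```

The pair condition normalizes to ≈ 1.0 (it was generated at the
positive-control efficiency), the competitor condition drops to ≈ 0.82 —
recovering the simulated ~16 % reduction — and the signed-rank test
flags the difference at the `*` band. `out$cells` holds the per-cell
table (corrected efficiency, number of QC-passing ROIs, reportability).

Everything is also drivable from a YAML configuration with a provenance
record (`run_config()`), and acquisitions round-trip to 16-bit TIFFs
with JSON ROI sidecars (`write_fret_dataset()` / `load_fret_dataset()`).

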