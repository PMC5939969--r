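---
title: "Isoelectric point estimation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoelectric point estimation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampholyte)
```

## The model

A denatured peptide or protein is treated as a collection of independent
ionizable groups: the free alpha-amino and alpha-carboxyl termini, the
sidechains of C, D, E, H, K, R and Y, and any modification-derived groups.
Each group is characterized by one acid-dissociation constant (pKa) and a
polarity. The net charge at pH $x$ is the Henderson–Hasselbalch sum

$$
Q(x) \;=\; \sum_{\text{bases } b} \frac{1}{1 + 10^{\,x - pK_b}}
\;-\; \sum_{\text{acids } a} \frac{1}{1 + 10^{\,pK_a - x}},
$$

a continuous, strictly decreasing function of $x$ whenever at least one
group exists. The isoelectric point (pI) is the root $Q(x) = 0$, which
exists precisely when groups of both polarities are present. Sequences with
a single polarity (for instance an N-terminally acetylated peptide with no
basic sidechain) have no pI; the solvers raise a typed
`no_isoelectric_point` error rather than report a clamped boundary value,
because a silently clamped 0 or 14 would poison downstream benchmark
statistics.

The model deliberately ignores structural context: no disulfides, no
temperature or ionic-strength dependence, no activity corrections. These are
the standard assumptions for sequence-only pI estimation of denatured
chains.

### Limits of the titration function

As $x$ falls far below every pKa, $Q(x)$ approaches the number of basic
groups; far above every pKa it approaches minus the number of acidic
groups. Each group converges to its plateau at rate $10^{-d}$, where $d$ is
the pH distance to its pKa. The limit checks in the test suite therefore
evaluate $Q$ at `min(pKa) - 4` and `max(pKa) + 4`, where every group is
within $10^{-4}$ of its plateau; evaluating exactly at pH 0 or 14 would
confound the limit with the tail of whichever group happens to sit closest
to the boundary (a phosphate group at pKa 1.2 still carries 6% of a charge
at pH 0). The sum is well defined at any finite pH, so this is a statement
about where the limit has converged, not an extension of the model.

## Method families

All five families of the toolkit share the net-charge core; they differ
only in how the group pKas are assigned.

* **Iterative** (`solve_pi()`): pKas taken verbatim from one of the
  interchangeable basis sets. The root is found by bisection on
  $[0, 14]$ — the pKa bounds guarantee a bracketing sign change whenever a
  pI exists. Bisection was chosen over Newton or secant steps because the
  charge curve can be extremely flat between well-separated pKas and
  guaranteed convergence matters more than iteration count at this scale.
* **Bjellqvist terminal variants** (`solve_pi_bjellqvist()`): the terminal
  pKas depend on the identity of the first and last residue, and sidechain
  pKas may carry positional overrides (n-terminal / c-terminal / internal
  context). The algorithm is a single code path; the four shipped variants
  (`default`, `expasy`, `calibrated`, `skoog`) are pure data layered over
  the `bjellqvist` base set, so swapping or editing a variant requires no
  code change.
* **Cofactor** (`solve_pi_cofactor()`): additive pKa shifts applied once,
  before solving, to the carboxyl groups only (Asp/Glu sidechains and the
  C-terminus), summed over neighboring residues at signed offsets within
  ±3. Offsets are signed because N-side and C-side neighbors may differ; a
  table may of course ship symmetric entries.
* **Branca** (`solve_pi_branca()`): shifts from ionizable neighbors up to
  six residues away, each multiplied by that neighbor's *charged fraction*
  (the absolute value of its fractional charge — the only reading that
  yields a multiplier in $[0,1]$) at the current pH estimate, plus an
  additive term indexed by the counts of Asp and Glu sidechains, applied to
  the Asp/Glu pKas. Because the weights depend on the answer, the method is
  solved as a fixed point: initialize at the uncorrected iterative pI,
  recompute weights and effective pKas, re-solve, and repeat until the
  estimate moves less than the solver tolerance. Updates are damped by 0.5
  when successive steps alternate in sign; the plain iteration converged in
  every observed case, and the damping is a guard, not a tuning knob. The
  method is defined only for sequences with a K or R C-terminal residue
  (tryptic peptides); anything else raises a typed `not_applicable` error
  that the benchmark layer counts rather than crashes on.
* **SVR** (`train_pi_svm()` / `predict()`): an epsilon-insensitive
  RBF-kernel support-vector regression over sequence-derived features. The
  module is a retrainable pipeline, not a frozen set of weights — the
  published weights of the original peptide SVR are not available, and the
  method's value is precisely that it can be refit to a particular
  analytical setting.

## Parameters that matter

* **pKa basis sets** (`load_builtin_sets()`): ten sets ship as editable CSV
  files (solomon, rodwell, lehninger, grimsley, patrickios, thurlkill,
  toseland, sillero, emboss, bjellqvist), each with a source citation,
  validated at load: every value in the open interval (0, 14), terminal
  entries mandatory, sidechain keys restricted to C, D, E, H, K, R, Y. A
  residue missing from a set is non-ionizable under that set — the
  patrickios set, for instance, omits C, H and Y entirely. This
  missing-means-neutral rule is a deliberate totality decision: the
  alternative of refusing to compute would make entire sets unusable.
* **Solver tolerance** (`solver_config()`, default `1e-4` pH): the bisection
  bracket width. Predictions are conventionally reported to 2 decimals, so
  the default sits two orders below reporting precision; tests that need to
  resolve strictly ordered shifts smaller than the default bracket (for
  example the removal of an amine that is already neutral near a basic pI)
  tighten it to `1e-9`, which costs ~15 further bisection steps.
* **Modification pKas** (`inst/extdata/modifications.csv`): a phospho site
  contributes two acid groups with default pKas 1.2 and 6.5. Phospho-Y
  shares the S/T defaults since no separate tyrosine values are
  established; the data file makes the choice overridable. N-terminal
  acetylation removes the alpha-amino group outright.
* **Correction tables**: the cofactor/branca ΔpKa constants and the
  carboxyl-count term ship as editable CSV defaults of plausible magnitude,
  marked externally sourced in their citation fields. Every algorithmic
  test runs on synthetic tables (zero, single-entry) so that correctness of
  the algorithms is independent of the provenance of any particular
  constant transcription.
* **SVR features** (`feature_spec()`): residue composition (20), length, a
  seed pI computed with the iterative method, sequence-mean property scales
  (Kyte–Doolittle hydropathy and monoisotopic residue mass ship as
  fixtures), and modification counts, in a fixed, versioned order; model
  files refuse to load across feature-spec versions. The seed pI is
  computed with the `bjellqvist` base set by default — of the classical
  bases it tracks peptide behavior best, and a strong seed feature is what
  lets the regression spend its capacity on the residual. Hyperparameters
  are selected by a small seeded grid search (cost × gamma) on a fixed
  80/20 validation split; the split, the search, and e1071's fit are all
  deterministic given the data order and seed, which is what makes
  same-seed retraining bit-reproducible.

## The benchmark layer

`run_grid()` evaluates a method × parameter grid against experimental
values, excluding failed predictions pairwise (and counting them), and
reports signed Pearson r, $r^2$, RMSD, and outlier counts per combination,
with per-record residual tables as list columns. Both the signed and the
squared correlation are carried because squared summaries silently hide
anticorrelation. The outlier rule flags a record when its absolute residual
meets or exceeds the sample standard deviation of the *predicted* values;
with constant predictions (SD zero) only strictly positive residuals flag,
so an exact constant fit reports none. Users who prefer a residual-SD rule
can apply one directly to the residual tables. `per_fraction_summary()`
reports per-fraction means, SDs (zero with a `single_record` annotation for
singleton fractions) and RMSDs, ordered by the fraction's experimental pI
midpoint.

## Synthetic data: what it emulates and what it does not

`simulate_peptides()` emulates an OFF-GEL-style experiment: random tryptic
sequences, ground truth from a chosen generating method, optional phospho
and N-terminal-acetyl subpopulations, Gaussian measurement noise, and a
fraction id from binning the measured pI into 15 equal-width bins over
pH 3–10 (values outside the gradient accumulate in the terminal bins, as
they do in a physical device). Residue composition is uniform by default —
the right choice for exercising code paths — with a bundled vertebrate-like
frequency table (`get_property_table("composition_vertebrate")`) for
distribution-shape work; uniform tryptic sequences almost never reach the
most acidic fractions, so occupancy questions are only meaningful under
the realistic composition. The default noise SD of 0.2 pH units reflects
the reproducibility of peptide IEF measurements; it is a fixture of the
generator, not a literature constant.

`simulate_proteins()` emulates a literature-collated protein pI table: a
rate-controlled subset of proteins carries two or more discordant
measurements drawn with a between-laboratory SD (default 1.0 pH unit,
reflecting the decade-spanning heterogeneity of published protein pI
values), and a small subset is forced to a wide focalization zone of at
least 3.5 pH units between its extreme measurements.

What passing tests on these simulations demonstrate is internal
consistency: that each solver computes the model it claims, that the
benchmark layer recovers known noise levels, and that the machinery
degrades gracefully. They do not demonstrate accuracy on real datasets —
real experimental pI values carry calibration offsets, mis-assignments,
unannotated modifications and protocol heterogeneity that no additive
Gaussian emulates.

## Numerical choices and degenerate inputs

* pH search domain fixed to $[0, 14]$; pKa validation bounds guarantee a
  sign change inside it whenever both polarities exist.
* Sequences are uppercased; the degenerate codes B, Z, X, U, O are accepted
  and treated as non-ionizable (they contribute nothing to charge, and zero
  weight to composition features, which renormalize over standard
  residues).
* Predictions are kept at full precision internally and rounded to 2
  decimals only at serialization (`write_predictions()`, overridable).
* Correlation over constant vectors is a typed error, never a silent zero.
* Problem sizes in the shipped tests — 200 peptides for solver/oracle
  agreement, 500 for the noise-free self-benchmark, 2000 for noise recovery
  and SVR training — were chosen as the smallest sizes at which the checked
  properties are statistically stable across seeds.

## Known limitations

* No structure-based pKa modeling; everything assumes denatured chains.
* The cofactor/branca correction constants are user-editable
  transcriptions, not fitted values; conclusions about those two methods'
  absolute accuracy require user-supplied constants from the primary
  literature.
* iTRAQ/TMT and other derivatization chemistries are out of scope; the
  modification model covers phosphorylation and N-terminal acetylation.
* The SVR ships untrained by design; `run_grid()` reports SVM rows as
  not-applicable until a trained model is passed.
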