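---
title: "Convergence of differences versus differences in convergence: methods and design notes"
author: "alecontrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergence of differences versus differences in convergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Coordinate-based meta-analysis aggregates the peak activation coordinates
("foci") that neuroimaging studies report in a standard space. When the
question is a *contrast* between two conditions A and B, there are two
routes to an answer:

* **CM** (contrast meta-analysis): run one ALE meta-analysis across
  experiments that each reported the contrast A > B at the experiment
  level. The result shows where *activation differences converge* across
  studies.
* **MC** (meta-analytic contrast): run two separate ALE meta-analyses of
  the main effects (A > baseline, B > baseline) and test voxel-wise where
  their convergence differs by permutation. The result shows where
  *convergence differs* between the two analyses.

These are conceptually different quantities, and `alecontrast` implements
both pipelines plus the voxel-, cluster- and peak-level similarity metrics
needed to compare their thresholded result maps. Because real coordinate
collections of this kind are typically not redistributable, the package
also ships a synthetic-data module that generates coordinate datasets with
known ground-truth convergence centres, so every stage — including the
statistical calibration of both permutation procedures — is testable end
to end.

## The ALE model

Each focus is modelled as the centre of an isotropic 3-D Gaussian whose
full width at half maximum combines two empirical uncertainty components:

$$\mathrm{FWHM}(n) = \sqrt{\mathrm{FWHM}_{subject}^2 / n +
\mathrm{FWHM}_{template}^2},$$

so that experiments with more participants (n) get denser kernels, with
the between-template term as a floor. The shipped defaults are the
literature-standard empirical values, 11.6 mm (between-participant, at
n = 1) and 5.7 mm (between-template); both are plain arguments of
`kernel_model()` and nothing in the package's tests depends on the
specific constants, only on the monotone behaviour of FWHM(n). Kernels
are truncated at the radius where the untruncated Gaussian falls below
1e-5 of its peak and renormalised to unit mass, which keeps the modeled
activation (MA) map construction linear in the number of foci.

Per experiment, the MA map assigns each voxel the *maximum* per-focus
kernel value (the non-additive max rule), so several nearby reported
peaks do not count more than one. Across experiments, ALE is the
voxel-wise union of probabilities:

$$\mathrm{ALE}(v) = 1 - \prod_i \bigl(1 - \mathrm{MA}_i(v)\bigr).$$

### The analytic null and its numerical construction

Under the null of random spatial association, each experiment contributes
an MA value drawn from its own in-mask MA histogram, independently of the
others. The null ALE distribution is built by the non-linear histogram
algorithm: histogram each experiment's in-mask MA values on a lattice of
width 1e-4 on [0, 1], then fold experiments in one at a time, depositing
the product of every pair of occupied bin masses at the bin of
$1-(1-a)(1-m)$.

Two numerical choices matter here:

* **Nearest-bin deposition.** Both the histogramming and the combination
  deposit at the nearest bin. Depositing at the floor bin instead would
  bias the null downward by up to one bin per step (roughly
  (E+1) × bin width in ALE units for E experiments); on toy instances
  this already misplaces survival probabilities by 0.02–0.03, which is
  why the construction is kept unbiased.
* **Conservative lookup.** `ale_to_p()` reads the survival function at
  the *floor* bin of the observed ALE score, so observed scores never
  borrow probability from finer-than-bin resolution; p-values are
  conservative at bin edges, never anticonservative. z-values are the
  standard-normal quantiles of 1 − p with p clamped to the null's own
  resolution (the smallest positive survival mass), so they are always
  finite.

The calibration of this construction is tested against an independent
Monte-Carlo oracle (sampling one in-mask MA value per experiment and
combining, 50,000 draws), with agreement required to 0.01 in survival
probability. That comparison is run on a 10³ lattice at **2 mm**: at 4 mm
a truncated kernel takes only ~10 distinct values, so toy MA
distributions are dominated by large atoms and the comparison would
measure atom placement rather than calibration; at 2 mm (the resolution
at which such analyses are typically run) the value set is rich and the
measured disagreement is ~0.005.

### Cluster-level FWE correction

The ALE map is thresholded at uncorrected p < 0.001 (the cluster-forming
threshold) and 26-connected components are formed — 26-connectivity is
the convention of the FSL cluster tooling and is used consistently for
clusters and local maxima throughout the package. For each of `n_perm`
permutations (default 10,000; the reduced scale used in tests and in the
analysis scripts is 1000), every focus of every experiment is relocated
to a uniformly random in-mask voxel, holding foci counts and sample sizes
constant, the ALE map is recomputed, thresholded identically, and the
maximum cluster size recorded. A real cluster is significant if its size
strictly exceeds the empirical 95th-percentile order statistic of that
null.

Because uniform relocation within the mask leaves the in-mask MA
histograms — and therefore the analytic null and the cluster-forming ALE
cutoff — unchanged, the cutoff is derived once from the real data and
reused across permutations; recomputing it per permutation would be
redundant work with an identical result.

One master seed drives the permutation stream; per-permutation child
seeds are derived deterministically from it, so results are reproducible
bit for bit.

**Discreteness caveat.** Cluster sizes are integers. At 4 mm, noise-only
maximum cluster sizes concentrate on very few values (2–4 voxels), the
strict ">" rule then undershoots the nominal level, and we measure a true
family-wise error rate of ~0.02 at a nominal 0.05. At 2 mm the size
distribution is fine-grained and the measured rate is 0.05. The package's
FWE calibration study therefore runs on a scaled-down 2 mm ellipsoid
(32×38×32 grid, ~16k in-mask voxels); the conservatism of coarse-lattice
cFWE is a property worth knowing, not a defect of the correction.

## The meta-analytic contrast

`contrast_permutation_test()` compares the observed voxel-wise difference
ALE(A) − ALE(B) to a pool–shuffle–split null: pool the experiments of
both conditions, shuffle, split into pseudo-groups of the original sizes,
and record the pseudo-difference, `n_perm` times. Whole experiments are
shuffled, never individual foci, so each experiment's foci count and
sample size travel together — this is what "exchangeability of
experiments" means here. The permutation p-value uses the add-one
correction p = (1 + #{perm ≥ obs}) / (1 + n_perm), so p is never zero. A
voxel is significant when p < α (default 0.05, i.e. the observed
difference beats more than 95% of the null), it lies in the main-effect
mask, and it survives a k = 5 extent filter on 26-connected components
(extent filtering applied after masking). The test is one-sided (A > B);
the reverse direction is a second call with the roles swapped.

Design choices the underlying procedure leaves open, and what this
package does:

* **Main-effect mask.** Inclusive masking "by the respective main
  effect" does not pin down a threshold. Default: the condition of
  interest's *uncorrected* p < 0.001 map; the cluster-level corrected map
  is available via `mask_type = "cfwe"`. The mask provenance is echoed in
  every output manifest so it is never ambiguous which mask was used.
* **Tie rule at α.** Significance requires p strictly below α; with the
  add-one correction this means the observed difference must beat at
  least ⌈(1−α)(n_perm+1)⌉ permutations.

**Sparse-coverage conservatism.** At a voxel covered by m of the pooled
experiments (an experiment "covers" a voxel when its MA value there is
non-zero), the permutation distribution of the difference has at most as
many atoms as there are ways to split those m experiments, and every
permutation that assigns them exactly as observed reproduces the observed
difference. With few covering experiments the tie mass alone exceeds α
and the voxel can never be rejected. On a brain-scale 4 mm mask (~16k
voxels) with 25 + 25 experiments of 2–10 foci, mean coverage is ~3
experiments per side and we measure a voxel-wise rejection rate of
~0.003 at α = 0.05 — the test is valid but heavily conservative exactly
where data are sparse, which is consistent with the known reluctance of
such contrasts to reject. The package's type-I calibration study
therefore uses a compact 12³ lattice at 4 mm, sized by this coverage
analysis so that pooled coverage is ~25–30 experiments per voxel and the
permutation distribution is effectively continuous; there the measured
rejection rate is 0.044–0.050 at α = 0.05.

## Comparing CM and MC maps

All comparisons operate on the *thresholded* significance maps — what a
study would report — never on unthresholded maps:

* voxel level: Jaccard |CM∩MC|/|CM∪MC|, sensitivity |CM∩MC|/|CM|,
  precision |CM∩MC|/|MC|;
* cluster level: 26-connected clusters count as overlapping if they share
  at least one voxel; sensitivity = overlapping CM clusters / all CM
  clusters, precision = overlapping MC clusters / all MC clusters;
* peak level: local maxima (≥ all 26 neighbours) of each side's
  uncorrected thresholded z map, greedily thinned to a minimum separation
  of 8 mm (the SPM default), ties broken by lexicographic voxel index;
  then the median Euclidean distance from each CM peak to its nearest MC
  peak, and vice versa.

The z threshold for peak extraction is each map's own uncorrected
criterion — z(p < 0.001) for CM maps and z(α) for MC maps — both exposed
as settings, since the choice is not dictated by the procedure itself.
Undefined ratios (empty maps, zero clusters, empty peak sets) are
reported as NaN together with a machine-readable reason, never silently
as 0.

## The synthetic scenarios

`generate_dataset()` draws, per experiment: a sample size uniform in
10–40; per ground-truth centre, with the condition's hit rate, one focus
at centre + isotropic Gaussian jitter (sd 5 mm), redrawn until inside the
mask (resampling, not projection, to avoid boundary pile-up); and 2–10
noise foci uniform over in-mask voxels. These magnitudes are of the order
typical for task-fMRI coordinate datasets; they are configuration, not
claims about any particular literature. Seeds propagate hierarchically
(scenario → condition → experiment), so adding experiments never perturbs
earlier ones and everything is reproducible from one integer.

Three presets span the regimes of interest. `differential_only` (one
centre: hit rates 0.6 for condition A and for the difference experiments,
0 for B; 30 experiments per dataset) is the recoverable case.
`shared_activation` (equal hit rates 0.6 in A and B, 0.6 in the
difference experiments) encodes the central mechanism separating the two
approaches: the experiment-level meta-analysis converges on the centre,
while a contrast between two equally convergent main effects has, in
expectation, nothing to find — differences in activation *strength* are
invisible once each condition is reduced to its own convergence map.
`null` (no centres, 25 experiments per dataset) gives exchangeable
conditions for calibration.

What the generator does *not* emulate: publication bias, study-specific
smoothing or thresholding, correlated foci within a study beyond the
shared centres, anatomically structured grey matter, or reported-peak
selection behaviour. Passing calibration and recovery tests on these
synthetic datasets therefore validates the statistical machinery, not the
field realism of any particular dataset.

## Problem sizes and defaults

Test- and script-scale runs use a 4 mm lattice (the default
`synthetic_grid()`: a 32×38×32 ellipsoid, ~16k in-mask voxels — the order
of magnitude of a grey-matter mask at 4 mm) and 1000 permutations; the
FWE calibration study uses the 2 mm variant, and the contrast type-I
study the 12³ coverage-dense box, both for the reasons above. Full-scale
settings (2 mm grids, user-supplied grey-matter masks via `load_grid()`,
n_perm = 10,000) are plain arguments. The analysis drivers under
`analysis/` run the whole story — simulate, CM, MC, compare — from files
in a few minutes at the reduced scale.

## Known limitations

* The kernel constants are configurable defaults, not fitted values;
  exact numeric parity with any specific ALE implementation is not
  claimed.
* TAL→MNI conversion is deliberately out of scope; Talairach input is
  rejected rather than converted.
* The MC procedure inherits the conservatism documented above at
  sparsely covered voxels; raising `n_perm` does not remove it (it is a
  tie-mass effect, not a resolution effect).
* Balanced contrasts (equal-n subsampling), conjunction analysis and
  meta-regression are out of scope.
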