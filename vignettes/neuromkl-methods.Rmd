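---
title: "Methods: VOI features, GA wrapper selection and multi-kernel SVM classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VOI features, GA wrapper selection and multi-kernel SVM classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromkl)
```

## The problem

Parametric FDG-PET maps image the cerebral metabolic rate of glucose
(CMRGlc) voxel by voxel. Dementia syndromes leave characteristic regional
signatures on such maps: Alzheimer-type disease (AD) reduces metabolism
predominantly in posterior parietotemporal cortex, frontotemporal dementia
(FTD) in frontal and temporal cortex, often with a pronounced left–right
asymmetry. `neuromkl` implements an automated three-way classifier
(AD / FTD / normal control) for spatially normalized parametric volumes,
built from three stages: region-based feature extraction, genetic-algorithm
(GA) wrapper feature selection, and a multi-kernel soft-margin SVM whose
kernel weights are themselves estimated by a real-coded GA.

## Feature extraction

Given an integer parcellation (an AAL-style label volume plus a VOI registry
declaring left–right homologue pairs), each study *i* yields three feature
groups:

* **M** — the mean voxel value of each VOI (average regional metabolism);
* **S** — the standard deviation of voxel values within each VOI (spatial
  heterogeneity of regional metabolism);
* **A** — for each declared pair, mean(left VOI) − mean(right VOI)
  (lateralized hypometabolism; negative = left-sided deficit).

With the 116-region / 54-pair atlas of the clinical setting this gives
116 + 116 + 54 = 286 features per study; the toy atlases used throughout the
tests scale the same construction down. Only labeled voxels contribute;
label 0 (background/CSF) is always excluded, and no intensity threshold is
applied beyond the labeling itself. Voxel statistics use the population
standard deviation (divide by *n*): the voxels of a region are the complete
population of that region. Non-finite voxels are rejected at load time.

Features are z-scored per column. Cross-study statistics use the sample
standard deviation (divide by *n* − 1). By default the normalization
parameters are fitted on training rows only and applied to held-out rows
(`zscore_features(fit_rows = ...)`), which keeps the evaluation leakage-free;
a global single-cohort fit is available as a fidelity mode
(`pipeline_config(normalization = "global")`). Constant columns carry no
information and pass through as zeros with a warning.

## Wrapper feature selection

Selection is per group. A binary mask Φ over the group's columns is scored
by the mean k-fold cross-validated accuracy of a linear soft-margin SVM on
the masked columns, and a binary GA searches for the mask maximizing that
accuracy. The GA uses elitist inheritance, roulette-wheel selection,
one-point crossover, random bit mutation, and two less common operators:

* **Adaptive mutation schedule.** The mutation probability is kept when the
  generation's best fitness improved and multiplied by `alpha_pm` otherwise;
  on reaching the threshold `T_pm` it resets to its initial value, so the
  search escapes plateaus without degenerating into random sampling.
* **Gene modification.** The incumbent best mask is probed by clearing the
  1–3 set bits with the smallest marginal fitness contribution (fitness of
  the mask minus fitness with the bit cleared, on the same folds); the
  resulting sub-masks replace the worst individuals. "Least contribution"
  is not otherwise defined, and this marginal delta is the only
  fitness-consistent reading; its cost is bounded by one extra evaluation
  per set bit and it is applied only to the incumbent best.
* **Stagnation kick.** When the best fitness has been unchanged for more
  than `stagnation_window` (default 4) consecutive generations, every
  individual tied at the best fitness is replaced by a mutated offspring.

Two readings of the objective existed: the prose calls fitness a
classification *error* while the optimization problem maximizes *accuracy*.
We maximize accuracy; everything else in the GA is consistent with
maximization.

### Fitness determinism and selection overfitting

Re-randomizing CV folds at every fitness call would make the
generation-to-generation comparison of the adaptive schedule meaningless, so
all fold partitions are drawn once per run from the seeded RNG and held
fixed. A single fixed partition, however, lets masks that exploit one
partition's test-fold luck tie with genuinely better masks once accuracy
saturates — the familiar selection-overfitting failure of wrapper methods.
The fitness is therefore the mean accuracy across `cv_repeats` (default 2)
independently drawn, fixed partitions: still fully deterministic within a
run, at twice the cost, and enough to break most lucky ties. The t-test
baseline (below) uses the same averaged objective so head-to-head
comparisons are fair.

Averaging over partitions cannot remove a deeper limit of any wrapper
objective: a noise column that happens to separate the borderline cases of
*this particular cohort* does so under every partition of that cohort, so
at small n the exact maximizer of cross-validated accuracy need not contain
every truly informative column — redundant signal carriers can be displaced
by in-cohort noise once accuracy saturates. On phantom cohorts this shows
up as planted-column recall plateauing around 0.8 when per-column effects
are large enough to saturate the fitness; it is a property of the selection
objective at that sample size, not of the search. Recovery should therefore
be read jointly with the selected mask's cross-validated accuracy, which
the GA does maximize. The number of folds drops to the smallest class size
when classes are small; fitness of an all-zero mask is 0 by convention, and
mutation repairs all-zero offspring by setting one random bit.

With three classes the fitness SVM is a one-vs-one pair of linear machines
with majority vote, matching the multi-class construction of the final
classifier. Identical masks within a run reuse a cached fitness value — at
population 500 the population revisits masks constantly, and caching has no
semantic effect.

The compiled fitness engine is a dual coordinate-descent solver for the
L1-loss linear SVM (the liblinear algorithm) with the bias as an augmented
constant feature, a fixed-seed internal shuffle, and liblinear's default
stopping tolerance; it is cross-checked against an independent SVM
implementation in the test suite. At the test scale (n = 60, p = 20) one
fitness evaluation costs a few milliseconds, which is what makes
population-100, 40-generation runs practical on one CPU.

### Defaults

At clinical scale the selection GA runs with a population of 500 under
10-fold CV; the remaining GA hyperparameters default to standard practice:
`p_m0 = 0.01`, `alpha_pm = 1.5`, `T_pm = 0.2`, crossover probability 0.8,
elitism 1, `C0 = 1`, 50 generations. All are exposed in `ga_config()`. The
synthetic studies in the tests and the acceptance script use reduced
populations (20–100) and generations (8–40) — the phantom cohorts are far
easier than clinical data, and these sizes keep a full nested
cross-validation in minutes on one CPU; they are package defaults for the
desk-scale studies, not statements about the clinical setting. Whether
gene-modified offspring replace population members or extend the population
is unstated; they replace the worst individuals. "Halted evolution" (the
stagnation trigger) is read as best fitness unchanged for more than 4
consecutive generations — the only measurable meaning.

## Multi-kernel classification

Each feature group gets its own kernel; the machine's kernel is the
weighted sum

K(i, j) = β_M K_M + β_S K_S + β_A K_A,  β_C > 0,

with, by default, a linear kernel on M, a second-order polynomial
(x·y + 1)² on S and a Gaussian exp(−‖x−y‖²/2σ²) on A — the nonlinear
kernels on the lower-dimensional groups, where lifting to a
higher-dimensional space buys separability. The assignment is configurable
per group, so all six permutations of the kernel-swap ablation can be run.
The Gaussian bandwidth σ defaults to the median pairwise distance of the
group's training vectors (the median heuristic: scale-adaptive and
deterministic).

Each group kernel is trace-normalized — divided by its mean self-similarity
on the training set — before β-weighting. The raw kernels differ by orders
of magnitude (a second-order polynomial on a dozen z-scored features
dwarfs a Gaussian bounded by 1), so without normalization the numerical
size of β_C says little about the group's effective influence and weight
vectors are not comparable across groups. Unit-trace kernels are the
standard MKL convention; since scaling a kernel by a constant is absorbed
into its weight, the model class is unchanged — only the parameterization
becomes interpretable. Supplying `scale = 1` in `kernel_spec()` disables
the normalization.

Binary machines are trained by solving the standard box-constrained dual
(0 ≤ α ≤ C₀, Σαᵢtᵢ = 0) with an interior-point QP solver; if the solver
reports a non-positive-definite system the Gram diagonal is jittered
(starting at 10⁻¹⁰ and escalating) and the solve retried — numerical
robustness without materially changing the solution. The bias is recovered
from margin support vectors (0 < α < C₀), falling back to the midpoint of
the decision-value bounds with a warning when none exist. KKT residuals
(equality constraint, box violations) are stored on the model and asserted
in the tests at 10⁻⁶.

The three-class problem is decomposed one-vs-one with all tasks sharing a
single β vector — the minimal binary decomposition consistent with the
per-training-case voting rule below. Whether the original setting shared β
across subproblems is unstated; sharing is the simpler model.

### Prediction: accumulated kernel votes

For a test case *j*, every training case *i* with αᵢ > 0 casts the vote
yⱼᵢ = αᵢ Σ_C β_C K_C(Xᵢ, Xⱼ) for *its own* class, accumulated across
one-vs-one tasks; the predicted label is the class with the largest
accumulated vote. As printed, this rule omits the label sign tᵢ and the
bias b — unusual for an SVM decision rule, so the standard signed one-vs-one
margin vote is implemented behind `rule = "margin"` and the concordance of
the two rules on separable data is asserted in the tests (they agree on
well-separated cohorts; the unsigned rule is the default for fidelity).
Multiplying every β by a constant scales all votes uniformly and cannot
change the predicted label; this scale-invariance is also under test. Vote
ties are broken by class order with a warning.

### Kernel-weight estimation

β = [β_M, β_S, β_A] maximizes seeded k-fold CV accuracy of the multi-kernel
classifier, searched by a real-coded GA on the box [10⁻³, 10] per weight:
blend (arithmetic) crossover, Gaussian gene mutation under the same adaptive
schedule as the binary GA, elitism 1, population 50 and 30 generations by
default (10 × 6 in the desk-scale pipelines). The fold partition is fixed
per run, so the search is deterministic given its seed. If every candidate
ever evaluated ties (a degenerate, fully saturated cohort), the uniform
weight vector is returned with a warning. Inside nested cross-validation, β
is estimated on the training folds only.

## Evaluation protocol

`run_nested_cv()` partitions studies into near-equal folds (default 10,
reduced to the smallest class size; stratified by class by default, with
plain random assignment as a fidelity flag). Within each fold the full
training pipeline — z-scoring, per-group GA selection, β estimation,
classifier training — sees only the training rows; each study is predicted
exactly once. Pooled predictions give the overall accuracy; for two-class
cohorts sensitivity (true positive rate) and specificity (true negative
rate) are reported with the disease class positive.
`pairwise_experiments()` repeats the protocol restricted to each class pair.

The per-feature rejection analysis (`ttest_rejection_rate()`) tests each
feature column for a class-mean difference. The groups compared are
independent and of unequal size — a paired test cannot accommodate that —
so a two-sample Welch test is used (a pooled-variance Student option
exists). Rejections are counted at raw α (default 0.05, configurable) with
no multiplicity correction, since the rejection *fraction* at raw α is the
quantity of interest; a Bonferroni flag exists but is off by default.

The screening baseline (`ttest_baseline_selection()`) ranks features by
|t| (maximum over class pairs beyond two classes) and walks the ranking with
a greedy forward search that stops as soon as adding the next-ranked feature
fails to improve the CV accuracy — the classic filter-plus-forward
construction. Because the ranking is univariate, features that are
informative only jointly (a suppressor pair: one column carrying signal
buried under a shared nuisance, a second column measuring the nuisance
alone) rank at the bottom and the search never reaches them; the wrapper GA
evaluates masks jointly and can recover such pairs. This is the designed
contrast between the two selectors, and the interacting-pair phantom
(`simulate_interacting_features()`) makes it testable: a literal XOR pair
would be invisible to the *linear* fitness classifier both selectors share,
so the phantom plants a linearly separable joint signal instead.

## Synthetic phantoms

`make_toy_atlas()` tiles cubic VOI blocks on a y–z grid with each pair's
left block mirrored across the mid-sagittal plane, plus unpaired midline
blocks straddling it. `simulate_cohort()` draws voxels in VOI *v* of class
*c* from Normal(μ_cv + gᵢ, within-VOI sd), adds independent measurement
noise, with

* μ_cv = baseline × (1 − depth) in affected VOIs, baseline otherwise;
* FTD-affected pairs additionally lose `asymmetry_delta` on the left;
* gᵢ ~ Normal(0, `between_subject_sd`), a per-study global offset.

Defaults emulate gray-matter CMRGlc: baseline 30 µmol/100 g/min, within-VOI
sd 3 (10% of baseline), measurement noise sd 1, depth 0.25 (a moderate 25%
regional reduction), asymmetry 3 (10% of baseline), global between-subject
sd 1.5, 30 studies per class. The affected sets follow the clinical
topology at toy scale: FTD reduces the anterior half of the pairs (with
asymmetry), AD the posterior half (symmetrically), controls none. The
global offset is deliberately included: whole-brain metabolism varies
between subjects, it cancels exactly in the A features, and it is what
gives the three groups genuinely different discriminative roles (e.g. a
cohort whose only signal is asymmetry stays invisible to M once the global
variation dominates). Per-class `sd_scale` makes S-informative cohorts
constructible the same way.

`simulate_feature_table()` bypasses voxels and draws the features directly
from the sampling distributions the volume path implies (normal means with
variance σ²/n_vox, scaled-χ sds, asymmetries as differences of the drawn
means) — one to two orders of magnitude faster, used for the selection and
kernel-weight stress tests; a two-path distributional consistency check is
in the test suite. Voxel noise is Gaussian throughout: the pipeline consumes
parametric maps, not sinograms, so no Poisson counting statistics or
scanner point-spread modelling is attempted. What passing tests on these
phantoms show is that the pipeline recovers planted, well-specified
regional signals; they say nothing about registration error, partial-volume
effects, atlas mismatch or the heterogeneity of real clinical cohorts.

## Numerical choices, degenerate inputs, limitations

* QP: interior-point solve at 9 significant figures, diagonal jitter on
  non-PSD reports, α clipped to the box and thresholded at 10⁻⁸C₀.
* Single-voxel VOIs have sd 0; zero-voxel VOIs are a named fatal error.
* Zero-variance feature columns: zeroed in z-scoring (warning), counted as
  non-rejecting in the t-test analysis (warning).
* All-zero GA masks: fitness 0 by convention, repaired on sight in
  mutation, never emitted by gene modification.
* Vote ties: broken by class order, with a warning.
* Determinism: every stochastic entry point takes a seed and restores the
  caller's RNG state; identical seed + input is bit-identical output,
  including the whole GA trajectory and the simulated volumes.
* The GA's best-mask report keeps the first individual that attained the
  best fitness; when several masks tie exactly (saturated cohorts), which
  one is reported is a matter of search history, not of the objective.

The headline numbers of the clinical setting (129 studies, AAL atlas) are
not reproducible here — the clinical volumes are proprietary — so the test
suite and the acceptance script validate properties: oracle equivalence of
the feature extractor, closed-form and KKT correctness of the SVM dual,
recovery of planted signals by the GA and of informative groups by the β
search, chance-level behavior on null cohorts, and type-I calibration of
the t-test analysis.
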