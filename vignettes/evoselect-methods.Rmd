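---
title: "Methods: evolutionary wrapper feature selection for volumetric case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary wrapper feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(evoselect)
```

## The problem

Volumetric analysis of structural T1 MRI yields, per subject, on the order
of 40–180 named parameters: regional volumes (mm³), volumes as a percentage
of intracranial volume, and left–right asymmetry indices. Discriminating
early mild cognitive impairment (EMCI) from cognitively normal (CN)
subjects with such tables is hard for two reasons: the group differences
are minute (univariate screens typically leave few or no features standing
after multiplicity correction), and cohorts are small (about a hundred
subjects against up to ~180 features), so classifiers overfit unless the
feature panel is pruned aggressively.

`evoselect` implements the two competing strategies for this setting:

1. a **statistical baseline** — rank each feature by a Mann–Whitney
   rank-sum p-value, correct with Benjamini–Hochberg FDR, and classify with
   the top-*k* panels for increasing *k*;
2. **wrapper selection by evolutionary search** — score candidate feature
   subsets directly by the validation performance of the downstream
   classifier, and search subset space with NSGA-II (two objectives:
   classification error and panel size) or with one of four canonical
   single-objective metaheuristics (GA, ACO, SA, PSO).

The classifier in both arms is a fixed multilayer perceptron with hidden
layers of 20, 10 and 5 units, trained by Levenberg–Marquardt
backpropagation (LMBP) on a stratified 80/20 split.

## The classifier and its trainer

The network computes $a^0 = x$, $n^m = W^m a^{m-1} + b^m$,
$a^m = f^m(n^m)$; hidden activations are `tanh`, the output unit is a
sigmoid read against a 0.5 threshold with targets coded {0, 1}. Neither
the output coding nor the activations are forced by the study design this
package reproduces; these are our choices, made once: the minimal binary
head consistent with a mean-squared-error performance index, and the
standard activation for LM-trained networks.

Training minimises the performance index $F(x) = e^\top(x)\,e(x)$ over the
flat weight/bias vector $x$, where $e_i = t_i - o_i$ is the per-case error.
Each iteration:

1. forward pass (caching $a^m$, $n^m$);
2. backward sensitivity recursion
   $S^m = \dot F^m(n^m)\,(W^{m+1})^\top S^{m+1}$, from which the Jacobian
   rows are assembled blockwise as $J = S^m a^{m-1}$ (weights) and $S^m$
   (biases), with one row per training case;
3. damped Gauss–Newton update
   $x_{k+1} = x_k - (J^\top J + \mu I)^{-1} J^\top e$.

The damping schedule is canonical: accept a step only if $F$ decreases
(then $\mu \leftarrow \mu/10$), otherwise retry with
$\mu \leftarrow 10\mu$, giving up at $\mu > 10^{10}$. Accepted-step $F$ is
therefore strictly decreasing by construction. Defaults:
$\mu_0 = 10^{-3}$, 100 iterations, goal MSE $10^{-8}$; weights initialise
uniformly in $\pm 1/\sqrt{\text{fan-in}}$, seeded.

### Numerical choices

* **The solve is never an explicit inverse.** When there are fewer training
  cases $n$ than parameters $P$ (the usual situation: 88 cases vs up to
  ~3000 weights), the update is computed through the algebraically exact
  dual identity
  $(J^\top J + \mu I)^{-1} J^\top e = J^\top (J J^\top + \mu I)^{-1} e$,
  reducing the linear system from $P \times P$ to $n \times n$. A unit test
  asserts primal and dual paths agree to 1e-8.
* **Standardization before fitting.** Features mix mm³ volumes,
  percentages and asymmetry ratios; raw scales make $J^\top J$ severely
  ill-conditioned. Every evaluation z-scores each feature using mean/SD of
  the *training* subjects only, then applies that transform to all
  subjects — validation rows never influence the transform. A
  training-constant feature cannot be scaled and is mapped to all-zeros
  with a warning record.
* **Restarts.** LM is init-sensitive; each subset evaluation trains
  `n_restarts` (default 3) networks from seeded inits and keeps the best by
  training MSE.
* **XOR as a trainer benchmark.** We verify the trainer on the classic XOR
  least-squares benchmark (2-2-1 topology, linear output). With a
  *saturating* sigmoid head the 2-2-1 XOR problem has genuine local minima
  at MSE 0.125 that capture roughly a quarter of random
  $\pm 1/\sqrt{\text{fan-in}}$ inits — an independent trust-region
  least-squares solver started from identical inits fails similarly — so
  convergence-rate claims are only meaningful for the least-squares posing.

## Wrapper fitness

`evaluate_subset()` is the fitness every selector optimises: restrict the
table to the masked columns, stratified 80/20 split (seeded), standardize
on the training rows, train the MLP, classify the held-out subjects, and
return (error = 1 − validation accuracy, panel size). "Classification
error" is validation error, not training MSE: it is the quantity the
reported accuracies are built from. The empty subset is defined to have
the sentinel worst fitness (error 1.0, size 0) rather than raising.
Fitness is memoised per mask within a run — the split/train seeds are
fixed by the evaluation config — so duplicated individuals cost nothing.

Because the search *maximises accuracy measured on one 22-subject
validation split*, reported operating-point accuracies carry the usual
wrapper selection bias: they are honest values of the optimised objective,
not unbiased estimates of generalisation. The harness exposes repeated
splits (`n_repeats`) so users can quantify this.

## NSGA-II

Masks are binary chromosomes. Defaults follow the reference
parameterisation: population $N = 25$ equal to the mating-pool size,
crossover applied to 14% of the pool (⌈0.14·25⌉ = 4 pairings → 8 offspring
by uniform crossover), mutation applied to 40% of the pool (10
individuals) at a per-bit flip rate of 0.1, 50 generations by default.
Per generation: fill the mating pool by binary tournament on (front rank,
crowding distance); produce offspring and mutants; merge parents +
offspring + mutants; re-sort by nondomination rank then crowding; truncate
to $N$. Crowding distance is the standard formula: per objective, boundary
members get infinity, interior members accumulate the neighbour gap
normalised by the objective range (zero-range objectives contribute 0).

Open choices we fixed:

* **Crossover operator**: uniform crossover — unbiased for subset
  problems (single-point crossover privileges column order, which is
  meaningless here).
* **Initial population**: each bit Bernoulli(0.5), empty masks redrawn.
* **Operating point**: the front is the deliverable; when one subset must
  be reported we take the minimum-error member, ties broken by fewer
  features, then by lexicographically smallest mask.
* **The empty mask** (error 1.0, size 0) is never dominated — size 0 is
  unbeatable — so it is a degenerate front member whenever it occurs.
  Front-equality checks against exhaustive enumeration therefore compare
  the objective pairs of *non-empty* masks.

## Single-objective comparison methods

GA, ACO, SA and PSO are implemented as canonical textbook binary variants
(the study they mirror defers their details to unavailable supplementary
material, so we prefer reproducible canonical versions with every rate
exposed): generational GA with tournament selection, uniform crossover,
elitism 1; binary ACO with per-feature pheromones in [0.05, 0.95] acting
as inclusion probabilities, evaporation 0.2, iteration-best deposit
proportional to quality; SA with single-bit-flip neighbourhood, Metropolis
acceptance $\exp(-\Delta/T)$ and geometric cooling (T₀ = 0.1, α = 0.995);
binary PSO with inertia 0.7, accelerations 1.5/1.5, velocity clamp ±4 and
sigmoid bit resampling. They minimise the scalarisation
$\text{error} + \lambda\,k/p$ with $\lambda = 0.01$: a light panel-size
penalty that makes single-objective results comparable to NSGA-II's
two objectives while reducing to pure error at $\lambda = 0$. Each method
defaults to the shared 25 × 50 evaluation budget.

## The synthetic cohort generator

Real volumetric tables are gated; the generator produces cohorts with the
features of that data that matter for the methods: two groups (defaults
56 controls / 54 patients), $p$ correlated positive features (default
142), right-skewed marginals, and a small informative subset with modest
standardized shifts. Mechanism: a latent equicorrelated standard normal
matrix (one common factor); the informative columns of the patient group
are shifted *down* by the configured effect size on the latent scale
(emulating atrophy); each feature maps through
$\exp(\text{meanlog}_j + s\,z)$ with feature-specific baselines
(meanlog ~ N(7, 1), arbitrary volume-like units) and common log-scale SD
$s$ (`skew`, default 0.4).

Two calibration details:

* the configured `correlation` is matched on the **observed** scale: the
  latent correlation is back-solved from the log-normal moment identity
  $\rho_z = \log\!\big(1 + \rho_x(e^{s^2}-1)\big)/s^2$, so empirical
  feature correlations converge to the configured value exactly, not
  approximately;
* `effect_sizes` are standardized shifts on the log scale, so a value of
  1.0 means a one-SD separation of the log-volume distributions.

Defaults (correlation 0.2, skew 0.4, k = 8 informative at effect 1.0) were
fixed once as a plausible mild-disease regime: univariate effects around
d = 1 are detectable but the equicorrelated background caps combined
separability well below perfection.

What the generator does **not** emulate: block/anatomical correlation
structure (lobes, bilateral pairs), heavy-tailed measurement error,
site/scanner batch effects, age/sex covariates, or label noise from
behavioural diagnosis. A green recovery test therefore establishes that
the machinery finds planted signal under an idealised dependence
structure, not that it would rank real anatomical regions correctly.

## Replication harness

`run_replicated_experiment()` reruns a method `n_runs` times (default 100)
with per-run seeds derived from one master seed; each run also redraws the
80/20 split. It records each run's operating-point accuracy, panel size
and wall time, and per-feature selection counts over operating-point
masks. `feature_frequency_ranking()` returns the most frequently selected
features (default top 5, ties alphabetical); `compare_methods()` reports
per-method mean (SD) accuracy and time as differences from the
cross-method average (differences sum to zero by construction). Wall time
is recorded but deliberately never asserted against — it is
hardware-dependent.

### A known limitation of short multiobjective runs

At sharply reduced budgets (e.g. 10 generations with the default operator
fractions, which produce only ~18 new individuals per generation),
operating-point masks remain near their Bernoulli(0.5) initialisation
density: roughly half the noise features are still present. Selection
counts over a handful of replicates then separate informative from noise
features only weakly (informative ≈ 0.8·n_runs vs noise ≈ 0.5·n_runs, and
the maximum over a hundred-plus noise features reaches into the informative
range). Frequency rankings should be read from runs long enough for panel
sizes to contract — at short budgets the *accuracy* contrast against the
p-value baseline is already decisive, but the *identity* of top-ranked
features is not yet stable. This is measured, not hypothetical: the
acceptance suite runs exactly this regime and the recovery assertion
documents the shortfall when it occurs.

## Degenerate inputs and tie-breaks (summary)

* duplicate feature names, missing values, non-numeric columns,
  single-class labels: distinct named errors at load;
* zero-variance training features: zeroed with a warning record;
* p-value ties in the baseline ranking: original column order;
* count ties in frequency rankings: alphabetical;
* equal-error front members: fewer features, then lexicographic mask;
* rank-sum: exact enumeration for combined n ≤ 12 (tie-safe), normal
  approximation with tie and continuity correction otherwise;
* BH at q outside (0,1), split fractions outside (0,1), correlation
  outside [0,1): named errors.

## Reproducibility

Every public run function takes a seed and restores the caller's RNG
state. Sub-seeds (restarts, repeats, replicate runs) derive from the
master seed through a fixed integer hash, all below 2³¹. CLI runs write a
provenance JSON (command, config echo, seed, package and R versions,
timestamp); rerunning any subcommand with the same config and seed
reproduces every CSV/JSON output byte-identically (timestamps aside),
which the acceptance suite asserts.
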