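---
title: "Threshold-rule classification of expression profiles: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-rule classification of expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logiclm)
```

# The problem

Bulk and single-cell expression studies routinely need classifiers whose
decisions a biologist can read: *if AQP7 ≤ 8.46 then hepatocellular
carcinoma* is auditable in a way a support-vector machine is not.
`logiclm` trains such threshold-rule classifiers in the style of the Logic
Learning Machine family, evaluates them with the standard
diagnostic-accuracy statistics, and pools accuracy across analyses with a
summary-ROC meta-analysis.  A synthetic generator with planted rules makes
every stage testable offline.

# The model

## Latticization

Each continuous feature is discretized by supervised entropy
minimization: candidate cutoffs are midpoints between consecutive distinct
values; cutoffs are accepted greedily (the segment whose best cut most
reduces the count-weighted class entropy is split) until `max_bins` bins
exist or no cut is acceptable.  A sample is then coded per feature with the
*inverse only-one* code — `q` bits, all 1 except a 0 at the bin holding the
value — and the blocks are concatenated into one fixed-length binary
pattern per sample.  The bin boundary convention is `(-∞,c₁], (c₁,c₂], …`,
so a value equal to a cutoff falls in the lower bin, matching the `≤`
conditions of rendered rules.

Two defaults matter:

* **`max_bins = 4`** keeps any single condition to at most one interval
  (two thresholds), the shape seen in published rule tables.
* **`stopping = "mdl"`** subjects every cut to the Fayyad–Irani
  minimum-description-length test.  This is a deliberate strengthening of
  plain "stop when no entropy reduction": with hundreds or thousands of
  uninformative features and a few dozen samples, almost every noise
  feature otherwise receives cutoffs, and the rule stage downstream then
  faces hundreds of chance windows that in-sample look exactly like
  signal.  The MDL test removes the overwhelming majority of them (a
  feature with no class signal gets *no* cutoffs, `bin_count = 1`, and can
  never appear in a rule).  `stopping = "none"` restores the plain rule
  when the classical behaviour is wanted; the pure-R reference
  implementation of the cutter is kept in the package and tested against
  the C hot path under both settings.

## Implicant generation

For each class in turn (one-vs-rest), implicants are grown by sequential
covering.  A *seed* — the first not-yet-covered sample of the class, in
data order — anchors a premise built by top-down specialization:

1. candidate conditions are contiguous bin runs that contain the seed's
   bin on any not-yet-restricted feature;
2. the condition with the largest FOIL gain (still-uncovered class samples
   retained × log-precision improvement) is added, with deterministic
   tie-breaks (fewer false positives, larger univariate entropy gain of
   the feature, wider run, lower feature index);
3. conditions accumulate until the premise's false-positive count is
   within the error budget `floor(max_error × n_neg)`;
4. a *drop pass* removes conditions the budget no longer needs (least
   informative feature first) and a *relax pass* widens every surviving
   run bin-by-bin as far as the budget allows.  Both passes re-evaluate
   the premise exactly, never an approximation of it.

Seeding repeats until all class samples are covered or provably
uncoverable at the budget (those are reported per class in the model).

The premise-level exactness is the load-bearing choice.  We first
implemented the more literal bottom-up bit-flipping greedy (start from the
seed's full bin signature, admit one pattern bit at a time subject to the
error budget).  At realistic dimensionality it fails structurally: when a
move is judged by the samples it *immediately* covers, negatives still
excluded by dozens of other features are invisible, so restrictions on
genuinely informative features dissolve while "protection" silently
migrates onto arbitrary noise features; the resulting models scored LOOCV
kappa as low as 0.15 on cleanly separable synthetic data.  Specializing a
short premise top-down evaluates every candidate against the actual
premise, where no such masking exists.

During development we also evaluated an additional "envelope" pass that
closed every rule around the observed bin span of its class along
materially discriminative features.  It is strictly no worse in-sample
(covering unchanged, error non-increasing), but measured out-of-sample it
traded wrong-fire errors for no-fire errors roughly one for one on the
synthetic benchmark and was removed; the parsimonious premises above are
the shipped behaviour.

## Rule quality, relevance, prediction

For a rule `r` of class `c`, the covering `C(r)` is the fraction of class
`c` captured and the error `E(r)` the fraction of all other classes
captured; in a binary task these are the rule's sensitivity or
specificity.  Condition relevance is `R(c) = ΔE(c)·C(r)` with `ΔE` the
error increase after removing the condition (clipped at zero), and
per-variable relevance aggregates `R_v = 1 − Π(1 − R)` over all conditions
on the variable across rules; `R_v ≤ 10%` flags a marginal variable, and
`C(r)(1 − E(r)) ≤ 10%` flags a likely outlier-covering rule.

Prediction is a covering-weighted vote: every fired rule adds its `C(r)`
to its class, the largest score wins, ties go to the larger training class
and then to lexicographic order, and a sample firing nothing receives the
largest training class.

# Diagnostic accuracy and meta-analysis

Per analysis: sensitivity, specificity, Youden index `Y = SE + SP − 1`,
empirical accuracy, and Cohen kappa (the binary closed form and its
multi-class generalization through expected diagonal counts agree
algebraically for m = 2, which the tests verify).  The diagnostic odds
ratio `OR = SE·SP/((1−SE)(1−SP))` is log-transformed with asymptotic
variance `1/TP + 1/FN + 1/TN + 1/FP`; when a cell is zero, 0.5 is added to
all four cells before both the ratio and the variance (and, for
multi-class data, per collapsed 2×2 table independently).  Multi-class
tables are pooled against a reference category (disease-free class if any,
else least severe, else largest, ties lexicographic) with the
Mantel–Haenszel estimator and its printed asymptotic variance; the
multi-class specificity is the reference category's own accuracy and the
sensitivity is recovered by inverting the odds-ratio identity.  Rows are
true classes, columns predictions, throughout.

Across analyses, the fixed-effect summary odds ratio is the
inverse-variance weighted mean of the study log odds ratios.  Two printed
formulas in the source literature are dimensionally inconsistent with
their own published tables: the pooled estimator lacks the weight
normalization `Σ 1/σᵢ²` (unnormalized it yields astronomically large
values) and the confidence interval exponentiates `sOR` rather than
`log(sOR)` (the published intervals are symmetric on the log scale).  We
implement the normalized weighted mean and the log-scale interval — the
only forms consistent with those tables.  The summary ROC curve is
`sROC(x) = x·sOR/(x·sOR + 1 − x)` and its area has the closed form
`sAUC = sOR/(sOR−1) − sOR·log(sOR)/(sOR−1)²`, continuous at `sOR = 1`
(value ½, handled by a series expansion below |sOR − 1| < 10⁻⁶); the test
suite checks the closed form against numerical quadrature of the curve.

# Cross-validation harness

`loocv()` predicts each sample from a model trained on the other n−1,
refitting all preprocessing (discretization included) inside every fold.
`tune_loocv()` scans a grid and retains the point with the highest LOOCV
kappa — the published protocol, which is *non-nested*: the tuned score is
an optimistic upper bound of expected accuracy, and a `nested = TRUE` mode
is provided as the unbiased alternative.  The encoded grids are exactly
the published ones (rule classifier: `E(r)` from 2.5% to 7.5% in 0.5%
steps; kNN `k` 1–10; neural net layers 0–1, neurons 2–6, learning rate
0.25–0.75 step 0.05; decision tree pruning {pessimistic, none,
cost-complexity} with node impurity 0–0.1 step 0.01; SVM linear/RBF,
degree 1–10).  Classifiers enter only through the `trainer()` fit/predict
contract; rule-classifier and kNN trainers ship in the package, the other
three grids await any user-supplied implementation (none of the usual R
ones are assumed installed).

# The synthetic world

`simulate_expression()` draws every feature Normal on a log2-intensity
scale (baseline mean 7, sd 1 — values spanning roughly 2–14, the range
seen in published rule thresholds) and shifts, for each class, its
informative feature(s) upward by `effect` standard deviations in that
class only, so the true rule is `gene_k > mu + effect·sigma/2 ⇒ class k`.
Defaults follow the stated evaluation world: two classes of 20 samples,
p = 200 features, one informative feature per class, effect 3σ.  The
generator does not emulate probe-level artifacts, normalization, batch
effects, heavy tails or correlated features; a green recovery test
therefore establishes correct behaviour under clean location-shift signal,
not robustness to real microarray pathology.  `make_study_set()` draws
study-level `log OR` values around a true summary value with uniform
per-study variances, feeding the meta-analysis stage.

Under the null (no shift anywhere) the LOOCV kappa of the rule classifier
is expected to fluctuate around zero; the acceptance suite checks
`|mean kappa| < 0.2` over 20 replicates at n = 60, p = 200 (the feature
count is carried over from the recovery setting, which states n only).
The null classes are unbalanced (36/24) on purpose: at exact balance a
no-rule model falling back to the largest training class hits the
classical LOOCV pathology (each held-out sample makes its own class the
minority, kappa ≡ −1), which measures the validation scheme rather than
the classifier.

# Numerical and formatting choices

* Percentages print with one decimal, rounded half-up.
* Rendered thresholds carry 10 significant digits; parsing rendered rules
  recovers premise and class exactly and thresholds to that precision.
* All tie-breaks (grid order, class order, feature order) are
  deterministic; nothing in training or prediction consumes randomness.
* Model JSON serialization stores cutoffs, premises, coverings, errors,
  class sizes and parameters; a reloaded model predicts identically.

# Known limitations

* One-vs-rest rule generation can leave a class ruleless on degenerate
  data; the model records it and predicts such classes only by default.
* The greedy covering has no optimality guarantee; on adversarial bin
  structures the exhaustive-enumeration oracle in the tests bounds its
  behaviour only for small binary instances.
* Non-nested tuning reproduces the published protocol and inherits its
  optimism; use `nested = TRUE` for honest generalization estimates.
* The kNN trainer is a minimal faithful implementation for benchmarking,
  not a tuned production classifier.
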