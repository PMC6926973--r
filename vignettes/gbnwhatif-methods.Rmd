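---
title: "Bayesian-network risk-factor analysis with what-if scenarios: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian-network risk-factor analysis with what-if scenarios: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbnwhatif)
```

This vignette is the package's account of its own methods: the model class,
the algorithms behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic survey generator does and
does not emulate, and the numerical conventions (tolerances, tie-breaks,
degenerate inputs) that make the pipeline reproducible.

## 1. The model

A *general* Bayesian network (as opposed to the fixed star topology of naive
Bayes) is a directed acyclic graph $G$ over categorical variables
$X_1, \dots, X_p$, together with one conditional probability table per node.
The joint factorises as

$$P(x_1,\dots,x_p) \;=\; \prod_{i=1}^{p} P\!\left(x_i \mid \mathrm{pa}_G(x_i)\right),$$

and any conditional $P(A \mid B)$ follows by Bayes inversion,
$P(A\mid B) = P(B\mid A)\,P(A)/P(B)$, evaluated here by exact variable
elimination. Edges learned from cross-sectional survey data are
*associative*, not causal: a "what-if" scenario in this package is
conditioning (observing evidence and propagating beliefs), never a
do-intervention, and the package deliberately offers no do-calculus.

`dbn()` validates the invariants on construction: unique variable names, at
least two unique states per variable, acyclicity (Kahn's algorithm), CPT
parent sets exactly matching the graph, and every CPT column a probability
vector within $10^{-9}$ of unit mass.

## 2. Exact inference, twice

`infer_posterior()` implements variable elimination: CPTs become factors,
evidence is sliced out, and the remaining variables are summed out along a
min-degree order on the moralised interaction graph, ties broken
lexicographically by variable name so the elimination order — and therefore
the floating-point result — is a pure function of the query. The normaliser
of the final factor is $P(\text{evidence})$; when it is zero the package
raises a typed `inconsistent-evidence` error rather than returning NaN or a
uniform vector, and scenario engines surface that error with the offending
assignment named. In the evidence-free case the normaliser must be 1 within
$10^{-9}$; larger drift is treated as an internal consistency failure rather
than silently renormalised away.

`brute_force_posterior()` is the same contract computed the crude way —
tabulate the full joint (guarded to $10^7$ cells), filter, marginalise. It
exists purely as an independent oracle: the test suite and the acceptance
script drive both routes over hundreds of random networks and require
agreement within $10^{-10}$. Keeping the oracle alive next to the production
path is the package's main defence against silent inference regressions.

## 3. Structure learning and its defaults

The survey source never documents its search settings, so the learner is
explicit about its own. `learn_structure()` runs greedy hill climbing over
single-edge moves (add / delete / reverse), checking acyclicity per move and
capping parent sets, from the empty graph; optional random-DAG restarts are
seeded and compared on the final score. Move scanning is first-improvement
in lexicographic $(\text{from}, \text{to})$ order — slightly greedier than
best-improvement but fully reproducible, which matters more here.

Parameters, defaults, and rationale:

* **score** — `bdeu` (default) or `bic`. BDeu is the conventional prior
  for discrete structure search; BIC is offered because its harsher penalty
  is the cleaner choice when demonstrating that independent noise columns
  acquire no edges.
* **equivalent_sample_size = 1.0** — the weakly-informative BDeu prior
  strength customary at survey scale; larger values smooth family scores
  toward denser graphs.
* **max_parents = 3** — with 2–4-state variables and $10^4$ rows, a
  four-parent family already has more cells than can be estimated stably;
  three keeps every CPT identifiable at the scales the package targets.
* **restarts = 0** — the deterministic empty-graph start is the default;
  restarts exist for harder landscapes and are seeded so reruns agree.
* **smoothing_alpha = 1.0** — Laplace smoothing for CPT estimation,
  $(\text{count} + \alpha)/(\text{total} + \alpha r)$; $\alpha = 0$ gives
  maximum likelihood with a uniform fallback for unseen parent
  configurations. Smoothing matters at prediction time, where held-out rows
  routinely contain parent configurations absent from a training fold.

Learners refuse data containing missing values (typed `unclean-data` error)
rather than imputing: the cleaning stage deletes incomplete rows, mirroring
how the survey data were prepared, and silently imputing inside the learner
would blur that contract.

## 4. Markov-blanket feature selection

The Markov blanket of a node — parents, children, children's other
parents — is the smallest variable set that renders the node independent of
everything else. `gbn_mb_classifier()` reads blanket membership as feature
selection: learn a full network, take the class node's blanket, drop
everything else, and relearn on the reduced roster. The alternative reading
(keep the full graph, complete the blanket around the class) exists in some
toolkits; the feature-selection reading was chosen because it is the one
that actually shrinks the model, which is the stated purpose of using the
blanket here. An empty blanket degrades to a prior-only classifier with a
warning rather than an error, since that is a legitimate (if useless)
selection outcome on class-independent data.

Prediction given a full row reduces to a product of CPT entries per class
state, accumulated in log space and vectorised across rows; rows whose
evidence has probability zero under the fold model fall back to a
uniform-mixed (Laplace-like) copy of the same network, logged, never
silently dropped.

## 5. Sensitivity to findings

For a target $T$ and each node $X$, three measures, all computed from the
exact pairwise joint assembled by inference ($P(X)$ and $P(T \mid X = x)$
per state — bounded memory, no global joint):

* mutual information $I(T;X)$ in **bits**;
* entropy reduction $100 \cdot I(T;X)/H(T)$, the percentage of the target's
  uncertainty that observing $X$ removes. The self-row is exactly 100
  whenever $H(T) > 0$, which the report exploits as a structural sanity
  check; a degenerate target raises a typed error since the percentage is
  undefined.
* variance of beliefs
  $\sum_f P(f) \sum_s P(s\mid f)\,(P(s \mid f) - P(s))^2$ — the expected
  squared belief shift weighted by posterior belief. The survey literature
  prints this column without defining it; this conventional form was
  adopted, and its self-row closed form $\sum_s p_s (1-p_s)^2$ is kept as a
  documented consistency check in the tests.

Base-2 logarithms are used throughout: a four-state outcome then has
entropy at most 2 bits, matching the magnitude conventions of published
sensitivity tables (natural logarithms would rescale every row by
$\ln 2$ and push the self-entropy of a four-state node above 2).
Rows are ordered self-row first, then by mutual information descending with
lexicographic tie-breaks.

## 6. What-if scenarios and the functional decomposition

`apply_scenario()` clamps evidence, propagates, and reports every node's
baseline → posterior shift; the headline is the target state's move, and
evidence nodes get indicator posteriors. "Maximize / minimize $X$"
directives resolve to the highest/lowest state in the variable's declared
(ordinal) state order at apply time, and the resolution is recorded in the
report — scenarios manipulate states, not parameters.

The target $Y$ is the indicator of one state of one variable, so
$E(Y \mid \cdot)$ is a posterior probability; an optional score vector turns
it into a general expectation over states. The decomposition expands

$$E(Y \mid x) = E(Y) + \sum_i z_i + \sum_{i<j} z_{i,j} + \dots,
\qquad z_S = E(Y \mid x_S) - \sum_{\varnothing \neq T \subsetneq S} z_T - E(Y),$$

computed **at the scenario's observed states only** (the notation's
intent; a full tabulation over all states of one variable exists as
`main_effect_profile()`, whose weighted mean is zero because
$E[E(Y\mid X_i)] = E(Y)$ — a property the tests assert at $10^{-12}$).
`max_order` defaults to 2: main effects and pairwise interactions are what
a scenario table reads off, third order is available, and everything beyond
folds into an explicit remainder instead of being silently dropped. At
`max_order = d` the reconstruction is exact and the remainder must vanish
within $10^{-12}$.

## 7. BMI preprocessing

BMI is weight (kg) over height (m) squared. Categorisation against the 2007
adolescent growth chart (ages 12–18, per sex, 5th/85th/95th percentile
cutoffs, shipped as a package CSV and validated on load) uses left-closed
intervals: below the 5th-percentile cutoff underweight, at or above the
95th obese. Prose descriptions of such charts are boundary-ambiguous;
closed-left is the common growth-chart convention and is applied uniformly,
so a BMI exactly at a printed cutoff always lands in the upper category.
Ages outside 12–18 raise an `out-of-chart` error rather than clamping — the
chart defines nothing there.

Cleaning (`filter_rows()`) counts each dropped row against the first rule it
violates (missing value anywhere → never-user → "don't know"), so the
report's four counts always reconcile exactly with the row totals, and the
operation is idempotent. Attribute merging (`merge_attributes()`) combines
ordinal-coded source columns by `ordinal_sum` (default; `mean` available)
and quantile-bins the combined score into 3 ordered categories by default —
the source material says only that groups of items were "transformed into"
composites, so the package picks the rule that preserves ordinal
information and keeps it configurable. With discrete scores the realised
bins match the quantile design only up to the probability mass sitting
exactly on a break value; the tests therefore check frequencies against the
exact distribution of the combined score, not against idealised thirds.
Weekday/weekend daily-minute pairs combine as $(5w + 2e)/7$ — a
calendar-weighted weekly average, again chosen once and documented because
the source states no rule.

## 8. The synthetic survey generator

The real survey is restricted, so the generator exists to give every
downstream stage a ground truth with exact bookkeeping. It emulates the
*statistical shape* of the post-processing target — eleven categorical
analysis variables including a four-state obesity outcome, ~11k rows,
injected missingness and never-user/"don't know" answers with a complete
injection log — and deliberately does **not** attempt statistical mimicry
of the real joint distribution: passing tests demonstrate that the
machinery is correct at survey scale, not that any particular published
coefficient generalises.

The `survey11` fixture draws Dirichlet(1) CPT rows over a fixed
sparse graph (wealth fed by both parents' education; pocket money, academic
performance and smartphone service fed by wealth; a smartphone → sitting
time → pressure → sleep chain; obesity fed by pocket money) and accepts a
draw only when

* every family's parent-configuration probability is at least 0.135, so
  each CPT row is backed by thousands of rows at $n = 20{,}000$ and
  parameter-recovery claims are about estimation, not about starved table
  cells;
* the obesity node's marginal entropy lies in $[1.5, 2.0]$ bits — the
  belief-geometry regime of a genuinely four-state outcome (neither
  near-degenerate nor exactly uniform);
* pocket money has the strictly largest mutual information with the obesity
  node, making the fixture's expected sensitivity ranking part of its
  contract. (Given the graph this is guaranteed up to ties — every other
  variable reaches obesity through pocket money, so the data-processing
  inequality caps it — and the check enforces strictness.)

Rejection operates on deterministically derived sub-seeds, so the fixture is
still a pure function of its seed. The `naive4` fixture (a three-state
class with four feature children) additionally floors the class prior at
0.15 so stratified 10-fold splits are well-defined at $n = 5000$.

## 9. Evaluation protocol

`evaluate_models()` uses stratified k-fold cross-validation (default
$k = 10$, the common toolkit default; the source protocol is unreported):
rows shuffle within class and deal cyclically, giving fold sizes within one
row and per-class proportions within one row of global. Per model and fold,
train on the training split, score the held-out split, pool **all**
held-out predictions, and compute metrics once on the pooled records:

* accuracy — percent of argmax-correct records, argmax ties resolved to the
  lexicographically first state;
* F-measure — class-frequency-weighted mean of per-class F1 (macro
  averaging by flag; weighted is the default because it is the convention
  of the classification toolkits such tables usually come from);
* AUC — one-vs-rest ranking AUC per class with midrank tie handling
  (equivalently the normalised Mann–Whitney statistic, which the tests
  verify against a direct pairwise count), averaged with the same weights.

Only the in-house models (full network, blanket-restricted network, naive
Bayes) are implemented; off-the-shelf comparators carry no methodological
content here.

## 10. Problem sizes and limitations

The shipped test and acceptance workloads use: 200 random networks of up to
8 nodes for the inference-oracle equivalence, 100 random DAGs for blanket
screening, $n = 20{,}000$ rows for structure/parameter recovery on
`survey11`, $n = 5000$ with 10-fold cross-validation for the
classifier-vs-oracle comparison, and $n = 11{,}206$ rows for the
corruption/cleaning round-trip — sizes chosen so each claim is tested at
the scale where it is meaningful while a full run stays comfortable on a
single CPU.

Known limitations, by design: no continuous or hybrid nodes, no approximate
inference (the exact engine is the point, and the enumeration guard refuses
joints beyond $10^7$ cells), no constraint-based or exact structure search,
no imputation, no survey weighting, and no causal semantics for scenarios.
Stochastic acceptance properties (skeleton F1, CPT recovery, accuracy gaps)
are properties of a seeded draw; they hold across the seeds exercised but
are statistical statements, not identities.
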