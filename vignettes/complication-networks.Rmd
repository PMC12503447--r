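---
title: "Modelling perioperative complication networks with complnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling perioperative complication networks with complnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complnet)
```

## The problem

Perioperative complications after heart valve surgery are not independent
events: an early, relatively mild complication (a long ICU stay, prolonged
mechanical ventilation, high chest tube drainage) raises the risk of severe
secondary complications (renal failure, secondary intubation, multiple organ
dysfunction), which in turn drive mortality. `complnet` models a cohort of
patients, each coded as a vector of binary complication indicators plus a
30-day death indicator, as a **discrete Bayesian network**: a directed
acyclic graph (DAG) over the 13 variables together with one conditional
probability table (CPT) per node. The product of the CPTs defines a joint
distribution

$$P(x_1, \dots, x_V) \;=\; \prod_{v=1}^{V} P\!\left(x_v \mid \mathrm{pa}(x_v)\right),$$

from which any conditional probability — "given renal failure and MODS, how
likely is death?" — can be computed exactly.

Two modelling caveats are built into the package's vocabulary rather than
hidden. First, arcs express statistical dependence, not verified causation:
cross-sectional complication indicators cannot order events in time. Second,
death is constrained to be a *sink*: the default arc blacklist forbids every
arc out of the outcome node, since death cannot cause a complication.

## The pipeline

`run_pipeline()` chains five stages, each available as standalone
functions:

1. **Ingestion** (`read_cohort`) — strict 0/1 validation; missing values
   are rejected, not imputed, because the analysis cohort is defined by
   complete complication information.
2. **Filtering** (`filter_any_complication`) — network learning operates on
   patients with at least one complication (death alone does not qualify).
   The choice is exposed as a flag because either convention is defensible
   for the parameter-learning stage.
3. **Description** (`marginal_summary`, `cooccurrence_summary`,
   `phi_matrix`, `collinearity_report`).
4. **Structure learning** (`hill_climb`, `bootstrap_arcs`,
   `averaged_network`).
5. **Parameters and inference** (`fit_cpts`, `query`,
   `single_evidence_matrix`, `multi_evidence_deaths`, `critical_nodes`).

## Descriptive layer

The **phi coefficient** for two binary indicators is computed from their
2×2 contingency table,
$\phi = (n_{11}n_{00} - n_{10}n_{01}) / \sqrt{n_{1\cdot}n_{0\cdot}n_{\cdot 1}n_{\cdot 0}}$,
and is algebraically identical to the Pearson correlation of the 0/1
columns — the test suite asserts this identity on random cohorts. Pairs
involving a constant column are undefined; they are reported as a typed
`NA` with a count of affected pairs instead of silently propagating NaN.

The **collinearity report** summarises the eigenvalue spread of the
correlation matrix. The condition number is defined as
$\sqrt{\lambda_{\max}/\lambda_{\min}}$ — the convention under which the
usual severity threshold of 30 applies; the plain eigenvalue ratio is
available via `method = "ratio"`. A singular matrix (duplicated column)
reports `Inf` with the severity flag set rather than failing.

Percentages in display columns are rounded **half-up** to one decimal, the
convention of clinical frequency tables (base R's `round()` is banker's
rounding and would turn 0.25 into 0.2); full precision is always retained
in parallel columns.

## Structure learning

`hill_climb()` is a greedy local search over single-arc moves (add,
delete, reverse) that accepts the best strictly improving move until no
move improves the score. The default score is **BIC**,

$$\mathrm{BIC}(G) = \sum_v \left[ \log L_v - \frac{\log N}{2}\, q_v \right],$$

where $\log L_v$ is the multinomial log-likelihood of node $v$ given its
parents and $q_v = 2^{|\mathrm{pa}(v)|}$ is the number of free parameters
of a binary node. BIC is the conventional default for score-based search;
a pure log-likelihood score is available for testing (it always prefers
more arcs, which is exactly what makes it useful as a contrast). The score
is decomposable, so the search caches family scores keyed by
(node, parent set) and re-evaluates only the families a move touches.

Deterministic behaviour is a design goal throughout:

* tie-breaks between equally good moves prefer the lexicographically
  smallest (source, target, move-type) triple;
* a move must improve the score by more than an absolute tolerance of
  1e-8 (guards against floating-point noise masquerading as improvement);
* optional random restarts perturb the optimum with seeded random arc
  additions, so even restarted runs are reproducible.

**Bootstrap model averaging** (`bootstrap_arcs`) draws N rows with
replacement, re-learns the network on each replicate, and tallies per
unordered pair its *strength* (fraction of replicates containing the arc
in either direction) and *direction probability* (conditional on
presence). Replicate seeds are `seed + replicate`, so any replicate can be
reproduced alone. The canonical averaging rule keeps pairs with strength
strictly above 0.75 and orients each in its majority direction when that
direction's probability is at least 0.5 — under the conditional reading of
direction probability, every retained pair is orientable. Direction
conditional on presence (rather than unconditional) is the deliberate
choice here.

The averaged arc set can in principle contain a directed cycle even though
every replicate is acyclic. The repair rule is: find a cycle, drop its
lowest-strength arc, repeat. This preserves the strongest evidence and
touches nothing outside cycles; it is a documented convention, not a
canonical result.

The **Markov blanket** of death — parents, children, and co-parents of
children — is the operational definition of the network's *critical
complications*: conditioning on the blanket renders death independent of
every other node.

## Parameter learning

`fit_cpts()` is maximum likelihood with an optional pseudocount:
$\hat p = (n_1 + \alpha)/(n + 2\alpha)$ per parent configuration. The
default is $\alpha = 0$ (pure MLE). Parent configurations never observed
at $\alpha = 0$ are assigned the uniform value 0.5 and flagged
`unsupported`; this keeps inference total while making extrapolation
visible, and the per-configuration support counts are stored and exported
so reports can annotate low-evidence probabilities. With complications as
rare as 0.5% prevalence, empty configurations are a practical certainty at
realistic cohort sizes, which is why $\alpha > 0$ is offered.

A useful calibration fact, enforced by the test suite: for a configuration
with support $n$ the MLE's sampling error is binomial,
$\mathrm{sd}(\hat p) = \sqrt{p(1-p)/n}$. At $n = 200$ and mid-range $p$
this is about 0.03 — so recovered tables should be judged in units of
standard errors, not absolute percentage points; the parameter-recovery
suite checks every supported configuration to within four standard errors.

## Exact inference

With 13 binary nodes, exact inference is cheap and approximation is
pointless. `query()` implements sum-product **variable elimination**:
evidence is instantiated into the CPT factors, non-query variables are
summed out in a greedy min-degree order, and the surviving factor is
normalised. The result is invariant to elimination order; the test suite
compares it against brute-force enumeration of the full $2^{13}$-state
joint (which doubles as an independent oracle) to 1e-10. Evidence with
zero model probability raises an explicit "impossible evidence" error.

Report generators follow the layout conventions of clinical probability
tables: `single_evidence_matrix` renders self-conditioning cells as
missing (rather than the trivial 100%), and probabilities are displayed as
half-up-rounded percentages with full precision kept in the JSON export.
Canonical queries condition on complications being *present*; the API
accepts 0-valued evidence for general use.

## The synthetic generator

No registry data ship with the package; every validation runs against
cohorts drawn from a configurable **ground-truth network**
(`ground_truth_spec`, `sample_cohort`). Sampling is ancestral: nodes are
visited in the deterministic topological order of the DAG (lexicographic
tie-breaks) and each is drawn conditional on its sampled parents from a
single seeded generator, so a (spec, n, seed) triple is bitwise
reproducible.

`default_ground_truth()` encodes a 13-node cohort emulating the published
frequency profile of valve-surgery complications:

* marginal prevalences anchored to the reference frequency table
  (`reference_counts()`): the three common early complications near 50%,
  reoperation 5.7%, secondary intubation 2.9%, renal failure 2.4%, MODS
  1.6%, and rare nodes floored at 0.5% so cohorts of ~20,000 still contain
  enough positives for table estimation;
* a directed chain of length six from chest tube drainage through ICU
  stay, ventilation, intubation and renal failure into MODS and death;
* a v-structure (ventilation → reoperation ← tamponade);
* death as a sink whose parents are the four severe complications
  (secondary intubation, stroke, renal failure, MODS), with a CPT monotone
  in every parent and above 0.9 whenever MODS is present;
* stroke as a near-independent rare node whose only edge is its arc into
  death, reflecting the observation that stroke is driven mainly by
  pre/intra-operative factors;
* pairwise phi coefficients between complications in the 0.01–0.41 range,
  with renal failure–MODS the strongest pair.

What the generator deliberately does **not** emulate: patient covariates,
the timing and ordering of complications within a patient, negative
dependencies, and any selection effect of conditioning a cohort on having
at least one complication. Passing recovery tests on these cohorts
demonstrates the correctness of the algorithms under a known truth; it is
not evidence that a particular registry's network has been found.

## Validation problem sizes

The shipped suites exercise, among others: exhaustive-search equivalence
on all 25 three-node DAGs at N = 20,000 over 50 seeded replicates;
variable elimination versus $2^{13}$-state enumeration on 100 random
13-node models with evidence sets of size 0–4; skeleton recovery from 200
bootstrap replicates at N = 20,000; and CPT recovery at N = 50,000. These
sizes were chosen to make sampling error small relative to the effects
being recovered while keeping a full run of the suite in the minutes
range on a single core.

## Known limitations

* Binary nodes only: severity grades and continuous precursors are out of
  scope; indicators must be pre-coded upstream.
* Arcs are dependencies under the chosen score, not causal claims; several
  arcs in any run are orientation-ambiguous within the score-equivalence
  class (their bootstrap direction probabilities hover near 0.5, which is
  informative in itself).
* Greedy hill climbing finds local optima; bootstrap averaging is the
  stabiliser, not a global-optimality guarantee.
* The cycle-repair and unsupported-row conventions are documented choices
  where no canonical convention exists.
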