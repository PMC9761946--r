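---
title: "Learning Bayesian network structures from incomplete categorical data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning Bayesian network structures from incomplete categorical data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnmiss)
```

## The problem

Observational health and social-survey data are categorical and riddled with
missing values: unanswered questionnaire items, refused income questions,
skipped laboratory measurements. When the analysis goal is a Bayesian
network — a DAG whose edges summarise the conditional dependence structure
among the variables — the analyst must decide what to do with the incomplete
rows before (or while) learning the structure. `bnmiss` implements the three
standard strategies and the simulation machinery needed to compare them:

* **complete-case analysis** (`learn_complete_cases`): listwise deletion,
  then score-based search;
* **chained-equation imputation** (`mice_impute`, `learn_with_mice`):
  fill the missing cells with a cyclic sequence of per-variable conditional
  models, then learn from the single completed table;
* **structural EM** (`structural_em`): alternate completing the data under
  the *current* network with re-learning the network on the completed data,
  so the imputation model and the structure are estimated jointly.

## Scoring and search

Structures are learned by maximising a decomposable network score with tabu
search. Three scores are provided (`score_config`):

* **BDe** — the Bayesian Dirichlet equivalent (uniform) marginal
  likelihood. For node $i$ with $r_i$ levels and $q_i$ joint parent
  configurations, each cell gets prior weight
  $\alpha_{ijk} = \mathrm{iss}/(r_i q_i)$, and the family score is
  $\sum_j [\ln\Gamma(\alpha_{ij}) - \ln\Gamma(\alpha_{ij}+N_{ij})] +
   \sum_{jk} [\ln\Gamma(\alpha_{ijk}+N_{ijk}) - \ln\Gamma(\alpha_{ijk})]$.
  The imaginary sample size defaults to 1. BDe assigns equal scores to
  Markov-equivalent DAGs; the test suite verifies this numerically.
* **BDs** — the sparse variant: prior mass is spread only over parent
  configurations actually observed, $\alpha_{ijk} = \mathrm{iss}/(\tilde
  q_i r_i)$ with $\tilde q_i$ the number of observed configurations.
* **BIC** — log-likelihood minus $c$ free parameters, with
  $c = \log(n)/2$ by default.

The tabu search (`tabu_search`) starts from the empty graph and applies the
best admissible single-edge addition, deletion or reversal. A tenure-limited
list of recently visited structures is forbidden (default tenure 10), the
search tolerates up to 10 consecutive non-improving moves, and ties between
moves are broken lexicographically by (operation, parent, child) so the
search is fully deterministic. Acyclicity is checked through the path-count
matrix $(I-A)^{-1}-I$ (exact for a DAG, where $A$ is nilpotent): an addition
$i \to j$ is admissible iff there is no $j \leadsto i$ path, and a reversal
iff the edge is the only $i \leadsto j$ path. On three-variable problems the
search provably reaches the global optimum found by exhaustive enumeration
of all 25 DAGs (tested on 50 random datasets).

Family scores are memoised per dataset, which is what makes local-move
search affordable: along one search most candidate moves revisit families
already scored.

## Generating the study conditions

`generate_random_dag` draws a uniform random topological order, then gives
each node an in-degree uniform on $\{0..\min(3, \text{predecessors})\}$ with
parents chosen uniformly. This satisfies the structural constraints of the
study design (acyclic, in-degree at most 3, three shared levels per node);
the generator name is recorded in a provenance attribute so an MCMC-based
generator could be swapped in. Whether the original generator enforced
graph connectivity is not documented; a `connected = TRUE` rejection option
is provided but off by default.

CPT rows are symmetric Dirichlet draws (`sample_cpts`): concentration 0.5
per cell for nodes with parents (sharp, informative conditionals) and 5 for
parentless nodes (near-uniform roots). `forward_sample` draws complete
tables by ancestral sampling; sampled joint frequencies converge to the
enumerated joint (`exact_joint`) at the Monte-Carlo rate.

## Amputation

`ampute` introduces missingness into a complete table following the
multivariate-amputation scheme. Rows are assigned to missingness patterns
by a multinomial draw over the pattern frequency vector (default: one
pattern per variable, uniform frequencies). Within a pattern's subset each
row becomes incomplete with probability

* **MCAR** — the target proportion, independently of everything;
* **MAR / MNAR** — $\mathrm{logit}(p_r) = \mathrm{shift} + z(s_r)$, a
  right-tailed logistic in the standardized weighted-sum score $s_r$ of the
  row, with the shift solved by bisection so the mean probability equals
  the target proportion within $10^{-6}$. Under MAR all variables except
  the one to be removed carry weight 1; under MNAR only the to-be-removed
  variable's own value does — that is the entire difference between the two
  mechanisms.

Categories enter the weighted sum as integer codes in declared level order,
standardized per column; zero-variance columns are excluded. The original
table is retained in an attribute (`ground_truth`) so evaluation code can
score imputations; amputation never alters an observed value.

## The learners

*Structural EM* initialises with an empty network whose marginals are fit on
the available cells, then iterates at most 5 times: the E-step completes
every missing cell from the current network using the node's conditional
distribution given its parents (parents imputed first, in topological
order); the M-step runs tabu search on the completed table and refits CPTs
by maximum likelihood. It stops early when the structure is unchanged. The
E-step is a *hard* completion. Two variants exist: the default fills each
cell with the conditional mode (ties to the lowest level index), which makes
a single run deterministic; `estep = "sample"` draws from the conditional
instead. Hard assignment does not guarantee a monotone score across
iterations; decreases are recorded in the per-iteration trace and flagged,
not treated as errors.

*Chained-equation imputation* initialises missing cells from each
variable's observed empirical distribution, then performs 5 cycles in
column order: for each variable, a polytomous (multinomial) logistic
regression on all other variables — main effects, one-hot coded,
ridge-stabilised (penalty $10^{-3}$, fitted with `glmnet`) — is estimated
on the rows where the variable is observed, and imputations are drawn from
the fitted category probabilities. Degenerate fits (a single observed
level, separation, failure to converge) fall back to draws from the
observed marginal for that cycle and are counted in the diagnostics. One
completed dataset is produced for structure learning; pooling across
multiple imputations is out of scope here.

With missingness near zero all three learners coincide (tested at 1%
missingness), and imputers never contradict an observed cell.

## Evaluation

Learned structures are compared with the generating structure as
**skeletons** — all links undirected — because a single missing or extra
edge can flip the orientation of distant edges within an equivalence class
and make CPDAG-level comparison erratic. With TP/FP/FN as the shared,
extra and missed links:

$$\mathrm{Precision} = \frac{TP}{TP+FP}, \qquad
  \mathrm{Recall} = \frac{TP}{TP+FN}.$$

An empty learned graph has undefined precision; such replicates are
recorded as missing, excluded from cell means, and counted in the report
(the alternative 0/1 conventions would bias cell means arbitrarily).

Imputation accuracy is the **Hamming distance**: the number of originally
missing cells whose imputed value differs from the ground truth.

`aggregate_and_test` reproduces the statistical aggregation: per
(variable-group × proportion × sample-size × mechanism) cell, per-method
means and standard errors; a one-way ANOVA across methods; Bonferroni
correction across all cells of the same (metric, sample size, mechanism)
panel; Tukey HSD pairwise tests where the corrected p-value is below 0.05;
and Student's t-tests on Hamming distances between the two imputing
methods. The six variable groups 2–5, 6–8, 9–11, 12–14, 15–17, 18–20
partition the 2–20 range.

## The survey stage

`survey_pipeline` is the real-data analysis recipe, exercised here on a
synthetic fixture. Structural EM is run repeatedly with distinct seeds
(sampling E-step — with the deterministic mode E-step every repeat would
learn an identical network and the consensus would be vacuous), each result
is reduced to its CPDAG, and the **arc strength** of an unordered pair is
the fraction of CPDAGs containing the link in any orientation (the final
presentation is the undirected skeleton; no causal claims are made).
Strength distributions from such runs are typically strongly bimodal —
stable links near 1, noise links near 0 — and `detect_bimodal_threshold`
selects the minimum of the upper cluster when a gap of at least 0.5
separates the clusters, falling back to a configurable default (0.87)
otherwise. Communities in the consensus skeleton are found by
Girvan–Newman edge-betweenness divisive clustering, cut at maximum
modularity (the cut rule is this package's choice; the clustering library's
standard).

`generate_survey_fixture` emulates the shape of a linked
health-and-retirement survey extract: 29 categorical variables with 2–4
levels, generated from a planted network of five blocks (6, 6, 6, 6, 5
variables) densely connected within and joined by single bridges, so real
communities exist to recover. Missingness is introduced by the amputation
module under MAR with uneven targets — one variable near 33%, two near
10%, the remaining 26 near 1% and co-missing with the heavy variable so
missing patterns overlap — leaving about 47% of rows fully complete. The
default 5726 rows match the emulated extract; tests use fewer rows, which
preserves every distributional property above.

What the fixture does *not* emulate: real surveys mix ordinal and nominal
scales, missingness driven by latent mechanisms (true MNAR refusal), and
clustered or longitudinal observations. Passing tests show the pipeline
recovers planted structure under its own generative assumptions, not that
it would recover the "true" network of any real survey.

## Numerical choices and degenerate inputs

* Probability calibration in amputation uses bisection on the logistic
  shift over [-40, 40] to $10^{-12}$ interval width; constant scores yield
  exactly the target proportion.
* Unobserved parent configurations get uniform conditionals in ML fits
  (they carry no likelihood but imputation needs proper distributions).
* Forward sampling and all imputation draws use inverse-CDF draws against
  the row's conditional, with a $10^{-15}$ guard against rounding at
  category boundaries.
* Zero complete rows makes complete-case learning a recorded failure (not
  an exception), so replicate batches continue; a variable with no
  observed values at all is a hard error for the EM and imputers.
* All randomness flows through `derive_seed(master, label, ...)`, a fixed
  integer hash, so every stage (structure, CPTs, rows, amputation,
  learner) has an independent, reproducible stream and results are
  independent of execution order.

## Reduced problem sizes

The full factorial design — 19 variable counts × 6 proportions × 3
mechanisms × 3 sample sizes × 100 replicates = 102,600 datasets — is
enumerable (`scenario_grid()`, `enumerate_scenarios`) but deliberately not
run by tests. The shipped checks use reduced designs chosen as this
package's own test conditions: 20 replicates at 15 variables / proportion
0.5 for the recall ordering, 10 datasets per cell at proportion 0.3 for
Hamming comparisons, and a 1000-row fixture with 20 SEM repeats for the
survey stage. `ci_grid()` provides a similar reduced grid for
experimentation.

## Known limitations

* The E-step is hard assignment (impute-then-refit), not expected
  sufficient statistics; the classic soft structural EM is a possible
  extension, and score monotonicity is therefore only monitored.
* MNAR is simulated, not corrected for: none of the learners model the
  missingness mechanism (no selection/Heckman-style imputation).
* Arc strengths count any-orientation adjacency of CPDAGs; orientation
  consensus is not reported.
* Continuous or mixed variables, latent variables and multi-imputation
  pooling are out of scope.
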