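---
title: "Models and methods behind phyllonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phyllonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllonet)
```

phyllonet analyses co-occurrence structure in leaf-associated (phyllosphere)
fungal communities and its relationship to plant secondary metabolites,
specifically the triterpenoid saponins (ginsenosides) of *Panax* leaves.
This vignette explains each model in the pipeline, the tunable parameters
and their defaults, the synthetic-data generator that the test suite
exercises, and the numerical choices made where the design was open.

## Network construction

Nodes are amplicon sequence variants (ASVs) from a rarefied count table.
ASVs whose overall relative abundance is at most 0.01% are removed
(`abundance_filter()`), since rare taxa produce unstable rank correlations
at typical sample sizes. All pairwise associations are Spearman
correlations with mid-rank ties (`spearman_matrix()`); two-sided p-values
use the t approximation on $n-2$ degrees of freedom, and
Benjamini–Hochberg q-values are computed over the strict upper triangle.
Zero-variance columns are assigned $\rho = 0$, $q = 1$ with a warning
rather than propagating `NaN`.

The correlation cutoff is chosen by random matrix theory rather than by
hand (`rmt_scan()`, `select_transition()`). For each candidate cutoff $t$
the q-masked matrix is hard-thresholded at $|\rho| \ge t$ and
eigen-decomposed. Eigenvalues are deduplicated (tolerance $10^{-8}$;
isolated nodes contribute a high-multiplicity eigenvalue), unfolded by a
cubic smoothing spline fitted to the empirical cumulative spectral density
(10 degrees of freedom by default), and the nearest-neighbour spacing
distribution (NNSD) of the unfolded spectrum, normalised to unit mean
spacing, is scored by a chi-square statistic (40 bins by default) against

* the Poisson law $e^{-s}$, characteristic of uncorrelated (system-specific,
  modular) structure, and
* the GOE Wigner surmise $\tfrac{\pi s}{2} e^{-\pi s^2/4}$, characteristic
  of a random matrix.

The selected threshold is the smallest cutoff at which the Poisson fit
beats the GOE fit *and* the Poisson chi-square test is not rejected at
$\alpha = 0.05$. Two caveats are worth stating plainly. First, the
reference implementations of RMT thresholding in the microbial-ecology
literature do not publish their unfolding internals, so the spline and
binning defaults here are this package's own, documented and test-covered
choices. Second, the NNSD is a bulk statistic: it cannot see the last few
extreme sampling-noise correlations, so the selected threshold removes
(in our planted-block tests) more than 99% of noise pairs but is not
guaranteed to exceed the single largest noise correlation. Networks keep
edges with $q \le 0.05$ and $|\rho|$ at or above the threshold; signs are
retained as edge attributes, but all topology metrics use the unsigned,
unweighted simple graph, as is standard for these measures.

## Topology, robustness, and random-graph comparison

`complexity_indices()` reports average shortest path length over connected
pairs, global efficiency $\frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij}$ (with
unreachable pairs contributing zero — the two metrics deliberately
disagree on disconnected graphs), natural connectivity
$\bar\lambda = \ln\big(\tfrac{1}{N}\sum_i e^{\lambda_i}\big)$ over
adjacency eigenvalues (computed with a log-sum-exp guard), Freeman degree
centralization, average local clustering, and Newman modularity of the
fast-greedy partition. Robustness is the natural connectivity remaining
after removing 20/30/40% of nodes uniformly at random
(`robustness_removal()`, 100 replicates by default).

Observed values are compared against 100 Erdős–Rényi $G(n,m)$ graphs with
the same node and edge counts (`er_ensemble()`, `ensemble_panel()`); a
deviation beyond 1.96 ensemble standard deviations is flagged significant.
Node roles use the within-module degree z-score and participation
coefficient with the conventional cuts $z = 2.5$ and $P = 0.62$
(`zi_pi()`); kinless plus provincial hubs constitute "hub nodes". Modules
with zero degree spread define $z = 0$. The upper degree tail (degrees at
or above the median — the median is fixed as $x_{\min}$ rather than
searched, matching the tail definition used for these networks) is fitted
by discrete maximum likelihood with a Hurwitz-zeta normalisation, and
goodness of fit uses a parametric-bootstrap Kolmogorov–Smirnov test
(200 bootstrap replicates by default). A passing fit covering more than 50
nodes is "weak" scale-free; fewer, "weakest".

## Link attribution (environment / dispersal / biotic)

Each edge is tested for two non-biotic explanations
(`attribute_links()`). *Environmental filtering*: some environmental
factor correlates significantly (Spearman, BH q ≤ 0.05 over the
node-by-factor family) with both endpoints, and the endpoints' partial
Spearman correlation controlling that factor falls below the network
threshold — the link is explained away by shared environmental response.
Factors are tested one at a time (an any-factor rule); conditioning on
factor combinations is deliberately out of scope and the rule is isolated
behind this module's interface so it can be swapped. *Dispersal
limitation*: both endpoints have single-taxon Bray–Curtis profiles with
Mantel correlation $r \ge 0.6$, $p < 0.05$ against Euclidean spatial
distance (999 permutations by default). For a single taxon Bray–Curtis
reduces to $|x_a - x_b|/(x_a + x_b)$, with double zeros contributing 0.
Edges qualifying for both tests are labelled `env&disp`; the remainder are
potential biotic interactions.

## Modules, eigengenes, and saponin profiles

Modules come from greedy modularity maximisation
(Clauset–Newman–Moore). Each module with at least 5 nodes gets an
eigengene: the first principal component of the column-standardised
relative abundances of its members, sign-oriented so it correlates
non-negatively with the members' mean standardised abundance (a WGCNA-style
convention; the orientation is otherwise arbitrary). Saponin profiles are
summarised by covariance PCA — centred but *not* scaled, because the eight
saponin contents (Rb1, Rb2, Rc, Rd, Re, Rg1, F1, R1, in mg/g) are absolute
quantifications on a common scale; centring is applied as standard even
though some descriptions leave it implicit. Total saponin content is the
row sum.

Candidate modules and environmental factors are screened by Spearman
correlation against the saponin PC1 with BH FDR applied within each family
separately (FDR < 0.05). Environmental variables are log-transformed
(except pH) and greedily pruned for collinearity ($\rho^2 > 0.6$, dropping
the member of the worst pair with the larger mean absolute correlation to
the rest). Growth year is not a covariate anywhere in the pipeline.

The incremental value of module eigengenes is assessed by paired
cross-validation (`ml_compare()`): random forest (500 trees) and
k-nearest-neighbour regression (k = 7) predict the saponin PC1 from four
feature sets (environment only; plus endosphere eigengenes; plus
phylloplane eigengenes; plus both) under one shared 5-fold assignment, so
differences in fold-averaged MSE and Spearman rho are paired comparisons.
The learner hyperparameters are package defaults — the analysis names the
learners but no settings — and are configurable.

## Positive regulation modules, assembly, and path models

A candidate module is a *positive regulation module* (PRM) when at least
half of its members (boundary inclusive; configurable) correlate
significantly and positively with total saponin content, member-level
significance being BH FDR < 0.05 across all tested members — FDR rather
than raw p, consistent with the package-wide multiple-testing policy. PRM
members are compared with the remaining network nodes by degree (Wilcoxon
rank-sum), guild composition (only probable and highly probable guild
calls are tallied; plant pathogen + endophyte + epiphyte form the
plant-associated aggregate), and assembly stochasticity.

The stochasticity ratio (`nst()`) is a pinned member of the normalised
stochasticity ratio family: the null model redraws each sample's taxa with
probability proportional to occupancy while preserving the sample's
richness and permuting its observed non-zero abundances; dissimilarity is
Ruzicka (quantitative Jaccard); each sample pair contributes
$\min(D_{obs}, \bar{E}_{null}) / \max(D_{obs}, \bar{E}_{null})$, and the
mean over pairs is clamped to $[0, 1]$. The ratio is 1 when observed
dissimilarity matches the null (stochastic assembly) and approaches 0 when
selection makes communities more similar *or* more divergent than chance.
Published variants differ in dissimilarity metric and null model and the
original analysis does not pin one; this package's choice is explicit and
swappable.

Direct effects on total saponin are tested with an observed-variable path
model (`fit_path_model()`), the prior structure being environment →
modules, environment → saponins, modules → saponins. Inputs are
z-standardised, so estimates are standardised effects. Fitting minimises
the maximum-likelihood discrepancy
$F = \ln|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1}) - \ln|S| - p$
with `nlminb`, started at the equation-wise OLS solution (which is the ML
optimum for recursive models — the optimiser run guards against
non-recursive extensions); $\chi^2 = (n-1)F_{\min}$, CFI uses the
independence baseline, and
$\mathrm{RMSEA} = \sqrt{\max(\chi^2 - df, 0)/(df\,(n-1))}$. Standard
errors come from the numerical Hessian. A saturated model gives
$\chi^2 = 0$ and CFI = 1 exactly. Exogenous variances and covariances are
fixed at their sample values, which is ML-equivalent to freeing them.
There are no latent variables anywhere in the model, so this is path
analysis, not full structural equation modelling. PRMs with a significant
positive direct path contribute their significantly positive members as
*positive regulation taxa* (PRT); a module excluded from the path model
because its eigengene is collinear with another's can be retained
explicitly, mirroring the documented collinearity exception in the
screening design.

Order-level enrichment of PRT uses the one-sided hypergeometric upper tail
(`order_enrichment()`), which coincides with the one-sided Fisher exact
test — the test suite asserts the identity — with BH FDR across orders
only; orders with fewer than 2 network members are reported as skipped
rather than tested. `taxonomy_tree()` nests ASVs under genus → family →
order → class → phylum → kingdom and emits newick; conflicting lineages
are an error, not a repair.

## The synthetic-data generator

`simulate_community()` plants the structure the analysis assumes, so every
recovery test has an exact ground truth:

* **Scale.** Defaults mirror the study design: 27 samples per plant
  species × compartment, 120 ASVs, rarefaction depth 12,412 reads.
  Recovery tests that need stable stochastic assertions use 100–200
  samples; both scales are exercised in the test suite.
* **Modules.** Latent Gaussian factors, one per module; member
  log-abundances load so pairs reach the configured within-module
  correlation (0.7 by default; a latent-factor Gaussian copula — the
  source data's abundance law is unknown, and this choice is ours).
* **Environment.** Five edaphic variables (pH on its natural scale, the
  others log-normal) as monotone transforms of latent factors; planted
  environmentally driven ASV pairs load on a shared factor.
* **Space.** Samples sit in three tight plantation clusters on the unit
  square, mirroring the multi-plantation field design. Dispersal-limited
  ASVs decay exponentially with distance from one plantation's centre.
  With 27 *uniform* points a point-source taxon's single-taxon
  Bray–Curtis profile has an intrinsic Mantel ceiling near 0.45 — it can
  never meet the $r \ge 0.6$ operational definition of dispersal
  limitation — so uniform coordinates would plant a structure that
  contradicts its own ground truth; the clustered layout (noiseless
  Mantel $r \approx 0.85$) is therefore the default.
* **Counts.** Multinomial sampling at 3× depth, then rarefaction without
  replacement to exactly the target depth. The closure this induces is
  realistic and visible: when planted modules dominate total reads,
  genuine negative couplings appear between them, which is why the
  all-positive-edges property is only asserted on draws where modules are
  diluted among background taxa.
* **Saponins.** Eight log-normal contents driven by the planted PRM
  factor(s) (effect 0.8 by default), a small environmental term (0.3), and
  noise.
* **Taxonomy and guilds.** Real fungal orders with
  construction-consistent lineages and random guild labels with
  confidence tags.

What passing recovery tests do *not* show: robustness to compositional
effects beyond rarefaction (no SparCC-style correction is attempted — a
stated non-goal), to unmeasured environmental confounders, or to abundance
distributions far from log-normal. The generator emulates the statistical
skeleton of the study design, not amplicon sequencing.

## Numerical choices and degenerate inputs

* Stage seeds derive deterministically from one master seed
  (`derive_seed()`), so any stage can be replayed alone; identical config
  and seed reproduce byte-identical outputs and manifest hashes.
* RMT thresholds with fewer than 10 usable spacings are marked unusable;
  selection errors out (advising a wider grid) rather than guessing.
* Wilcoxon comparisons on fully tied degree sets report $p = 1$.
* Eigengene computation drops constant member columns with a warning;
  `module_eigengene()` refuses modules below 5 members.
* The path-model fitter rejects non-positive-definite sample covariances
  with the offending minimum eigenvalue in the message.
* Problem sizes in the test suite (communities of 24–120 ASVs, 8–400
  samples; ensembles of 30–100 graphs; 200 null randomisations;
  2,000-observation path-model recovery) were chosen as the smallest
  scales at which the corresponding stochastic assertions are stable
  across seeds.

## Known limitations

Correlation networks are not interaction networks; the package keeps the
field's vocabulary ("potential biotic interaction") deliberately. The
LTED operationalisation is one reasonable reading of a method whose
formulas are not published in full; it lives behind a narrow interface.
The RMT unfolding defaults, the NST flavour, and the ML hyperparameters
are package choices where the source analysis delegates to external tools
without pinning settings — each is documented above and configurable at
the call site.
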