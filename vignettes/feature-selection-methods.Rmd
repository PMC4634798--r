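---
title: "Feature subset selection for abundance tables: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature subset selection for abundance tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otuselect)
```

## The setting

The input is a feature-by-sample count matrix $\mathbf{X} \in
\mathbb{N}_+^{K \times M}$ — rows are OTUs or functional features, columns
are samples — together with one categorical phenotype $Y$ per sample.
Feature subset selection asks which rows carry information about $Y$,
removing both *irrelevant* features (independent of the phenotype) and
*redundant* ones (carrying the same information as features already
chosen). `otuselect` implements three families: information-theoretic
filters, a bootstrap meta-selector (NPFS) that infers the number of
relevant features, and embedded selection by the lasso.

## Information-theoretic filters

### Estimators

All filter criteria are built from plug-in (maximum-likelihood) estimates
of entropy, mutual information and conditional mutual information on
discretized abundances:

$$\mathsf{I}(X;Y) \;=\; \sum_{y \in \mathcal{Y}} \sum_{x \in \mathcal{X}}
  p_{X,Y}(x,y)\,\log_2 \frac{p_{X,Y}(x,y)}{p_X(x)\,p_Y(y)},$$

with $0 \log 0 := 0$, conditional MI computed as
$\mathsf{I}(X;X'|Y) = \sum_y p(y)\, \mathsf{I}(X;X' \mid Y=y)$ on the
conditional slices, and tiny negative floating-point residue clamped to
zero. Logarithms are base 2 (bits) throughout; any fixed base preserves
every argmax decision the selectors make, bits are simply interpretable.
No bias correction is applied: the plug-in estimator is the standard
choice in the compiled filter-selection libraries this package follows,
and all criteria compare estimates *across features on the same sample
size*, where the dominant $(|\mathcal{X}|-1)(|\mathcal{Y}|-1)/(2M\ln 2)$
bias term is shared. The bias is *not* shared across features of
different discretized cardinality — a consequence discussed under
*Known limitations*.

### Discretization

Counts must be mapped to a small discrete support before estimation.
`discretize()` keeps integer-valued features with at most `n_bins`
distinct values as-is (rank-encoded), and otherwise bins by rank into
`n_bins` equal-frequency bins, ties always sharing a bin. Equal-frequency
binning is robust to the heavy zero-inflation and right skew of OTU
counts (a zero-heavy feature collapses its zeros into one state instead
of wasting most bins on an empty range). The default `n_bins = 10` is a
conventional compromise — enough resolution to see nonlinear
associations, few enough states that $M$ in the low hundreds still
populates the joint table — and is exposed on every selector and on the
CLI (`--bins`).

### The greedy search and the criterion catalog

The search initializes the selected set $F = \emptyset$ and for $k$
iterations adds the candidate $X$ maximizing

$$\mathcal{J}(X, Y, F) = \mathsf{I}(X;Y)
  - \alpha(|F|) \sum_{X' \in F} \mathsf{I}(X;X')
  + \beta(|F|) \sum_{X' \in F} \mathsf{I}(X;X'|Y),$$

removing it from the candidate pool. The conditional-redundancy term
enters with a *positive* sign: two features that share information about
the class are jointly useful. The linear criteria are MIM
($\alpha=\beta=0$), MIFS ($\alpha$ constant, default 1), mRMR
($\alpha=1/|F|$), JMI ($\alpha=\beta=1/|F|$) and CIFE ($\alpha=\beta=1$);
the nonlinear ones follow the standard survey definitions — CMIM
($\min_{X'} \mathsf{I}(X;Y|X')$), ICAP (per-pair clamped redundancy),
DISR (normalized joint relevance) and CondMI (conditioning on the whole
selected set as one joint variable). Every criterion reduces to
$\mathsf{I}(X;Y)$ at $F=\emptyset$.

Two numerical choices matter. Ties in the argmax are broken toward the
lowest feature index, making every run deterministic. And the pairwise
sums are accumulated incrementally — one new MI/CMI term per candidate
per step — so a full run costs $O(kK)$ estimator evaluations rather than
$O(k^2 K)$; the tests verify the incremental engine against a
from-scratch evaluation of the objective at every step. Constant
features are retained (their MI is 0, so they can never precede a
feature with positive estimated MI); no prefiltering is applied.

## NPFS: inferring the number of relevant features

Fixed-$k$ filters force the user to guess the size of the relevant set.
NPFS runs a base criterion ("NPFS-SF", e.g. NPFS-MIM) on `n_bootstraps`
resampled datasets, each selecting $k$ features, and declares feature
$j$ relevant when its selection count $c_j$ exceeds

$$\zeta = \min\{z : P(\mathrm{Bin}(B, k/K) > z) \le \alpha\},$$

the critical value of a binomial test whose null says every feature is
equally likely to be selected ($p_0 = k/K$). Strict inequality makes the
per-feature size at most $\alpha$ by construction *under that null*.
Defaults: $B = 100$ bootstrap-size resamples drawn with replacement
(`subsample_fraction = 1`), $\alpha = 0.05$, base criterion MIM. Each
replicate is seeded as `seed + replicate`, so results are bitwise
reproducible for any number of worker processes — parallel scheduling
cannot change the output. A replicate that happens to draw a single
class is redrawn (up to 100 times) inside its own RNG stream.

## Embedded selection: the lasso

With a binary phenotype coded $\mathbf{y} \in \{\pm 1\}^M$ and the table
converted to per-sample relative abundance,

$$\theta^* = \arg\min_{\theta \in \mathbb{R}^K}
  \frac{1}{2M} \lVert \mathbf{y} - \mathbf{X}^{\mathsf{T}}\theta
  \rVert_2^2 + \lambda \lVert \theta \rVert_1,$$

and the support of $\theta^*$ is the selected set — its size is decided
by $\lambda$, not by the user. This is the least-squares form on $\pm
1$ labels, not a logistic model, and it is fit without an intercept and
without standardization by default (after relative-abundance
normalization all features share a scale; a `standardize` flag exists).

*Grid.* $\lambda_{\max} = \max_j |\mathbf{x}_j^{\mathsf{T}}\mathbf{y}|/M$
is the smallest penalty whose solution is exactly $\theta = 0$ (the
subgradient condition at zero); the grid is 100 log-spaced values from
$\lambda_{\max}$ down to $10^{-4}\lambda_{\max}$.

*Solver.* Cyclic coordinate descent with KKT-violation screening (a
matrix product finds coordinates that must activate), warm starts along
the descending grid, and an exact active-set polish: once the support
stabilizes, the stationarity system restricted to it is solved directly,
sign-inconsistent coordinates are dropped and the candidate is accepted
only if the full KKT conditions verify — in which case it is *the*
global minimum of this convex problem, with machine-precision KKT
residuals. On degenerate (saturated, collinear) supports where the solve
cannot be verified, plain coordinate descent finishes at a scale-free
energy tolerance ($\max_j a_j \Delta\theta_j^2 < 10^{-10}\,
\overline{y^2}$, ground further to $10^{-14}$ in strict mode).

*Cross-validation.* Stratified folds (default 5) so every training split
keeps both classes; the held-out cost is the data-fit term
$\frac{1}{2M_{val}}\lVert \mathbf{y}_{val} -
\mathbf{X}_{val}^{\mathsf{T}}\theta \rVert_2^2$ (the penalty is not
included — it is a complexity control, not a measure of fit); the
$\lambda$ minimizing the mean held-out cost is chosen, ties resolved
toward the larger (sparser) value, and the final model is refit on all
data. Inner fold fits run at a relaxed tolerance ($10^{-8}$) since
held-out costs do not need machine-precision solutions; the final refit
is strict. The support is $\{j : |\theta_j| > 10^{-8}\}$.

## The synthetic-data generator

`synthetic_abundance()` is the package's stated test world. It emulates
a 16S count table: log-normal feature means rescaled so a sample's
expected depth is `depth` (default 10,000 reads), negative-binomial
counts with dispersion `size = 1` (strongly overdispersed, typical of
OTU data), and a balanced binary phenotype. Four planted structures:

* **informative** — the case-class mean is shifted by `effect_size`
  standard deviations of the base negative binomial;
* **redundant** — Poisson resamples of an informative parent
  (correlated, no new information);
* **XOR pairs** — two-level (low/high) abundance driven by latent bits
  exactly balanced within each class, so each member's empirical MI with
  the class is *exactly* zero while the pair's parity determines the
  class. The two abundance levels are noiseless by design: the pair is a
  truth-table construction, which is what makes the marginal-independence
  property exact rather than approximate;
* **noise** — class-independent negative-binomial counts.

What the generator does *not* emulate: compositional closure at fixed
read depth (counts are drawn per-feature, not multinomially, so features
are independent given their means — real OTU tables are closed),
phylogenetic correlation among taxa, and batch or library-size effects.
A green selector test on this world therefore establishes correctness of
the *selection machinery* — step optimality, calibration against
oracles, determinism — not robustness to compositional artifacts.

## Design choices on genuinely open points

* *Metadata precedence*: when both a mapping file and in-BIOM sample
  metadata are present, the explicit mapping file wins, with a logged
  notice.
* *Taxonomy* is stored as a single `"; "`-joined lineage string.
* *Samples with empty or `"NA"` phenotype values* are dropped, not
  errored — real mapping files are incomplete.
* *Multi-valued phenotypes* are never collapsed silently; the CLI
  exposes `--label-map old=new,...` for explicit collapsing (e.g. diet
  subcategories to omnivore/vegetarian).
* *NPFS resampling*: bootstrap-size draws with replacement. Subsample
  fraction and replacement are exposed as options since the calibration
  of the binomial null depends on them (see below).
* *Difference report sign*: classes are ordered lexicographically and
  the convention is printed in the output header (negative = higher mean
  relative abundance in the second class).
* *BIOM dialects*: BIOM 1.0 JSON (dense and sparse) is the fully
  supported dialect for reading and writing; BIOM 2.1 HDF5 is read
  through the same operation on a best-effort basis (HDF5 fixtures are
  binary, so this path is not exercised by the text-only test suite).

## Known limitations

**Plug-in bias is cardinality-dependent.** A 10-bin feature's MI
estimate carries roughly $9/(2M\ln 2)$ bits of positive bias against a
binary label, a 2-state feature's roughly $1/(2M\ln 2)$; CMI doubles the
slice bias. Criteria that sum pairwise CMI terms (JMI, CIFE) therefore
systematically favor high-cardinality candidates at small $M$. The
estimators are compared against brute-force oracles to $10^{-12}$, so
this is a property of the estimator, not an implementation defect.

**A fully hidden parity pair is invisible to any greedy start.** If both
members of an XOR pair are exactly marginally independent of the class,
every class-independent noise feature weakly dominates both members
under every criterion at every step *until one member has been
selected*: a member's score is $0 - \alpha\Sigma\mathsf{I} +
\beta\Sigma\mathsf{I}(\cdot|Y)$ while a noise feature adds its
(almost surely positive) empirical marginal MI to the same bias terms.
Once one member enters $F$ — by tie-break or exhaustion — JMI's
conditional-redundancy term pulls the partner in *immediately* (the pair
is adjacent in the full JMI ranking; the tests assert this), but no
relevancy-started greedy search can place the pair early. Detecting such
pure interactions requires either one member to carry some marginal
signal (the partially-observable interaction demonstrated in the test
suite, where JMI selects the partner second while MIM ranks it last) or
an exhaustive pair search, which is out of scope.

**The NPFS binomial null is anti-conservative on one finite dataset.**
The test treats a feature's $B$ selection indicators as independent
Bernoulli$(k/K)$ trials. Bootstrap replicates of a single dataset are
not independent: whatever chance feature–label associations the realized
table carries persist across replicates, concentrating counts on the
same features. On pure-noise tables at $K = M = 100$, $k = 5$, $B =
100$, $\alpha = 0.05$ the package's own acceptance check measures a mean
declared-relevant fraction of $\approx 0.15$, versus $0.028$ expected
under a perfectly exchangeable null. The inflation shrinks as $M$ grows
(chance associations concentrate near zero) and can be reduced by
subsampling less than the full dataset per replicate — at the price of
noisier per-replicate selections. Treat NPFS relevance calls at small
$M$ as a ranking with a data-driven cutoff, not as a calibrated
$\alpha$-level test.

**The CV-minimizing lasso penalty over-selects.** The
prediction-optimal $\lambda$ is known not to be model-selection
consistent: on a strong 5-feature sparse signal at $K = 500$, $M = 100$
the cross-validated path recovers all five planted features in every
seed, but carries dozens of extras whose coefficients are small. The
ranked output (ordered by $|\theta_j|$) puts the true support first;
users wanting a sparser set should read the top of the ranking or
choose a larger $\lambda$ from the reported CV curve rather than trust
the support size at the CV minimum.

## Reproducibility contract

Every stochastic operation (NPFS bootstraps, CV folding, the generator)
takes an explicit integer seed and derives any per-replicate seeds
arithmetically from it; worker counts, scheduling and platform do not
change results. All tie-breaks are deterministic (lowest index / larger
penalty). Two runs with the same inputs and seed produce byte-identical
output files.
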