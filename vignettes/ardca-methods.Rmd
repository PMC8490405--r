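---
title: "Autoregressive generative models of protein families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autoregressive generative models of protein families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ardca)
```

## The model

A protein family is summarized by a multiple sequence alignment: M rows
(homologous sequences) by L columns (aligned positions), each entry one of
the 20 amino acids or the alignment gap, so q = 21 states. The package
models the joint distribution of full-length sequences by the exact chain
factorization

$$P(a_1, \ldots, a_L) \;=\; P(a_1)\,P(a_2 \mid a_1)\cdots
P(a_L \mid a_{L-1}, \ldots, a_1),$$

with each conditional parameterized as a soft-max (multinomial logistic)
regression on the one-hot encoded prefix:

$$P(a_i \mid a_{i-1}, \ldots, a_1) \;=\;
\frac{\exp\{h_i(a_i) + \sum_{j<i} J_{ij}(a_i, a_j)\}}
     {z_i(a_{i-1}, \ldots, a_1)} .$$

The couplings are *directed* and strictly triangular — $J_{ij}$ exists only
for $j < i$ — unlike the symmetric couplings of pairwise Potts models
(bmDCA/plmDCA-style direct coupling analysis). The parameter count is the
same, but three consequences of the factorized form drive everything in
this package:

1. **Exact likelihood and gradient.** Each parameter appears in exactly
   one conditional, so maximum-likelihood training decomposes into L
   independent soft-max regressions whose gradients are plain data
   averages — no MCMC estimation anywhere.
2. **Exactly normalized probabilities.** Normalization requires L sums
   over q states instead of one sum over $q^L$ sequences, so
   `log_probability()` returns true log-probabilities. This enables exact
   entropy estimation and cross-family log-odds scores.
3. **Ancestral sampling.** I.i.d. sequences are drawn position by
   position along the model order; there is no decorrelation time to
   monitor.

All probabilities and entropies are in natural log units (nats)
throughout; decimal logarithms appear only in the sequence-space
summaries.

## Site order

The chain rule is valid for any permutation of the positions, but the
one-layer soft-max parameterization is not permutation invariant:
different orders yield genuinely different fitted models. The package
default is the *entropic order*: sites sorted by increasing empirical
column entropy $s_i = -\sum_a f_i(a)\log f_i(a)$, i.e. most conserved
first, with ties broken by the original column index so the order is
deterministic. The entropies used for ordering are computed from
reweighted, pseudocount-free frequencies, so the order reflects raw
conservation. Direct (1..L), seeded random, and user-supplied orders are
available; the fit report's mean log-likelihood is the quantity to compare
across orders. No search over the L! orders is attempted. All user-facing
coordinates (mutational scans, contact pairs, samples) are reported in
original alignment columns; the permutation is an internal detail carried
inside the model and its serialized archive.

## Training

`ardca()` maximizes, per model position, the reweighted mean conditional
log-likelihood minus L2 penalties:

$$\frac{1}{M_\mathrm{eff}} \sum_m w_m \log P(a_i^m \mid \mathrm{prefix}^m)
\;-\; \lambda_h \lVert h_i \rVert^2 \;-\; \lambda_J \lVert J_i \rVert^2 .$$

Conventions that matter for reproducibility, since different codebases
differ silently on them:

* **Mean, not sum.** The likelihood is normalized by
  $M_\mathrm{eff}$, so the published regularization strengths are
  comparable across family sizes. This convention is recorded in the
  model metadata.
* **No 1/2 factor** on the penalties: the gradient contribution is
  $-2\lambda\theta$.
* **Presets.** `"generative"` uses $\lambda_J = 10^{-4}$,
  $\lambda_h = 10^{-6}$; `"effects_contacts"` uses $\lambda_J = 10^{-2}$,
  $\lambda_h = 10^{-4}$. Weak regularization gives the best generative
  statistics; mutational-effect and contact prediction degrade with large
  parameters and want the stronger setting.
* **Optimizer.** Low-storage BFGS (`stats::optim(method = "L-BFGS-B")`)
  with the exact analytic gradient; convergence when the sup-norm of the
  gradient falls below `grad_tol` (default 1e-5, `max_iter` 500). At
  $\lambda = 0$ that gradient *is* the moment-condition residual
  $f_i(a) - \langle P(a_i = a \mid \mathrm{prefix})\rangle_D$, which the
  test suite checks directly.
* **First position.** Unconditioned; at $\lambda_h = 0$ the closed form
  $h_1(a) = \log f_1(a) + \mathrm{const}$ applies (frequencies floored at
  $10^{-12}$), otherwise the same optimizer restricted to fields.
* **Gauge.** The soft-max is over-parameterized (adding a constant to a
  field row, or to a coupling column, changes nothing after
  renormalization). No explicit gauge is fixed; the L2 penalty selects
  one implicitly. Predictions are gauge invariant — asserted numerically
  in the tests — but raw parameter values are only comparable between
  runs of this package, not across implementations. On data with little
  or no true covariation the fitted couplings therefore carry
  finite-sample noise of order $M^{-1/2}$ scaled by inverse frequencies
  plus regularization-damped gauge drift; the tests check coupling
  smallness at that scale, and in gauge-invariant quantities (conditional
  distributions) where exactness is meaningful.

Sequence reweighting follows the standard inverse-neighbourhood rule:
$w_m = 1/|\{m' : \mathrm{identity}(m, m') \ge \theta\}|$ at
$\theta = 0.8$. Identity is plain Hamming identity over all L columns
with the gap as an ordinary 21st symbol — gap–gap positions count as
matches. This is the simplest deterministic reading of "80% sequence
identity"; it is exposed as `theta` and documented here because
conventions that ignore gap columns exist and give slightly different
$M_\mathrm{eff}$.

## Downstream quantities

**Statistical energy.** $E = -\log P$; lower is more family-like. Unlike
Potts models, $E$ is not a sum of parameters — it contains the local
partition functions — so all energy differences are computed from
conditionals, never from raw parameters.

**Mutational scans.** $\Delta E(a_i \to b) = E(\mathrm{mutant}) -
E(\mathrm{reference})$ for all L × q single substitutions
(`dms_scan()`). A substitution at model position p leaves conditionals
before p untouched, so the scan recomputes only the affected logits and
local partition functions; the result is contractually equal to naive
full-energy differences (tested to 1e-10). $\Delta E$ depends on the
whole reference background whenever couplings are nonzero — a property,
not a bug, and itself asserted in the tests.

**Epistasis and contacts.** $\Delta\Delta E(b_i, b_j) =
\Delta E(\mathrm{double}) - \Delta E(i) - \Delta E(j)$ defines effective
pairwise couplings relative to one reference sequence
(`effective_couplings()`). Each pair's q × q block is shifted to zero-sum
gauge, reduced to a Frobenius norm, and APC-corrected
(`contact_scores()`). Design choices, each exposed as an argument:

* The gap state is excluded from the Frobenius norm by default
  (standard DCA practice); `exclude_gap = FALSE` retains all q states.
* Ranked predictions mask pairs with $|i - j| <$ `min_sep` (default 5,
  the PPV-curve convention); the APC itself is computed on the full
  score matrix.
* One reference sequence, defaulting to the first record of the MSA, not
  an average over backgrounds: predictions hardly depend on the choice
  (the test suite requires Spearman > 0.9 between rankings from two
  references on the synthetic fixture), and a single background is M
  times cheaper.

**Entropy and sequence-space size.** Because probabilities are
normalized, $S = \langle E \rangle_P$; `estimate_entropy()` averages the
energy of n i.i.d. samples (default $10^4$, chosen so the reported
Monte-Carlo standard error is small relative to typical per-site
entropies) and reports that standard error. `exact_entropy()` is the
enumeration oracle, capped at $q^L \le 10^6$ by default (a second on one
CPU). `sequence_space_report()` converts entropies to decimal logarithms
and never leaves log space, so a length-112, q = 21 family with 1.4
nats/site yields $10^{68.1}$ compatible sequences out of $10^{148.1}$ —
a fraction of $10^{-80}$ — without overflow.

**Profile baseline.** `profile_fit()` is the independent-site model
$P = \prod_i f_i(a_i)$ with a default pseudocount of 0.01 so unseen
states keep finite log-probabilities; its entropy is the exact sum of
column entropies. It is the null model against which covariation-aware
results are judged: equal likelihood bounds, PCA collapse, and log-odds
accuracy comparisons all use it.

**PCA projections.** One-hot features (all q states including the gap —
gap patterns carry cluster structure), weighted mean-centering and
covariance from the *natural* data only, all datasets projected on those
two loadings, each loading's largest-magnitude entry made positive so
signs are reproducible.

**Subfamily log-odds.** $\log P_1 - \log P_2$ with exact normalized
probabilities, so scores from two independently trained models are
directly comparable — the capability that unnormalized Potts weights
lack.

## Synthetic fixtures and what they do (and do not) show

All tests run on synthetic data with known ground truth
(`random_armodel()`, `random_potts_exact()`, `two_subfamily_msa()`,
`two_cluster_msa()`), reproducible bit-exactly from a seed:

* The Potts fixture enumerates all $q^L$ probabilities and samples
  *exactly* (inverse-CDF over the enumerated distribution), so contact
  recovery is tested free of MCMC error. Default study condition:
  L = 12, q = 4, six strongly coupled pairs (unit-scale Gaussian
  coupling blocks over weak fields of scale 0.3, separation ≥ 2),
  M = 2×10⁴ sequences — small enough to enumerate (4¹² ≈ 1.7×10⁷),
  large enough that the six planted pairs dominate sampling noise.
* The two-subfamily fixture (L = 12, q = 8, 1500 training and 500
  held-out sequences per subfamily, four diverged sites, shared coupling
  topology with independently drawn coupling values) emulates two
  subfamilies distinguished partly by covariation that a profile model
  cannot see; the classification test requires the autoregressive
  log-odds to be at least as accurate as the profile log-odds.
* The two-cluster fixture mixes two sharply peaked profiles; it drives
  the PCA checks (cluster separation along PC1; profile samples of the
  mixture collapse to less than half the autoregressive samples' mean
  projected radius).

What these fixtures deliberately do not emulate: phylogenetic
correlation (samples are i.i.d., so reweighting is exercised only on
duplicates and near-duplicates), alignment errors, gap stretches, and
the long-tailed family-size and conservation profiles of real Pfam
alignments. Passing tests therefore certify the estimator and its
algebra, not performance claims on natural families.

Problem sizes used by the test suite and the acceptance script —
recovery from 5×10⁴ samples of an L = 8, q = 4 truth; 10-model entropy
checks at L = 5, q = 3 with 10⁴ samples; the contact fixture above —
were chosen so each stage completes in minutes on one CPU while keeping
Monte-Carlo error well inside the asserted tolerances.

## Numerical choices

* Every local partition function is computed by log-sum-exp with max
  subtraction; conditionals are overflow-safe for any parameter scale.
* Frequencies mix with the pseudocount as
  $(1-\alpha)f + \alpha/q$ (pairs: $\alpha/q^2$). Training statistics
  use $\alpha = 0$ — the moment conditions are stated for raw
  frequencies — while the profile default is $\alpha = 0.01$.
* Three-point correlations are evaluated on a seeded uniform subsample
  of (i, j, k, a, b, c) tuples (default 10⁵) rather than the full
  $O(L^3 q^3)$ tensor; Pearson comparisons are stable under this
  subsampling.
* Entropic-order ties break by ascending column index; ranked contact
  lists break score ties lexicographically by (i, j). Both make outputs
  deterministic.
* Model archives are a single binary container: magic bytes, a
  length-prefixed JSON header (dimensions, alphabet, order, training
  provenance, format version), then flat little-endian float64 arrays
  for h and J. The format contains no timestamps, so save → load → save
  is byte-identical; loading validates the format version and array
  lengths against the header and names the offending field.
* APC uses off-diagonal row/column means. On a separable (rank-one)
  score matrix it cancels the separable structure to first order, not
  exactly, because the zeroed diagonal breaks exact separability; the
  test asserts the first-order cancellation.

## Known limitations

* One-layer conditionals: no hidden layers, so strongly higher-order
  constraints are captured only through the chain of pairwise terms.
* No in-filling of partial sequences and no temperature-modified
  sampling; the sampler draws complete sequences at the trained
  distribution.
* Inverse-neighbourhood reweighting cannot represent genuinely
  hierarchical phylogenetic structure; it only damps duplication.
* Raw parameters are gauge-dependent; only likelihoods, energies, and
  energy differences are comparable across fits.
* Training is quadratic in L per sequence and the reweighting is
  $O(M^2 L)$ (in C++); families with $M \gtrsim 10^5$ will want
  subsampling or precomputed weights.
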