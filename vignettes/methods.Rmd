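---
title: "Methods: composite network construction and label-propagation scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite network construction and label-propagation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprop)
```

## The problem

Guilt-by-association function prediction asks: given a set of genes known to
share a function, which other genes in the genome are most likely to share
it? Evidence lives in many heterogeneous networks — physical interactions,
co-expression, shared protein domains, genetic interactions — each noisy and
partial, organized into evidence groups. `netprop` integrates them into one
composite network per query and diffuses the query labels over it.

## Model and procedure

**Universe.** All matrices are indexed against a fixed gene universe: the
ordered primary identifiers of the organism, with a case-insensitive synonym
map. Matching is case-insensitive because gene symbol capitalization varies
across sources; a synonym claimed by two different genes is a hard error
rather than a silent first-wins assignment, since a misassigned name would
corrupt every downstream matrix.

**Normalization.** Each source network $W_k$ (symmetric, non-negative, zero
diagonal) is normalized as $\bar W_k = D_k^{-1/2} W_k D_k^{-1/2}$ with $D_k$
the diagonal of row sums. This bounds every entry and the spectral radius of
$\bar W_k$ by 1, making networks comparable regardless of their raw weight
scales and edge densities, and guaranteeing the propagation system below is
well conditioned. Normalization happens before weighting and combination;
display provenance retains the raw pre-normalization weights so users see
the original measurements.

**Weighting.** The composite is $W^* = \sum_k \alpha_k \bar W_k$. The
`equal` and `group` methods are deterministic baselines. The `adaptive`
method fits $\alpha$ to the query: for every gene pair with at least one
query endpoint, the target is 1 (both endpoints in the query) or 0 (exactly
one), and the predictors are the networks' normalized weights on that pair.
Pairs touching no query gene are uninformative about co-membership and are
excluded, which also keeps the regression size at
$\binom{|q|}{2} + |q|(n-|q|)$ rows. The fit is non-negative least squares
with an unpenalized intercept and a ridge penalty (default $10^{-3}$) on the
network coefficients, solved by a Lawson–Hanson active-set iteration in
which the intercept is permanently passive. The ridge stabilizes collinear
(near-duplicate) networks — without it the split between two copies of the
same network is arbitrary; with it they share the weight equally. Negative
coefficients cannot occur by construction; if all coefficients are zero
(no network touches any query pair) the method falls back to equal weights
with a warning, and weights are rescaled to sum to 1 so that $\lambda$ has
the same meaning across methods. With fewer than two resolved query genes
there are no query–query pairs, so the query pipeline silently uses equal
weights in that case.

**Propagation.** Query genes are labeled $y_i = 1$, all others 0, and
scores solve the Gaussian-field system
$(I + \lambda L^*) f = y$ with $L^* = D^* - W^*$ the composite Laplacian.
This form was chosen over teleport-style random-walk variants because it is
symmetric positive definite for every $\lambda \ge 0$, reduces exactly to
$f = y$ at $\lambda = 0$, and obeys a maximum principle: with 0/1 input all
scores lie in $[0,1]$, which makes them directly comparable across queries.
$\lambda$ (default 1) trades label fidelity against smoothness over the
network; the default keeps the identity and smoothness terms on the same
scale after normalization.

**Ranking and display.** Non-query genes with positive score are ranked by
score, ties broken by universe index so output is deterministic. For
display, the composite's per-pair provenance is re-aggregated into at most
one edge per evidence group per pair; the group edge weight is the sum of
$\alpha$-scaled contributions, so summing a pair's display edges over groups
reconstructs the composite entry to within accumulation error ($<10^{-9}$ in
the test battery). Attribute nodes (e.g. protein domains) are ranked by the
sum of the scores of result genes carrying them — a deliberate construction
that favours attributes shared by many high-scoring genes; zero-score
attributes are dropped. Enrichment of the result set uses the one-sided
hypergeometric upper tail with Benjamini–Hochberg q-values, the field
default for annotation tables.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 1 | smoothing strength of the propagation (unitless; 0 = no diffusion) |
| `ridge` | 1e-3 | penalty on adaptive network coefficients |
| `n_related`, `n_attributes` | 20 | result-list truncation (0 shows only the query's own connectivity) |
| `k` (profile import) | 50 | neighbours kept per gene in co-expression sparsification |
| `tol`, `max_iter` | 1e-10, 10n | conjugate-gradient stopping rule |

Co-expression conversion uses Pearson correlation, keeps only positive
correlations, and retains each gene's `k` strongest partners with union
symmetrization (an edge survives if either endpoint selects it), so
increasing `k` only ever adds edges. Positive-only top-`k` Pearson mirrors
common co-expression practice and keeps networks sparse; zero-variance genes
are excluded rather than erroring because constant rows are routine in real
profiles. Missing values are rejected — imputation policy is out of scope.

## Numerical choices

The propagation system is solved by conjugate gradients with a relative
residual tolerance of $10^{-10}$ — effectively exact at the problem sizes the
engine targets — warm-started at $f = y$, which is already exact on isolated
genes; those coordinates are also set to their labels explicitly after the
solve since they decouple from the system. Solutions are clipped to $[0,1]$
to remove sub-$10^{-12}$ rounding spill outside the provable bounds.
Duplicate edge rows are summed (consistent with the composite's
collapse-by-sum), self-edges are dropped with a count (the diagonal is
handled by the identity term of the system), and binary persistence stores
upper-triangle CSR with 8-byte floats, making write/read round trips
bit-exact. All lexicographic orderings (autocomplete, tie-breaks) use C
collation so results do not depend on the session locale.

## The synthetic generator

`generate_fixture()` materializes a planted-partition organism: the first
`n_modules * module_size` genes form modules; within-module pairs get an
edge with probability 0.4 and weight Uniform(0.5, 1), background pairs with
probability 0.02 and weight Uniform(0, 0.3); each evidence group receives
its own independent draw. The expression profile gives each module a latent
factor per sample and each module gene that factor plus Gaussian noise
(effect size 1, noise sd 0.5, 20 samples), so module genes correlate at
roughly $1/(1+\sigma^2) = 0.8$ while background genes are pure noise. The
defaults (200 genes, 4 modules of 25, three groups) are small enough that a
full recovery-plus-cross-validation battery over 20 seeds runs in seconds,
yet large enough that module structure is statistically unambiguous. One
seeded RNG stream drives everything, and the stream is restored afterwards,
so fixtures are byte-reproducible and do not perturb the caller's RNG.

What the generator does **not** emulate: heavy-tailed degree distributions,
assortativity, batch structure in expression data, annotation incompleteness
or cross-annotation overlap. Passing the planted-module battery therefore
demonstrates the engine's mechanics — normalization, weighting, propagation,
ranking — not calibrated performance on real organisms, where signal is far
weaker and evidence far more redundant.

## Design decisions taken where the design was open

- **Weighting algorithm.** The adaptive NNLS-with-intercept regression is
  this package's own documented construction; it reproduces the qualitative
  behaviour required of query-dependent integration (informative networks
  up-weighted, irrelevant ones near zero) with a fully testable definition.
- **Case-insensitive identifier matching**, with collisions as errors (see
  above).
- **Attribute scoring** by score-weighted incidence sums is likewise our
  construction; display conventions show at most one edge per group.
- **Scores are reported raw**, not post-normalized to sum to 1: raw
  Gaussian-field solutions are bounded in $[0,1]$ and comparable across
  queries at fixed $\lambda$.
- **Transductive cross-validation**: held-out positives leave the query but
  stay in the network, matching how the scorer would be used in practice.
- **Binary format**: a documented CSR upper-triangle layout (`GMNW`,
  version 1, little-endian) rather than any production format; metadata is
  embedded as JSON so files are self-describing.

## Problem sizes used in the shipped checks

The test suite and the reproduction script run at deliberately compact
scale: oracle comparisons on random graphs with $n \le 50$ (100 instances),
planted-partition batteries at $n = 200$ over 20 seeds, and importer round
trips at $n \le 200$. These sizes make every check exact or
statistically unambiguous; the engine itself is sparse end-to-end
(CSC matrices, CG solves) and has no structural limit tied to these sizes.

## Known limitations

- Negative correlations and inhibitory relationships are discarded;
  only non-negative edge weights are representable.
- The adaptive regression treats pairs as independent observations and
  fits a single intercept; it does not replicate any particular production
  system's bias constants.
- No GO-DAG-aware annotation propagation; annotation sets are flat.
- Networks must fit in memory; there is no streaming store.
- One organism per database; no cross-organism identifier mapping.
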