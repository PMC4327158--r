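---
title: "Estimating antibody-specific substitution models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating antibody-specific substitution models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(absubst)
```

## The substitution model

`absubst` models amino-acid replacement during antibody affinity
maturation as a time-homogeneous, reversible continuous-time Markov chain
on the 20 amino acids, applied independently to each homologous site of an
alignment along a genealogy.  Reversibility decomposes each instantaneous
rate as $q_{ij} = s_{ij}\pi_j$ ($i \neq j$) with a symmetric
exchangeability matrix $S$ and stationary frequencies $\pi$; transition
probabilities over a branch of length $t$ are $P(t) = e^{tQ}$.  Every
model is normalized to $\sum_{i\neq j} s_{ij}\pi_i\pi_j = 1$, so branch
lengths read as expected substitutions per site.

These are strong assumptions.  Time homogeneity ignores the episodic
nature of germinal-center reactions; site independence ignores the
nucleotide context dependence of AID targeting (the WRC hotspot motif
operates on codons, not residues); a single matrix pools framework and CDR
positions whose selective regimes differ.  The Γ+I site-rate model absorbs
much of the last point: four discrete gamma categories plus an invariant
class let conserved framework positions and hypervariable loop positions
coexist under one matrix, with the gamma shape $\alpha$ and invariant
proportion $p_{inv}$ fitted per alignment (bounded search,
$\alpha \in [0.02, 100]$, $p_{inv} \in [0, 0.99]$).

Rate-category conventions, stated once: categories are equal-probability
gamma bins represented by their bin *means* (not medians), each with
weight $(1-p_{inv})/K$; the invariant class sits at rate 0 with weight
$p_{inv}$; the non-invariant rates are rescaled so the overall mean rate
is exactly 1.  A site is invariant-eligible exactly when all rows share
one residue.

## Homogeneous alignments instead of gap-rich MSAs

CDR3 length varies so much between clonotypes that conventional multiple
alignment must introduce gaps without resolving residue homology, and
model estimates inherit those alignment errors.  The package instead
*sorts* sequences into homogeneous groups — identical lengths in all seven
fragments FR1–FR4/CDR1–3, and in NGS mode additionally the same
best-matching germline V/(D)/J segments — so that each group is a gapless
alignment whose columns are homologous by construction.  Groups need at
least 3 sequences; NGS-scale groups are capped at 850 sequences (split
into near-equal contiguous chunks in input order) and discarded below 175.
Fragment lengths come from an annotation sidecar or from germline
assignment; re-implementing full IMGT numbering is out of scope.
Germline assignment itself is local (Smith–Waterman) alignment against the
segment libraries, restricted to each class's expected position window (V
in the first 75% of the query, J in the last 40%, D between the V and J
hits), BLOSUM62 scoring with gap open 11 / extend 1, ties broken by
library order with a warning.

## Genealogies

Within a homogeneous group the phylogenetic signal is shallow somatic
divergence from one rearrangement.  The package therefore fixes the
topology to a neighbor-joining tree built on pairwise maximum-likelihood
distances under the current model and optimizes branch lengths only; full
heuristic topology search would add cost far out of proportion to its
effect on the pooled, repertoire-level exchangeability estimates, and
externally inferred Newick trees can be supplied wherever a tree argument
is accepted.  Branch-length optimization is exact coordinate ascent: each
cycle runs one post-order pass, then a pre-order sweep that keeps the
above-edge partial likelihoods current as lengths update, so every scalar
search maximizes the true likelihood given all other branches and the
cycle-level log-likelihood never decreases.  Branches live in
$[10^{-8}, 10]$; NJ estimates below $10^{-6}$ (including the zero
distances of identical sequences) are clamped with a warning.

## The EM estimator

Given genealogies and site-rate parameters, the exchangeabilities are
estimated by expectation-maximization.  The E-step computes, per branch,
site and gamma category, the conditional expectations of substitution
counts $C_{ij}$ and dwell times $W_i$ given the tip data, using the
closed-form spectral integrals available for reversible generators
($\pi^{1/2}$-symmetrization makes $Q$ diagonalizable with real
eigenvalues; the same decomposition serves $e^{tQ}$).  Category
contributions are weighted by posterior category membership, and times are
accumulated on the category-rescaled clock, which is exactly the scale on
which the M-step
$$\hat s_{ij} = \frac{C_{ij}+C_{ji}}{W_i\pi_j + W_j\pi_i}$$
is the complete-data maximizer.  The test suite pins the E-step to a
Monte-Carlo endpoint-conditioned path oracle and, more stringently, to the
Fisher identity: the analytic gradient implied by $(C, W)$ must match the
numerical gradient of the pruning log-likelihood.

Two details keep the EM ascent exact:

* **Normalization.**  After each M-step the model is rescaled to the
  unit-mean-rate convention and *all branch lengths are multiplied by the
  same factor*, leaving $Q\,t$ — and hence the likelihood — unchanged.
  Normalizing without rescaling would break monotonicity.
* **Unobserved exchanges.**  An additive pseudocount in the numerator was
  considered and rejected: on desk-scale data it hands unobserved pairs
  rates far above their likelihood optimum (the dwell denominators of rare
  residues are small), which measurably *decreases* the joint
  log-likelihood and destabilizes late iterations.  Instead, pairs whose
  expected counts are numerically zero receive a positivity floor several
  orders below the smallest data-supported estimate
  ($\lambda \cdot 10^{-6} \cdot \min \hat s_{\mathrm{obs}}$ with
  $\lambda = 0.05$).  The floor exists only so the relative-difference
  diagnostic and downstream divisions stay defined; it cannot influence
  the fit.  With no observed exchanges at all the estimator degenerates to
  the uniform model.

`em_fit` pools $(C, W)$ over all alignments, iterates to a $10^{-4}$
joint-log-likelihood tolerance, and aborts if the likelihood ever drops by
more than $10^{-6}$ — with the design above, such a drop can only signal a
defect, not a policy artifact.

## The learning schedule

`fit_ab_model` alternates (1) genealogy re-inference under the current
best model — NJ start, branch-length optimization, per-alignment
$(\alpha, p_{inv})$ — with (2) EM re-estimation, for a fixed number of
rounds or until the monitoring criterion (held-out per-site
log-likelihood when a test set is supplied, else the training joint
log-likelihood) stops increasing.  Each round's model is kept as a
candidate.  Convergence is monitored by
$\Delta_{ij} = |(s_{ij}-s^*_{ij})/s_{ij}|$ averaged over the 190 unordered
pairs (unordered because $S$ is symmetric; the mean over ordered pairs
would be identical anyway for this symmetric statistic).

Frequency policies mirror standard practice: `"train"` (recommended)
estimates $\pi$ empirically over the whole training collection and holds
it fixed — per-alignment empirical frequencies are noisy for small, highly
similar antibody groups; `"learn"` re-estimates $\pi$ inside EM from
normalized dwell times; `"model"` keeps the initial model's frequencies.
Frequencies are floored at $10^{-6}$ and renormalized (the
exchangeability transform divides by $\pi$); normalization always uses the
same $\pi$ vector that builds $Q$.

## Bootstrap confidence analysis

Columns are resampled with replacement independently within each
alignment, and the *entire* estimation pipeline (including tree
re-inference) is re-run per replicate; per-replicate seeds derive from the
master seed by replicate index, so replicates are order-independent and
reproducible.  A reference exchangeability is declared significantly
different for a pair when it falls outside the central
$[0.025, 0.975]$ bootstrap interval of that pair, with type-7
(interpolated order-statistic) quantiles — stated explicitly because the
convention affects verdicts at small $B$.  Both ensemble and reference are
normalized before comparison, making verdicts invariant to joint
rescaling.

## Network modularity

An exchangeability matrix is read as a weighted network on 20 nodes with
weights $w_{ij} = s_{ij}$ (frequencies play no role, and rescaling all
weights changes nothing).  For a partition into clusters $s = 1..r$,
$$M = \sum_s \left[\frac{l_s}{L} - \left(\frac{d_s}{2L}\right)^2\right],$$
with $l_s$ the within-cluster weight, $d_s$ the summed node strength of
the cluster and $L$ the total weight.  The node-strength convention for
$d_s$ (within-cluster weight counted twice) is the one consistent with the
documented properties of the score — the single all-inclusive cluster at
$M = 0$ and the range $[-0.5, 1]$; the alternative reading of "at least
one end in the cluster" puts the trivial single cluster at $M = 0.75$ and
is rejected.  $M > 0.3$ is the conventional threshold for a clear modular
structure.

Maximization uses greedy agglomeration from singletons followed by
Kernighan–Lin-style single-node reassignment, restarted over random node
orders (deterministic under a seed).  On 20-node networks this attains the
certified global optimum: the test suite checks it against exhaustive
enumeration of all partitions up to 6 nodes, and for the bundled LG matrix
the result coincides with an exact integer-programming solution computed
independently.  The maximized modularity this package obtains for the
published LG matrix is 0.333 (4 clusters: aromatic, aliphatic,
charged/polar, small), which the acceptance suite compares against the
value of 0.38 reported for that matrix in the literature; the
discrepancy is recorded rather than absorbed, since the optimum here is
certified and the historical optimizer and its exact weight convention are
not reproducible.

## Model comparison

`fit_table` reports optimized per-site log-likelihoods per alignment and
model (tree, branch lengths and Γ+I parameters re-fit per cell, or fixed
trees on request).  Paired model comparisons use the Wilcoxon signed-rank
test with the alignment as the pairing unit, two-sided by default
(one-sided available), zero differences dropped, exact null up to 25
non-zero pairs and the continuity-corrected normal approximation beyond —
conventions stated because they are not universal.

## The synthetic-repertoire generator

`simulate_repertoire` emulates the data the estimator is built for: sets
of same-length sequences descended from a common germline-like root along
a random genealogy, evolved under a known reversible model with Γ+I rates
and region-structured rate multipliers.  Defaults define the package's
study conditions and are chosen once:

* fragment lengths (13, 8, 17, 8, 38, 12, 4) — 100 sites, the
  repertoire-average variable-region length;
* 20 alignments of 25 sequences — a mid-sized training repertoire;
* exponential branch lengths with mean 0.05 substitutions/site — shallow
  somatic divergence, consistent with one-to-two mutations per cell
  generation accumulating over a germinal-center reaction;
* $\alpha = 1$, $p_{inv} = 0.1$ — moderate heterogeneity on top of the
  regional contrast;
* CDR:FR multipliers 3:0.5, rescaled to length-weighted mean 1 — CDR
  columns evolve several-fold faster than framework columns.

What the generator does *not* emulate bounds what green tests prove about
real data: there are no indels (real homogeneous groups avoid them by
construction, but the sorting step that achieves this is exercised only on
synthetic annotations), no nucleotide-level hotspot context, no selection
or clonal structure in the genealogy law, and no sequencing error beyond
what the quality filter removes.  Parameter-recovery results therefore
validate the estimator under its own model class, not the model's adequacy
for any particular repertoire.

## Numerical choices

Matrix exponentials and the E-step integrals share one symmetric
eigendecomposition per model; partial likelihoods are rescaled per node by
scalar factors with accumulated logs (uniform per-node factors keep
per-site values exact); transition-probability entries are clamped at 0
and rows renormalized; eigenvalue differences below $10^{-9}$ switch the
spectral integral to its confluent limit.  Pairwise ML distances are
bounded by 10 substitutions/site.  Degenerate inputs are either repaired
with a message (frequency flooring, branch clamping) or rejected with the
offending entry named (asymmetric matrices, zero reference
exchangeabilities, mismatched leaf sets, all-zero Wilcoxon pairings).

Problem sizes in the test suite are the package's own choices: exhaustive
likelihood oracles run on 4–5 taxon, ~10-site fixtures; the
parameter-recovery study uses the generator defaults above; Monte-Carlo
E-step validation uses 40,000 endpoint-conditioned paths on a single
branch.

## Known limitations

Single matrix for FRs and CDRs (region-specific matrices are attractive
but framework positions alone carry too little signal at desk scale);
fixed NJ topologies; no rooting by germline concatenation (trees are
unrooted, likelihoods are rooting-invariant by reversibility); no
nucleotide- or codon-level modelling; the bootstrap treats alignments as
fixed groupings and does not propagate sorting uncertainty.
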