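# absubst

Estimation of antibody-specific amino-acid substitution models from
repertoires of immunoglobulin variable-region sequences.

## The problem

Somatic hypermutation diversifies rearranged antibody genes at rates many
orders of magnitude above background mutation, and the selective forces
acting on the antigen-binding loops are diversifying rather than
conservative.  General-purpose amino-acid substitution models (LG, WAG)
were estimated from ordinary proteins under purifying selection and
misrepresent this process: phylogenies, alignments and evolutionary
distances computed for antibody repertoires under such models can be
systematically wrong.  `absubst` estimates an *empirical, antibody-specific*
substitution model directly from repertoire data, for immunologists and
computational biologists who build B-cell lineage trees, match heavy/light
chain pairs, or rank candidate antibodies by evolutionary distance from
their germline precursors.

## The model

Amino-acid replacement at each homologous site is a reversible
continuous-time Markov chain on the 20 amino acids with generator

    q_ij = s_ij * pi_j   (i != j),

where `S = {s_ij}` is a symmetric matrix of *exchangeabilities* and `pi`
the stationary amino-acid frequencies; transition probabilities over a
branch of length `t` are `P(t) = exp(tQ)`.  Models are normalized so that
`sum_{i != j} s_ij pi_i pi_j = 1` (one expected substitution per site per
unit time).  Site-rate heterogeneity uses four discrete gamma categories
plus a class of invariant sites (Γ+I), with the gamma shape and invariant
proportion fitted per alignment.

Estimation proceeds on *homogeneous* alignments — gapless sets of
same-length sequences whose seven structural fragments (FR1, CDR1, FR2,
CDR2, FR3, CDR3, FR4) have identical lengths, so residues are homologous by
construction.  Genealogies are inferred per alignment (neighbor-joining on
pairwise ML distances, branch lengths optimized by exact coordinate
ascent), and the exchangeability matrix is learned by an
expectation-maximization algorithm whose E-step computes expected
substitution counts `C_ij` and state dwell times `W_i` in closed form from
the eigendecomposition of `Q`, and whose M-step sets

    s_ij_hat = (C_ij + C_ji) / (W_i pi_j + W_j pi_i).

Learning alternates tree re-inference with EM re-estimation over several
rounds until the joint likelihood stops improving.  Column-bootstrap
replication gives confidence intervals for every exchangeability;
weighted-network modularity of `S` (20 nodes, weights `s_ij`) summarizes
whether substitutions cluster by physicochemical class; per-site
log-likelihood tables with Wilcoxon signed-rank tests compare models on
held-out alignments.

## Worked example

Simulate a small repertoire with known ground truth and re-estimate the
generating model:

```r
library(absubst)

truth <- random_model(seed = 40)
spec  <- repertoire_spec(n_msas = 6, n_seq = 12, model = truth,
                         alpha = 1e6, p_inv = 0, gamma_k = 1, seed = 41)
rep   <- simulate_repertoire(spec)

fit <- em_fit(rep$msas, lapply(rep$truth, `[[`, "tree"),
              equal_rates_model(empirical_frequencies(rep$msas)))
tail(fit$trace, 3)
#>    iteration    loglik mean_delta
#> 32        32 -4939.418  0.1397988
#> 33        33 -4939.418  0.1397972
#> 34        34 -4939.418  0.1397958

exchangeability_correlation(fit$model, truth)
#> [1] 0.8532556
```

The trace shows the joint log-likelihood of all alignments ascending at
every EM iteration until the per-iteration gain falls below the tolerance
(the residual `mean_delta` is carried by exchanges never observed in this
small simulation, which sit at their positivity floor).  The Pearson
correlation between estimated and generating exchangeabilities here is
0.85; it exceeds 0.95 at the package's default study size of 20 alignments
of 25 sequences.

Full pipeline on alignments read from disk, starting from the published LG
matrix and comparing the fit:

```r
msas <- lapply(list.files("msadir", full.names = TRUE),
               function(f) hom_msa(read_fasta(f)))
fit  <- fit_ab_model(msas, initial_model = lg_model(), rounds = 3)
print(fit)
cmp  <- compare_models(msas, list(fit$model, lg_model(), wag_model()))
maximize_modularity(aa_network(fit$model), seed = 1)
```

A thin command-line wrapper over the same functions ships with the package
(`system.file("cli", "absubst", package = "absubst")`) with subcommands
`sort`, `estimate`, `loglik`, `compare`, `bootstrap`, `modularity` and
`simulate`; see `?ab_cli`.

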