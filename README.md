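# cdaNetFuse

Ensemble network prediction of circRNA–disease associations.

Circular RNAs (circRNAs) are covalently closed noncoding RNAs that act as
oncogenes or tumour suppressors in many cancers; knowing which circRNA is
associated with which disease points at candidate biomarkers. Curated
databases record only a sparse set of experimentally confirmed pairs, so
the practical question is link prediction on a bipartite graph: given a
binary association matrix **Y** (m circRNAs × n diseases) and a disease
semantic-similarity matrix, score every unknown pair and rank candidate
circRNAs per disease.

`cdaNetFuse` is aimed at computational biologists who have (or can
simulate) such an extract and want a transparent, fully reproducible
network scorer with built-in cross-validated evaluation.

## The method

1. **Similarity fusion.** circRNA similarity fuses *functional
   similarity* (best-match averaging of disease semantic similarity over
   the two circRNAs' disease sets) with the Gaussian
   association-profile kernel `exp(−γ‖yᵢ−yⱼ‖²)`;
   disease similarity fuses the semantic matrix with the profile kernel
   on columns of Y. Both fusions are convex combinations with weights
   `alpha_c`, `alpha_d` (default 0.5).
2. **Random walk with restart (P).** A row-stochastic transition matrix
   over the heterogeneous circRNA–disease network (within-network moves
   renormalize the fused similarities; cross-network jumps follow
   association edges with probability `mu = 0.6`). For each query disease
   the walk iterates `p ← β Wᵀ p + (1−β) p₀` (`beta = 0.2`) from a seed
   distribution and the circRNA block of the fixed point becomes that
   disease's score column.
3. **Laplacian regularized least squares (F).** With the normalized
   Laplacian `L = D^{−1/2}(D−S)D^{−1/2}` of each fused similarity, the
   closed form `S(S + γLS)⁻¹Y` minimizes
   `‖Y−F‖²_F + γ·tr(FᵀLF)`; it is applied in circRNA and disease space
   and averaged.
4. **Soft voting.** Final scores `Ypre = P + θ·F` (`theta = 0.3`).
5. **Evaluation.** Repeated k-fold cross-validation over the positive
   pairs; all similarities are recomputed from the masked matrix inside
   every fold; AUC is the normalized Mann–Whitney statistic over held-out
   positives versus all remaining unknown pairs.

A planted-cluster synthetic generator (`generateSynthetic()`) produces
association matrices and consistent semantic matrices so the whole
pipeline is testable without any external download.

## Worked example

```r
library(cdaNetFuse)

sim <- generateSynthetic(syntheticConfig(seed = 17))
sim$associations
#> AssociationMatrix: 60 circRNAs x 20 diseases, 148 known associations
#>   circRNAs: circ001, circ002, circ003, circ004, ... (60 total)
#>   diseases: disease01, disease02, disease03, disease04, ... (20 total)

scores <- cdaScores(sim$associations, sim$diseaseSim)   # ensemble, defaults
scores
#> ScoreMatrix: 60 circRNAs x 20 diseases, scores in [0.004243, 0.2566]

rankForDisease(scores, sim$associations, "disease01", top = 5)
#>   rank circRNA_id     score known
#> 1    1    circ021 0.2531025     1
#> 2    2    circ033 0.2531025     1
#> 3    3    circ041 0.2531025     1
#> 4    4    circ053 0.2531025     1
#> 5    5    circ057 0.2496756     1

cv <- crossValidate(sim$associations, sim$diseaseSim,
                    k = 5, repeats = 3, seed = 17)
cv
#> CVResult (ensemble): 3 repeats x 5 folds, mean AUC 0.7760
#>   per-repeat means: 0.7519, 0.7903, 0.7857
#>   seed: 17
```

The ranking for `disease01` puts five of its known associations (flag
`known = 1`) on top — the model reconstructs the planted block the
disease belongs to; tied scores are circRNAs with identical profiles.
The cross-validated mean AUC of 0.776 says that a held-out true pair
outranks a random unknown pair about 78% of the time on this benchmark
(cold-start positives — circRNAs whose only association was masked — cap
this well below 1; see the methods vignette).

Real data enter through `readAssociationEdgelist()` (two-column TSV) and
`readSimilarityMatrix()` (labelled square TSV); results leave through
`writeScoreTable()`. A command-line front end with `predict`, `cv`,
`rank` and `simulate` subcommands lives at `inst/cli/cda-netfuse.R`.

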