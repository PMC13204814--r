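# smcca — sparse multiple canonical correlation analysis for multimodal brain-behavior data

`smcca` implements a penalized-matrix-decomposition (PMD) sparse multiple
canonical correlation analysis for three aligned blocks of subject-level
variables, the design used in multimodal processing-speed studies that
relate white-matter microstructure (tract mean fractional anisotropy plus
the EEG individual alpha peak frequency), demographics (age, sex,
education) and GO/NO-GO reaction-time distribution features (mean, SD and
skewness of simple and complex reaction times). It is aimed at
neuroimaging statisticians who need the full inferential pipeline —
penalty tuning, permutation significance testing, and leave-one-out
stability selection — reproducibly, at desk scale, without access to
restricted cohort data.

## The model

Given standardized blocks $X_1, \dots, X_K$ ($K = 3$, subjects in rows),
the method finds per-block weight vectors maximizing the summed pairwise
bilinear objective

$$\max_{w_1,\dots,w_K} \sum_{i<j} w_i^{\top} X_i^{\top} X_j\, w_j
\quad \text{s.t.} \quad \lVert w_i \rVert_2 \le 1,\;
\lVert w_i \rVert_1 \le c_i,$$

with one L1 budget $c_i \in [1, \sqrt{p_i}]$ per block. Each block update
is the exact projection $w_i \propto S(v_i, d)$ of the combined
cross-covariance direction $v_i = \sum_{j \ne i} X_i^{\top} X_j w_j$,
where $S$ is the soft-threshold operator and $d$ is found by bisection,
so many weights are exactly zero and the objective is monotone over
sweeps. Successive dimensions are extracted after deflating
$C_{ij} \leftarrow C_{ij} - (w_i^{\top} C_{ij} w_j)\, w_i w_j^{\top}$.
Inference is permutation-based throughout: per-block-pair canonical
correlations against row-permutation nulls with Bonferroni correction
across the three pairs, per-variable weights via the max-z (maxT)
familywise correction, L1 budgets tuned by a permutation z-score on the
Fisher-transformed summed correlations, and stability assessed by
leave-one-subject-out inclusion fractions with the 0.75/0.25
dual-threshold rule. A synthetic-data generator with a planted
cross-block factor structure stands in for the restricted study data and
makes every stage testable.

## Worked example

```r
library(smcca)

spec <- syntheticSpec(seed = 7)            # 24 subjects, study layout,
bs   <- generateBlocks(spec)               # planted two-dimension structure
bs
#> BlockSet: 24 subjects, 3 blocks (biological=19, demographic=3, behavioral=6), 28 variables total
#>   standardized columns: biological=19, demographic=2, behavioral=6

fit <- fitSmcca(bs, penalties = c(2.6, 1.0, 1.45), nDims = 2)
fit
#> SmccaFit: 3 block(s), 2 dimension(s)
#>   penalties: biological=2.6, demographic=1, behavioral=1.45
#>   dim 1: r = biological:demographic 0.596, biological:behavioral 0.874, demographic:behavioral 0.473 | nonzero = 11/1/3
#>   dim 2: r = biological:demographic 0.697, biological:behavioral 0.679, demographic:behavioral 0.817 | nonzero = 10/1/3
#>   cumulative shared variance: 44.8%, 98.6%

st <- looStability(bs, c(2.6, 1.0, 1.45), nDims = 2)
st
#> StabilityReport: 24 folds (0 failed)
#>   thresholds: stable-zero < 0.25, stable-nonzero > 0.75
#>   mean loading correlation: dim1 0.995, dim2 0.928
```

The fit prints, per dimension, the three pairwise Pearson correlations of
the realized block scores, how many weights survived the L1 budgets in
each block (11 of 19 biological, 1 of 3 demographic, 3 of 6 behavioral
here), and the cumulative average squared pairwise correlation used to
judge how many dimensions are worth keeping. The stability report says
that refitting 24 times with one subject left out reproduces the full-fit
loading pattern almost exactly (mean loading correlation 0.995 on
dimension 1) and classifies each variable as stably selected, stably
zero, or unstable. `permTestCorrelations()` and `weightSignificance()`
attach permutation p-values to the correlations and weights;
`runPipeline(runConfig(...))` runs every stage and writes the CSV report
bundle with a reproducibility manifest.

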