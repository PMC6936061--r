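# mecorank

Patient-specific cancer driver-gene prioritization by bipartite network
propagation and Condorcet rank aggregation.

## What problem this solves

Somatic mutation calls alone are a weak guide to which genes *drive* a tumor:
most observed mutations are passengers, and a damaging mutation expresses its
effect largely through the genes its protein interacts with. `mecorank` is for
computational biologists with matched tumor/normal expression, somatic SNV
calls annotated with PolyPhen/SIFT, and a protein–protein interaction (PPI)
network, who want a ranked cohort-level list of candidate driver genes.

## The method

For every tumor sample a bipartite graph **G = (U ∪ V, E)** is built over the
PPI: U holds the patient's expression genes, V the patient's mutated genes,
with an edge wherever the two genes interact. Each mutation node carries a
damage coefficient *y = 1 + p*, where *p* sums per-variant damage
probabilities (PolyPhen score for labels containing "damaging", 1 − SIFT for
"deleterious" labels). Gene scores are the fixed point of the damped,
degree-normalized propagation

```
x_i = (1 − λu)·x0_i + λu(1 − λv)·Σ_k w_ik d_k^{-1/2} y_k + λu·λv·Σ_j w_ij d_j^{-1/2} x_j
```

with λu = 0.9, λu + λv = 1, x0 the patient's standardized expression, and the
iterate initialized to differential expression (tolerance 1e-4, cap 100
iterations; mutation vertices with no expression-side edges are pruned).
Per-patient rankings (scores rescaled to [0, 1]) are aggregated by
penalty-modified Condorcet voting: in each patient, gene A beats gene B when
δ(A)·Rank(A) > δ(B)·Rank(B), where δ = 0.85 for a gene not mutated in that
patient and 1 otherwise. Pairwise outcomes are completed to a full ranking by
Copeland tally (wins − losses), and the top 100 genes are reported as
candidate drivers. Evaluation against a known-driver list provides
rank-cutoff curves, average precision P = mean(p_k), and sub-sampling
robustness.

See `vignettes/driver-prioritization-methods.Rmd` for the full model account,
parameter meanings, and design decisions.

## Worked example

Everything runs on generated data — no downloads. The synthetic cohort plants
5 driver genes (mutated damagingly in 80% of tumor samples) in a 200-gene
scale-free PPI and perturbs the expression of their network neighbors:

```r
library(mecorank)
cohort <- generate_cohort(seed = 42)
fit <- mecorank(cohort$ppi, cohort$expr, cohort$mutations,
                known_drivers = cohort$planted_drivers)
fit
#> Cohort driver prioritization
#>   50 patients, 200 candidate genes, delta = 0.85, lambda_u = 0.9
#>   convergence: 50/50 patients, median 7 iteration(s)
#>   top 10 candidate drivers:
#>  rank  gene copeland     score n_patients_mutated known_driver
#>     1 G0007      199 1.0000000                  1        FALSE
#>     2 G0028      197 0.9944751                  0        FALSE
#>     3 G0042      195 0.9889503                  1        FALSE
#>     4 G0002      192 0.9806630                  2        FALSE
#>     5 G0067      191 0.9779006                  2        FALSE
#>     ...
#>   average precision (top 100) vs known drivers: 0.0849

match(cohort$planted_drivers, fit$aggregate$table$gene)
#> [1] 16 18 19 22 20
```

Reading the output: each patient's propagation converged in single-digit
iterations; the `copeland` column is the pairwise-voting tally (wins minus
losses over all gene pairs and patients) and `score` rescales it to [0, 1].
The very top ranks are occupied by well-connected *neighbors* of the planted
drivers — the propagation boosts the genes adjacent to mutation nodes — with
the five planted drivers themselves following at ranks 16–22 of 200, lifted
by the δ penalty their unmutated competitors pay. The methods vignette
discusses this geometry and what it implies for interpreting the top of the
list.

File-based workflows mirror the same pipeline from the shell:

```sh
Rscript inst/cli/mecorank.R simulate --out cohort --seed 7
Rscript inst/cli/mecorank.R run \
    --ppi cohort/ppi.tsv --expr-tumor cohort/expr_tumor.tsv \
    --expr-normal cohort/expr_normal.tsv --maf cohort/mutations.maf \
    --evaluate cohort/truth_drivers.txt --out results
```

which writes `aggregate_ranking.tsv`, per-patient convergence, evaluation
tables and a `manifest.yaml` echoing the configuration and input checksums.

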