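# dmsbench

Benchmarking variant effect predictors (VEPs) against measurements instead
of circular labels.

Supervised VEPs are routinely trained on the same clinical databases they
are later evaluated on, which inflates their apparent accuracy. Deep
mutational scanning (DMS) experiments provide an independent yardstick:
functional scores for thousands of amino acid substitutions in a protein,
measured rather than curated. `dmsbench` implements the two complementary
benchmarks this enables, for method developers and for anyone choosing a
predictor:

1. **Correlation benchmark** — rank predictors by how well they agree with
   DMS functional scores.
2. **Clinical benchmark** — rank predictors *and DMS score sets themselves*
   by how well they separate pathogenic from putatively benign variants.

plus the concordance between the two, and bootstrap significance for every
ranking.

## The statistics at the core

**Pairwise rank score.** Predictors differ enormously in which variants
they score (nucleotide-level methods only reach substitutions one
nucleotide change away; alignment-based methods skip low-coverage
regions), so naive comparisons on different variant sets are meaningless.
Every pair of predictors is therefore compared only on the variants *both*
score (that the DMS assay also covers): each predictor's Spearman ρ
against the DMS scores is computed on that common set, and the higher ρ
wins a point (ties ½ each). With points *s* over *m* comparisons the
per-protein rank score is *s/m* ∈ [0, 1], and the overall rank score is
its unweighted mean across proteins — interpretable as the average
proportion of rivals a predictor beats. The clinical benchmark uses the
same tournament with AUROC (or AUBPRC) on shared pathogenic/benign
variants in place of ρ.

**AUBPRC.** Average precision depends on class balance, which varies
wildly between proteins. The balanced precision–recall AUC

    AUBPRC = AUPRC·(1−π) / [ AUPRC·(1−π) + (1−AUPRC)·π ],   π = |pos| / (|pos|+|neg|)

is the precision–recall AUC the method would attain on balanced classes,
comparable across proteins.

**Outranking bootstrap.** Within each protein, the shared data are
resampled with replacement B times (pathogenic and benign sets
independently in the clinical benchmark, so neither class can vanish) and
the whole tournament re-run. If method A outranks method B in *c* of B
replicates, the one-sided P-value is 1 − c/B; with B = 1000, c = 950 is
P = 0.05.

Supporting machinery: representative-assay selection (highest median |ρ|
against all predictors), a 5% minimum DMS coverage filter, restriction to
SNV-reachable missense with most-benign imputation of missing predictor
scores, a 20-residue scanning-window filter removing poorly predicted
regions, and orientation handling for inverted score scales.

## Worked example

The package ships a synthetic benchmark generator with known ground truth
(five predictors with injected Spearman correlations 0.9/0.75/0.6/0.45/0.3
to a latent fitness landscape by default):

```r
library(dmsbench)

cfg <- simulation_config(n_proteins = 3, protein_length = 60, seed = 42)
b   <- simulate_benchmark(cfg)

rc <- run_corr_benchmark(b, B = 200, seed = 42)
rc$overall
#>   predictor n_proteins rank_score
#> 1     vep01          3  1.0000000
#> 2     vep02          3  0.7500000
#> 3     vep03          3  0.4166667
#> 4     vep04          3  0.3333333
#> 5     vep05          3  0.0000000

cl <- run_class_benchmark(b, metric = "auroc", B = 200, seed = 42,
                          corr_overall = rc$overall)
cl$overall
#>   predictor n_proteins rank_score
#> 1     vep01          3 1.00000000
#> 2       DMS          3 0.74444444
#> 3     vep02          3 0.61111111
#> 4     vep04          3 0.38888889
#> 5     vep05          3 0.06666667
#> 6     vep03          3 0.05555556

cl$concordance
#> [1] 0.7
```

The correlation benchmark recovers the injected ordering exactly
(vep01…vep05; rank scores 1 → 0). In the clinical benchmark the best DMS
assay per protein enters as its own entry ("DMS") and ranks second; vep03
drops because it is simulated as an SNV-only predictor, so its pairwise
comparisons rest on small shared label sets at this toy scale. One-sided
bootstrap P-values for the correlation ranking:

```r
round(rc$bootstrap$p_values, 3)
#>       vep01 vep02 vep03 vep04 vep05
#> vep01     1 0.000 0.000 0.000     0
#> vep02     1 1.000 0.060 0.000     0
#> vep03     1 0.945 1.000 0.085     0
#> vep04     1 1.000 0.955 1.000     0
#> vep05     1 1.000 1.000 1.000     1
```

vep01 significantly outranks everyone (P = 0); adjacent mid-field pairs
(vep02 vs vep03, P = 0.06) are not separable on three small proteins —
exactly the behaviour the bootstrap is there to expose.

Real data enter through the same door: per-protein TSV score tables
(`protein position ref alt score`) read with `read_score_table()`, label
tables with `read_label_table()`, FASTA sequences with
`read_protein_records()`, and per-predictor orientation declarations with
`read_predictor_config()`.

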