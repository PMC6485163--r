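# ghostabc

Inference of archaic **ghost introgression** in African populations by
Approximate Bayesian Computation with deep-learning summary statistics
(ABC-DL), plus the descriptive population-genetic statistics that
accompany such an analysis.

Unsequenced ("ghost") archaic lineages are detectable only through the
ancestry they left in modern genomes. `ghostabc` encodes six competing
demographic models for a seven-genome panel (Altai Neanderthal, Denisovan,
East Asian, European, West African, Mbuti, Khoisan): a shared backbone of
human/archaic history, optionally extended by a basal modern-human ghost
`XAf` and/or a Neanderthal-lineage ghost `Xn` pulsing ancestry into the
African populations. Because the likelihood of the 7-dimensional unfolded
joint site frequency spectrum (jSFS) is intractable, inference is
simulation-based:

```
prior draw θ → coalescent simulation → jSFS (3^7 tensor) → noise injection
            → network-ensemble prediction  = summary statistic (SS-DL)
            → rejection ABC: accept the q-quantile of reference draws
              nearest to the observed SS-DL
```

Model posteriors are accepted-label fractions; parameter posteriors are
summarized as mean and equal-tailed 95% credible intervals. Two
self-consistency procedures quantify how much the data can actually say:
the **confusion matrix** (mean posterior over pseudo-observed datasets of
known origin) and the **factor-2 statistic** (fraction of replicates whose
posterior mean falls within 50%–200% of the truth).

The package also implements the descriptive layer: pairwise genotype
differences per kbp of callable genome, three-tier (0.5/1/1.5 Mbp) runs of
homozygosity with a strict 10%-of-expected-heterozygosity rule and a 67%
callable-fraction requirement, ABBA-BABA D-statistics and f4-ratio
admixture proportions with weighted block-jackknife standard errors.

## Worked example

A planted-truth check of the admixture estimators — simulate a panel where
the target population received a 30% pulse from the source, then estimate
that proportion back:

```r
library(ghostabc)

p <- make_admixed_panel(0.3, fragment_set(2000, 20000), seed = 5)
d <- d_statistic(p$geno, "Ref", "Target", "Src_1", "Chimp", block_size = 5e6)
fr <- f4_ratio(p$geno, c("Src_1", "Sister", "Target", "Ref"),
               c("Src_1", "Sister", "Src_2", "Ref"), block_size = 5e6)
```

which prints (via `analysis/04_descriptive_stats.R`):

```
D(Ref, Target; Src, Chimp) = 0.2671 (Z = 6.36)
f4-ratio alpha = 0.266 +/- 0.039 (planted 0.3)
```

The D-statistic rejects treeness at |Z| > 3 (the pulse is real) and the
f4-ratio recovers the planted proportion within its jackknife error. The
same driver prints the panel's pairwise-diversity matrix (archaic genomes
show the lowest heterozygosity, ~0.33–0.43 differences per kbp, moderns
~0.45–0.55, archaic–modern divergence ~0.9) and recovers a planted 2-Mbp
run of homozygosity exactly at its boundaries.

A desk-scale model-choice study — six models, 500 training and 500
reference simulations each, 20 pseudo-observed datasets per model — runs
in about five minutes on one CPU:

```r
res <- run_model_choice_study(desk_study(), seed = 1)
round(res$confusion, 3)   # rows: generating model; columns: mean posterior
```

## Analysis scripts

Numbered drivers under `analysis/` reproduce the package's experiments and
write TSV tables under `results/`:

| script | what it does |
| --- | --- |
| `01_model_space.R` | resolved event tables and priors for models A–F |
| `02_model_choice.R` | desk-scale ABC-DL confusion matrix |
| `03_parameter_recovery.R` | factor-2 recovery of the XAf split time |
| `04_descriptive_stats.R` | diversity, ROH, D and f4-ratio on fixtures |

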