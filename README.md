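# metageno

Chromosome-wise multi-task genomic risk modelling in R.

## What this is for

Classic polygenic risk scores (PRS) rank individuals by a *linear* weighted
sum of effect-allele dosages. That form cannot represent interactions
between variants (epistasis) and treats each disease in isolation.
`metageno` implements a structured neural alternative for ischaemic stroke
(IS) and five modifiable risk factors — atrial fibrillation (AF), coronary
artery disease (CAD), type 2 diabetes (T2D), hypertension (HT),
hypercholesterolemia (HCL) — aimed at researchers who want to study such
architectures, and the evaluation layer around them, on data they fully
control.

The core model: each SNP's allele state x (one-hot over 0/1/2/missing) is
embedded as

    e = E x + P_snp,

with one state table **E** (V x d) shared by all SNPs and diseases and a
learned per-SNP identity term **P**. Scaled dot-product self-attention runs
*within each autosome*,

    alpha_kl = softmax_l(q_k . k_l / sqrt(d)),   h_k = sum_l alpha_kl v_l,

and mean pooling per chromosome yields the chromosome-aware representation
**Z** (22 x d). A sequence backbone over the 22 chromosome tokens
(transformer, LSTM, GRU, CNN or TCN) feeds six per-disease sigmoid heads
trained with a weighted multi-task cross-entropy. Everything — including
backpropagation — is implemented in R/RcppArmadillo with no deep-learning
framework dependency, and is deterministic given a seed.

Around the model: PGS-Catalog-style scoring-file and VCF ingestion, a
liability-threshold cohort simulator (block LD, planted within-chromosome
epistasis, shared cross-disease latent factor, age-at-event generation),
balanced stratified cross-validation, a true-weight PRS baseline, and the
downstream evaluation layer (percentile risk strata with Cox hazard ratios,
Harrell's C-index over task combinations, Kaplan-Meier cumulative incidence
on an age timeline, per-chromosome attention reports).

## Worked example

Simulate a cohort whose only IS signal is epistatic (eight within-chromosome
SNP pairs, no additive effects — a linear PRS is blind by construction),
train the chromosome-wise transformer, and compare:

```r
library(metageno)

spec   <- spec_epistasis(seed = 100)         # 200 SNPs, 22 autosomes
sim    <- simulate_cohort(5000, spec)        # genotypes + labels + ages
states <- dosage_states(sim$G)
groups <- group_by_chromosome(sim$G$panel)
labels <- as.matrix(sim$cohort[, DISEASES])

plan <- make_fold_plan(labels[, "IS"], k = 5, seed = 1)
tr   <- plan$train_idx[[1]]                  # balanced: cases == controls
ev   <- plan$eval_idx[[1]]                   # full held-out fold

fit <- train_metageno(states[tr, ], labels[tr, ], groups,
                      cfg = model_config(d = 16, depth = 1, width = 32,
                                         heads = 4),
                      epochs = 80, lr = 1e-2, batch_size = 128,
                      task_weights = c(1, 0, 0, 0, 0, 0), seed = 0)

probs <- predict(fit, states[ev, ])
cat(sprintf("model IS AUROC: %.3f\n", auroc(probs[, "IS"], labels[ev, "IS"])$auroc))
cat(sprintf("true-weight PRS AUROC: %.3f\n",
            auroc(prs_score(sim$G)$score[ev], labels[ev, "IS"])$auroc))

strata <- to_percentiles(probs[, "IS"], probs[, "IS"])
hr <- bin_hazard_ratios(strata,
                        data.frame(age = sim$cohort$age_end[ev],
                                   event = sim$cohort$event_is[ev]),
                        scheme = "tertiles")
print(hr, digits = 3)
```

Output (seed 0, single thread):

```
model IS AUROC: 0.861
true-weight PRS AUROC: 0.500
  bin   n events   HR lower upper
1  T2 334     71  5.9  3.26  10.6
2  T3 333    216 25.6 14.59  44.8
```

The model recovers the planted interactions (AUROC 0.861) where the linear
PRS with the *true* additive weights sits at chance (0.500), and its risk
tertiles separate the age-timeline hazard accordingly. The numbers above are
what the code prints; seeds 0-4 of this protocol average AUROC ≈ 0.77 (the
acceptance suite asserts the margin over PRS).

## Command line

```sh
Rscript inst/cli/metageno.R simulate --spec spec.json --n 5000 --out cohort
Rscript inst/cli/metageno.R prs --vcf cohort.vcf --panel panel.txt --tag IS --out scores.csv
Rscript inst/cli/metageno.R stratify --scores scores.csv --pheno cohort.pheno.tsv \
        --scheme tertiles --out hr.csv
```

## Documentation

The methods vignette (`vignettes/metageno-methods.Rmd`) describes the model
and its assumptions, the simulator's stated world and what a green test does
and does not establish, numerical choices, and known limitations.
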