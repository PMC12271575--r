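---
title: "Chromosome-wise multi-task genomic risk modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-wise multi-task genomic risk modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Polygenic risk scores (PRS) summarise a genome as a weighted sum of
effect-allele dosages. The weighted sum is linear by construction: it cannot
express epistasis (interactions between variants) or share information across
related diseases. `metageno` implements a structured alternative for
ischaemic stroke (IS) and five modifiable risk factors — atrial fibrillation
(AF), coronary artery disease (CAD), type 2 diabetes (T2D), hypertension
(HT), hypercholesterolemia (HCL) — built on two ideas:

1. **Chromosome-wise representation.** Variants physically close to each
   other (same chromosome, linkage disequilibrium) are the ones most likely
   to interact. SNPs are therefore grouped by autosome, and interactions are
   modelled *within* each chromosome by self-attention before any
   cross-chromosome mixing happens in the backbone.
2. **Multi-task supervision.** The six diseases share genetic architecture.
   Six prediction heads on one shared trunk let auxiliary diseases shape the
   representation that predicts IS.

# The model

## Encoding and embedding

Each genotype is a dosage in {0, 1, 2} of a designated effect allele, or
missing. Dosages are one-hot encoded over `V` allele states; by default
`V = 4` with a dedicated *missing* state, so no-calls are represented
honestly rather than silently imputed (`missing_policy = "zero"` collapses
them to homozygous-other if desired).

For SNP `k` on chromosome `j` the embedding is

```
e_jk = E x_jk + P_jk
```

where `E` (`V x d`) is a single state-embedding table shared by *all* SNPs
and diseases, and `P` holds one learned `d`-vector per panel SNP. The shared
`E` is what lets all six diseases read genotypes through one representation;
the per-SNP term `P` restores SNP identity, which a shared table alone would
erase (two SNPs with the same dosage would otherwise be indistinguishable,
and no variant-specific effect could ever be learned). `P` is this package's
resolution of a genuine ambiguity in the source architecture; the
representation ablation below lets you measure what it buys.

## Per-chromosome self-attention

Within chromosome `j` with `m` SNPs, single-head scaled dot-product
attention contextualises every SNP against the others on the same
chromosome:

```
q_jk = W_Q e_jk   k_jl = W_K e_jl   v_jl = W_V e_jl
alpha_jkl = softmax_l(q_jk . k_jl / sqrt(d))
h_jk = sum_l alpha_jkl v_jl
```

`W_Q, W_K, W_V` are shared across all 22 chromosomes (one parameter set,
controlled model size). Mean pooling `h_j = (1/m) sum_k h_jk` gives one
`d`-vector per chromosome; stacking them yields the chromosome-aware
representation `Z` (22 x d). `Z` always has 22 rows: a chromosome with no
panel variants contributes a learned per-chromosome *null token*, so panel
composition can never change tensor shapes. Softmax uses max-subtraction;
attention rows sum to 1 within 1e-6 by construction and to ~1e-16 in
practice.

Four representation modes realise the ablations of interest:

| mode | embedding | attention scope |
|---|---|---|
| `chromosome_wise` | `E x + P` | within chromosome |
| `global_snp` | `E x` (no identity) | whole panel |
| `independent_snp` | per-SNP `V x d` tables | none |
| `one_hot` | raw one-hot, padded to `d` | none |

## Backbone and heads

`Z`'s 22 chromosome tokens feed one of five sequence backbones
(`transformer` with multi-head attention and mean token pooling; `lstm`/`gru`
over tokens in chromosome order, final hidden state; `cnn`/`tcn` kernel-3
(dilated, causal for `tcn`) convolutions with global mean pooling). Six
independent linear heads with sigmoids produce per-disease probabilities; the
loss is a weighted sum of per-task mean binary cross-entropies (default
weights all 1; `c(1,0,0,0,0,0)` gives the single-task IS mode used by the
representation experiments).

Because no deep-learning framework is available in the target environment,
forward and backward passes are hand-written in RcppArmadillo and verified
against central finite differences (relative error ~1e-7 on the
chromosome-wise/transformer path; the test suite checks every backbone and
representation mode). All randomness — initialisation, minibatch order —
flows through R's RNG, so a seed fixes a run bit-for-bit on one thread.

## Training protocol

The cohort protocol mirrors biobank practice at desk scale: stratified
5-fold cross-validation on the IS label; within each training fold, controls
are randomly downsampled to the case count (balanced training); the *entire*
validation fold — including the controls excluded from training — forms the
evaluation pool, and out-of-fold scores are produced only by models that
never saw those samples. Optimisation is Adam (lr 1e-3 default, batch 256,
optional early stopping on validation IS AUROC with patience 10).

# The synthetic-data generator

The generator produces the statistical structure the framework assumes,
nothing more:

* **Genotypes** are sums of two haplotypes. Inside an LD block, haplotype
  alleles come from thresholding an equicorrelated Gaussian (copula) whose
  latent correlation is calibrated by 1-D numerical integration so the
  *dosage* correlation hits the target `r`; outside blocks, variants are
  independent Binomial(2, MAF).
* **Labels** follow a liability-threshold model per disease: liability =
  additive terms (centred dosages) + planted within-chromosome epistatic
  products + a per-sample shared latent factor + unit Gaussian noise; a
  sample is a case when liability exceeds the *empirical* `1 - prevalence`
  quantile. Empirical rather than theoretical-normal quantiles keep
  prevalence exact even when epistasis makes liabilities non-normal.
  Centring dosages (`g - 2 maf`) in the products keeps the marginal effect
  of a pure-epistasis pair near zero — the property the nonlinearity
  experiments rely on.
* **Ages** are exponential with hazard proportional to `exp(liability)`
  (base age 40, scale 30 years at zero liability), so Cox models on the age
  timeline recover planted hazard ratios; controls are censored by an
  independent exponential clock. Family history is Bernoulli with log-odds
  increasing in standardised IS liability (baseline 30%, slope 1).
* **The shared factor** (one global latent, per-disease loadings) creates
  label comorbidity *without* being predictable from genotype; cross-disease
  learnability comes from shared causal SNPs in the fixtures, which is the
  minimal mechanism that makes multi-task learning provably helpful.

What the generator does **not** emulate: realistic human LD maps, ancestry
structure, imputation uncertainty, age-dependent baseline hazards. A green
test therefore establishes that the *machinery* behaves as specified on data
with the assumed structure — not that the architecture would match published
biobank-scale performance.

## Frozen worlds

Four canonical specs ship with the package (`spec_null()`,
`spec_epistasis()`, `spec_shared_factor()`, `spec_attention_recovery()`,
plus `spec_additive()` for the linear ceiling). Their effect sizes were
chosen once by pilot simulation while designing the package and then frozen;
tests never tune them. Notable choices:

* `spec_epistasis()`: 200 SNPs, MAF 0.5, eight within-chromosome pairs with
  product effect 1.5, no additive effects, IS prevalence 0.3. MAF 0.5 makes
  centred products symmetric three-level variables; prevalence 0.3 gives a
  balanced training fold of ~2,400 samples, which pilot runs showed is what
  a small transformer needs to learn pure interactions reliably.
* Representation experiments train with IS-only task weights: in these
  fixtures the five MRF labels are noise by construction, and their
  gradients otherwise drown the shared trunk (piloted: ~0.53 vs ~0.89
  held-out AUROC). The multi-task-benefit experiment instead uses
  `spec_shared_factor()`, where the MRFs carry the same causal directions
  strongly and IS weakly — there, six-task training beats IS-only training.

# Evaluation layer

* **Percentiles**: scores map to mid-rank empirical percentiles of the
  pooled out-of-fold validation distribution (the "validation population");
  tertiles and the nested top-percentile bins (55/80/90/95/99-100 against
  the 45-55 reference band) follow.
* **Hazard ratios**: one Cox fit per comparison bin with age as the time
  axis and the bin indicator as the only covariate (the bins are nested, so
  a single factor model cannot represent them); Wald 95% CIs.
* **C-index**: Harrell's concordance over permissible pairs (event vs
  strictly-later survivor/event), score ties counting one half — implemented
  directly and checked against brute-force enumeration.
* **Cumulative incidence**: 1 minus Kaplan-Meier survival per subgroup with
  Greenwood bands; subgroup helpers cross top/bottom risk deciles with
  covariate flags (HT+AF, family history).
* **Attention report**: per SNP, the incoming attention mass (column sums
  of the chromosome-layer attention matrix) weighted by the norm of the
  SNP's value vector, summed per chromosome, averaged over samples, min-max
  normalised across the 22 chromosomes. The *unweighted* sum is available
  (`weighting = "raw"`) but is mathematically constant per chromosome —
  row-normalised attention makes the incoming masses of a chromosome's SNPs
  sum to exactly its SNP count — so it measures panel composition, not
  learned importance; reports that come out constant are flagged as
  degenerate. The value-norm weighting is the default because it is the
  simplest attention-derived quantity that demonstrably recovers planted
  causal chromosomes.

# Numerical and design notes

* Heads initialise at zero: an untrained model predicts 0.5 everywhere and
  the first gradient steps calibrate marginals before shaping features.
* LSTM forget-gate biases initialise at 1 (standard recipe).
* BCE is computed from logits in the stable `max(z,0) - z y + log1p(exp(-|z|))`
  form inside training; the user-facing `multitask_loss()` clips
  probabilities at 1e-7.
* `dropout` is accepted in the config for interface compatibility but only 0
  is supported: models of this size trained for tens of epochs showed no
  overfitting that dropout would address, and a no-op keeps runs
  deterministic.
* Config files are JSON (the environment provides no YAML parser for R).
* Multi-allelic VCF sites are skipped with a warning; half-calls and `./.`
  are missing; matching is by (chromosome, position) with allele
  verification, rsIDs being reporting-only.

# Known limitations

* Training is single-threaded CPU; the implementation targets panels of
  hundreds of SNPs and cohorts of thousands, not biobank scale.
* The `global_snp` ablation attends over the whole panel with identity-free
  embeddings; on a *pure* epistasis world both it and `one_hot` are blind to
  the planted pairs by construction, so their relative ordering there is
  noise-dominated — the published ordering of representation ablations
  arises on data that also carry additive signal.
* No imputation, QC, liftover or ancestry inference (out of scope by
  design); no competing-risk or net-reclassification analyses.
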