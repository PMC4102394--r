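# gkmkit

Classification of regulatory DNA sequences with gapped k-mer string
kernels, in R.

Predicting which genomic regions are bound by a transcription factor (or
act as enhancers) from sequence alone is a standard supervised problem:
positive sequences from ChIP-seq peaks, matched random negatives, and a
classifier over sequence features. Plain k-mer counts (the spectrum
kernel) work well for short words but collapse for long ones — a 300 bp
region contains at most a few hundred of the 4^16 possible 16-mers, so
long-word counts are hopelessly sparse. Gapped k-mers fix this: a feature
is a word of total length *l* with only *k* informative positions (the
other *l − k* are wildcards), giving long-range features whose counts are
still well estimated.

## The kernel

For sequences *S₁*, *S₂* the similarity is the normalized inner product of
their gapped k-mer count vectors. It never has to be computed in feature
space: with *N_m(S₁, S₂)* the number of l-mer pairs (one l-mer from each
sequence, both strands) at Hamming distance *m* — the **mismatch
profile** — the unnormalized kernel is

    K(S₁, S₂) = Σ_m h_lk(m) · N_m(S₁, S₂),   h_lk(m) = C(l − m, k),

since two l-mers differing at *m* positions share exactly `choose(l-m, k)`
gapped k-mers. The same sum with other distance-indexed coefficients gives
the classic wildcard and mismatch string kernels, and — with coefficients
`c_lk(m)` derived from the pseudo-inverse **gkm-filter** `g_lk(m)` — the
linear kernel on smoothed ("robust") l-mer count estimates. Mismatch
profiles are computed either by direct all-pairs comparison (2-bit packed
l-mers, XOR distance counting) or by a k-mer tree depth-first traversal
with optional truncation at `m_max` mismatches; the two agree exactly.

On top of the kernels the package provides: SVM training on the
precomputed kernel (kernlab's solver), a Naive-Bayes classifier on
truncated-filter l-mer count estimates, de novo PWM extraction from the
top-weighted 10-mers of a trained SVM, ROC/PR/cross-validation
evaluation, and a seeded planted-motif benchmark generator.

## Worked example

```r
library(gkmkit)
library(dplyr)

# a seeded benchmark: 500 positives with one planted 19 bp site each,
# 500 GC/length-matched negatives, 300 bp
b <- make_benchmark("ctcf_like", seed = 1)
seqs <- bind_rows(b$pos, b$neg)

# gapped k-mer kernel (l = 12, k = 6, tree algorithm, m_max = 3)
K <- gkm_kernel(seqs, l = 12, k = 6, m_max = 3)

# 5-fold cross-validated SVM vs the long-word spectrum baseline
glance(cv_svm_kernel(K, seqs$label, seed = 1))
#> # A tibble: 1 x 4
#>   folds mean_auc  sd_auc  se_auc
#>   <int>    <dbl>   <dbl>   <dbl>
#> 1     5    0.976 0.00826 0.00369
glance(cv_svm_kernel(gkm_kernel(seqs, l = 12, k = 12), seqs$label, seed = 1))
#> # A tibble: 1 x 4
#>   folds mean_auc sd_auc se_auc
#>   <int>    <dbl>  <dbl>  <dbl>
#> 1     5    0.829 0.0181 0.0081
```

The gapped k-mer kernel reaches mean AUC 0.976 where the ungapped 12-mer
spectrum kernel overfits to 0.829 — the sparsity collapse that gapped
k-mers are designed to avoid. Motifs come straight out of the trained
model:

```r
ls <- lmer_set(seqs, l = 10)
m  <- train_svm(gkm_kernel(ls, k = 6, m_max = 3), seqs$label, lmers = ls)
kw <- score_all_kmers(m, w = 10)   # every 10-mer, SVM-scored, ranked
pwms <- build_pwms(kw)             # iterated greedy merge of the top 1%
pwms[[1]]
#> <gkm_pwm> denovo_1 width 10, consensus ACCTGGTGGC, background GC=0.42
compare_pwms(pwms[[1]], b$pwms[[1]])$mean_cor   # vs the planted site
#> [1] 1
```

A thin command-line front end wraps the same functions:

```sh
exec/gkmkit simulate --preset ctcf_like --seed 1 --out-prefix bm
exec/gkmkit cv --pos bm_pos.fa --neg bm_neg.fa --l 12 --k 6 --m_max 3
exec/gkmkit train --pos bm_pos.fa --neg bm_neg.fa --l 10 --k 6 --m_max 3 --out model.rds
exec/gkmkit motifs --model model.rds --out motifs.meme
```

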