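---
title: "Gapped k-mer kernels: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gapped k-mer kernels: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
feature space and kernel, the two profile algorithms, the pseudo-inverse
count smoothing, the classifiers and the motif extraction, together with
the numerical conventions and the design decisions that were genuinely
open. It states no empirical claim that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

A sequence is represented by the counts of its **gapped k-mers**: words of
total length $l$ in which $k$ positions are informative and $l-k$ are
gaps. There are $\binom{l}{k} 4^k$ such features, far too many to
enumerate for useful $l$, but only l-mers actually present in a sequence
contribute, and the number of gapped k-mers shared by two l-mers depends
only on their Hamming distance $m$:

$$h_{lk}(m) = \binom{l-m}{k}.$$

The unnormalized kernel between two sequences is therefore
$\sum_m h_{lk}(m)\,N_m$, where the **mismatch profile** $N_m$ counts the
l-mer pairs (one from each sequence) at distance $m$. The reported kernel
is the cosine-normalized form, so $K(S,S)=1$. Both strands contribute:
each sequence's l-mer list is the forward-strand windows followed by the
reverse-complement strand's windows, which makes every kernel, SVM score
and NB score exactly strand-symmetric (verified to $10^{-10}$ in the
tests).

The same profile supports the classic string kernels by swapping the
coefficient family:

* **wildcard kernel** — features are words with up to $M$ wildcards,
  weighted $\lambda^{j}$ for $j$ wildcards. A shared pattern must cover
  all $m$ mismatch positions, so the pair weight is
  $\sum_{j\ge m} \lambda^{j}\binom{l-m}{j-m}$. The inner product could
  also be defined with $\lambda^{2j}$ (one factor per feature-vector
  side); we use $\lambda^j$ once per shared pattern and note that at the
  conventional benchmark setting $\lambda = 1$ the two conventions
  coincide.
* **mismatch kernel** — features are all l-mers within distance $M$; the
  pair weight is the size of the intersection of two Hamming balls,
  evaluated by a closed-form triple sum over $(m_1, m_2, t)$ with
  multiplicity
  $\binom{l-m}{t}(b-1)^t \binom{m}{m_1-t}\binom{m_1-t}{r}(b-2)^r$,
  $r = m_1+m_2-2t-m$, and verified against explicit ball enumeration.

## The gkm-filter

Long-word counts are sparse; the remedy is to map observed l-mer counts
through the gapped k-mer space and back, yielding minimum-norm **l-mer
count estimates**. Writing $A$ for the binary incidence matrix from
l-mers to gapped k-mers and $W = A^+$ for its Moore–Penrose
pseudo-inverse, the combined map $G = WA$ is the orthogonal projection
onto the span of gapped k-mer counts, and its entries depend only on the
distance between the two l-mers: the filter $g_{lk}(m)$.

Because the rows of $A$ span exactly the functions of polynomial degree
$\le k$ on the Hamming scheme, the projection kernel has the closed form

$$g_{lk}(m) = 4^{-l} \sum_{i=0}^{k} K_i(m;\,l),$$

with $K_i$ the Krawtchouk polynomial
$\sum_j (-1)^j 3^{\,i-j}\binom{m}{j}\binom{l-m}{i-j}$. The test suite
verifies this against the numerically computed $\mathrm{pinv}(A)A$ for
small $(l,k)$, along with the projection identities $G^2 = G$ and
$AG = A$; the per-pattern pseudo-inverse weights $w(t)$ are recovered
from $g$ by solving the triangular system
$g(m) = \sum_t \binom{m}{t}\binom{l-m}{k-t} w(t)$ exactly. The integer
numerator of $g$ is accumulated exactly and divided by $4^l$ once, so no
floating-point summation error enters the filter.

$g_{lk}(m)$ goes slightly negative at large $m$ (the minimum-norm
estimate is not sign-constrained). Where positive estimates are required
(log-likelihoods), the **truncated filter** zeroes every weight at and
beyond the first negative entry $m_0$. The linear kernel on estimate
vectors is again a profile sum with weights $c_{lk}(m)$; for the full
filter $c = g$ (projection idempotence, asserted to $10^{-9}$), while the
truncated filter uses the explicit $(m_1, m_2, t)$ sum.

## Profile algorithms

Two interchangeable algorithms produce $N_m$ and are cross-checked for
exact integer equality:

* **direct** — each sequence is a deduplicated list of 2-bit-packed
  l-mers with occurrence counts; all pairs are compared once, distance by
  XOR (chunked encoding with a $2^{2t}$-entry lookup table, default
  $t = 6$, exposed via `count_mismatches()`; the bulk path uses the same
  XOR on 64-bit words). Cost grows with the product of the two unique
  l-mer lists.
* **tree** — one prefix tree over the pooled l-mers of all sequences;
  leaves carry per-sequence occurrence lists. A depth-first traversal
  over node pairs carries the running prefix distance and prunes at
  `m_max`, accumulating all pairwise profiles (self-pairs included — they
  are needed for the kernel diagonal) in a single pass. Unordered node
  pairs are enumerated once, which plays the role of the classical
  lower-triangle ID-range skip.

`m_max` trades exactness for speed. For the gkm family, $h_{lk}(m) = 0$
for $m > l-k$, so `m_max = l - k` is exact; smaller values are an
approximation whose error is bounded by the rapidly decaying
coefficients. Raw kernel entries are non-decreasing in `m_max`
(coefficients are non-negative), a property the tests assert. The
automatic algorithm choice uses the pooled exact-match path when
$l = k$ or `m_max = 0` (a sparse count-matrix cross product), the tree
for $l \ge 8$ (sparse leaves), and direct comparison otherwise; all three
are available explicitly.

## Classifiers

**SVM.** Training solves the standard soft-margin dual on the
precomputed, normalized kernel via kernlab's SMO implementation
(`C = 1` default, solver tolerance $10^{-6}$, bias included). Truncated
configurations are not guaranteed positive semidefinite; if the solver
rejects the matrix, a ridge of $10^{-8}$ on the diagonal is added and
logged. Decision scores are the support-vector expansion through the
test-by-train cross kernel; the diagonal normalization always uses the
same truncated feature map on both axes. Scoring every w-mer of the
model (`score_all_kmers()`) is exact and fast when $w = l$: the
support-vector l-mer weights are scattered over the full $4^l$ table via
neighbor enumeration, which equals the generic kernel path (asserted
numerically at small $l$).

**Naive Bayes.** The score of a sequence is the sum over its l-mers of
$\log(N_P/N_N)$, where $N_P, N_N$ are truncated-filter count estimates
from the positive and negative training tables, with pseudo-count half
the smallest positive filter coefficient (raw-count mode uses exact
counts with pseudo-count 0.5; at $l = k$ the two modes coincide). We sum
log *counts* rather than log frequencies; the two differ by a constant
per l-mer when set sizes differ, to which ROC/AUC is invariant. The
optional window mode scores every substring of $w$ consecutive l-mers
(length $w + l - 1$) and takes the maximum — appropriate for a single
localized site; full-sequence scoring is the default for dispersed
features. Filter-mode lookups never materialize the $4^l$ table: queried
l-mers get their neighbor counts within the truncated support from a
block-pigeonhole search over the stored tables.

## De novo motifs

A trained SVM ranks all $4^{10}$ 10-mers; the top 1% seed an iterated
greedy merge. The first PWM is initialized from the single best 10-mer;
each pass aligns every remaining top 10-mer to the model (all offsets
with at least half the word overlapping, both strands, log-odds against a
position-independent GC = 0.42 background, natural-log units, acceptance
threshold 5.0) and rebuilds the PWM from the accepted words with mass
$e^{\alpha w_i}$, $\alpha = 3$, at their aligned positions. Passes repeat
until the assignment is unchanged (batch update with a final fixed-point
test; the wording of the procedure admits an online variant, but batch
updates make the result independent of within-pass order), capped at 50
passes with a logged message if hit. Accepted words are removed and the
process repeated for up to three PWMs; motifs with fewer than 5
contributing words are suppressed as noise. PWM width stays fixed at the
seed word's length; overhanging aligned bases are ignored. Pseudo-counts
are 1% of each column's mass split over the four bases (empty columns are
uniform) — small and uniform, since no convention is prescribed. Ties in
the ranked table are broken lexicographically, so the construction is
deterministic.

## The synthetic benchmark

`make_benchmark()` emulates the statistical structure of TF ChIP-seq
benchmark sets with two presets:

* `ctcf_like` — 500 positives / 500 negatives, 300 bp, one sampled
  instance of a fixed 19 bp high-information PWM (per-column maximum
  0.85) per positive: a long zinc-finger-class footprint. 300 bp and
  19 bp mirror typical peak and site widths.
* `ep300_like` — three distinct 8 bp degenerate PWMs (maximum 0.6), one
  to three instances per positive: dispersed enhancer-grammar signal.

Backgrounds are i.i.d. bases at configurable GC (default 0.42, a
genomic-like composition); negatives are drawn at the positives' lengths
and pooled GC, the matching used for real negative sets. All randomness
flows from one seed through a single RNG stream (background, planting,
negatives in that order), so a configuration and seed reproduce the FASTA
byte for byte. The generator deliberately omits several properties of
real genomic nulls: no repeat structure (repeat masking is carried as
lowercase and summarized by `repeat_fraction()`, but not simulated), no
dinucleotide or higher-order composition, no copy-number structure.
Passing benchmarks therefore demonstrates correctness and the relative
behaviour of feature families under planted signal — not absolute
performance on genomic data, where composition confounds are harsher.

## Validation problem sizes

The acceptance-grade checks run at sizes chosen to exercise every code
path while completing in minutes on one CPU: feature-space oracle
equivalence on 200 random pairs for all $(l,k)$ with $l \le 4$;
tree/direct equality on 50 sequences at $l \in \{4,6,8\}$; the SVM
benchmark on three replicates of the full `ctcf_like` preset with
$l = 12$, $k = 6$ and `m_max = 3` (the standard large-run approximation;
its error is negligible against the $h$ decay) versus spectrum baselines
at $k = 12$ and $k = 6$; the NB comparison at $l = 16$ on a 70/30 split;
and motif recovery at $l = k' = 10$. The spectrum baselines and the PWM
scan are exact computations.

## Known limitations

* Word length is capped at 26 bases on the packed-key path (53-bit exact
  doubles); chunked encoding alone supports longer words.
* kernlab's SMO can terminate short of the KKT optimum on very small
  kernels at large `C`; at the default `C = 1` (and on realistic sizes)
  we have not observed this. The duplication-invariance test documents
  the regime in which the property holds exactly.
* Gaps at word ends are treated like internal gaps, and all base
  mismatches are weighted equally; purine/pyrimidine-aware alphabets are
  not implemented.
* The dense w-mer scoring table is limited to $w \le 12$.
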