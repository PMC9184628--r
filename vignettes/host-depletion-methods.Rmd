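---
title: "Reference-free host depletion: model, procedures, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free host depletion: model, procedures, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical metagenomic samples are dominated by host DNA. Before microbial
reads can be classified taxonomically, the host fraction has to be removed;
doing this by alignment requires multi-gigabyte reference indices and
degrades on noisy long reads. `hostsieve` instead learns a sequence-level
classifier: each single-end read receives a probability of being host,
computed directly from its bases, with no reference database at inference
time. The dominant biological signal available to such a classifier is CG
(CpG) suppression - the `CG` dinucleotide is strongly depleted in
vertebrate genomes but not in microbial ones - though a learned model can
and does use additional composition features (the package's attribution
module exists to inspect what was learned).

## The classifier

A read of length $L$ is one-hot encoded into an $L \times 4$ matrix
($A, C, G, T$ map to unit vectors; IUPAC ambiguity codes to zero rows, so
they contribute nothing to any convolution and bias neither class; encoding
is case-insensitive because FASTA soft-masking uses lowercase). The network
is

$$ \big[\mathrm{conv}(k{=}15,\,128\ \text{filters}) \to \mathrm{ReLU} \to
\mathrm{avgpool}(5)\big] \times 4 \to \mathrm{GAP} \to
\mathrm{linear} \to \sigma $$

where GAP (global average pooling) averages each of the 128 feature maps
over the positional axis. GAP is what makes the model length-flexible: one
set of weights scores a 100 bp read and a 6,000 bp read without padding.
The single logistic output unit gives $P(\text{host})$; with all weights
zero every read scores exactly 0.5. The default architecture has 745,601
trainable scalars, i.e. 0.003 GB at 32-bit precision - the entire
"reference database" of the method.

Choices the architecture description leaves open, fixed here:

* **Convolution boundaries**: 'same' zero-padding, stride 1. Average
  pooling uses non-overlapping windows with a final partial window averaged
  over its true size (ceiling division). Together these guarantee that any
  length at or above the minimum survives four pool-by-5 stages.
* **Output head**: one logistic unit (the model reports *a* probability,
  one number), not a 2-unit softmax. The parameter count is insensitive to
  this at the reported precision.
* **Minimum input length**: 50 bp, the smallest truncation bin; enforced
  with an explicit error.
* **No dropout**: the final architecture lists only
  conv/ReLU/avg-pool/GAP/linear layers.

## Length-binned inference

Reads are never padded; they are truncated. At inference time a read of
length $\ell$ is assigned a truncation length

$$ t(\ell) = \begin{cases}
\texttt{max\_len} & \ell > \texttt{max\_len} \\
\lfloor \ell/\texttt{inc2}\rfloor\,\texttt{inc2} & \texttt{seq\_cutoff} < \ell \le \texttt{max\_len}\\
\lfloor \ell/\texttt{inc1}\rfloor\,\texttt{inc1} & \text{otherwise}
\end{cases} $$

with defaults `inc1 = 50`, `inc2 = 1000`, `seq_cutoff = 5000`,
`max_len = 6000`. Reads sharing a truncation length form a rectangular
batch; a bin of truncation length $t$ is scored in batches of
$\lfloor \texttt{batch\_max\_len}/t \rfloor$ reads
(`batch_max_len = 900000` bp), and passes are scheduled greedily by
ascending truncation length so that no pass stages more than
`lim = 1.2e9` truncated bases - the "classify what fits in memory, then
return for the larger reads" streaming scheme. Two deliberate readings of
under-specified corners:

* "Truncated to the smallest sequence in the bin" is implemented as
  truncation to the bin's *lower boundary*. That choice is deterministic,
  independent of which reads happen to occupy the bin, and never longer
  than any member.
* Reads shorter than `inc1` (50 bp) are rejected with a logged warning:
  the calibration table starts at 100 bp and behaviour below 50 bp is
  undefined in the source method. A length exactly at `seq_cutoff` uses
  `inc1`; since 5000 is a multiple of both increments the bins coincide.
* The staging text files of the original implementation are an
  implementation detail; the package stages in memory while honouring the
  same per-pass byte bound.

Thresholding is length-dependent: a table maps calibration lengths
$\{100, 150, 200, 300, 500, 1000, 5000, 10000\}$ to probabilities, a read
uses the entry nearest to its (original, untruncated) length, ties toward
the smaller length, and a read is host iff its probability strictly
exceeds the threshold. The shipped default is 0.5 everywhere until
`calibrate_thresholds()` is run: the published per-length values live in
supplementary material outside this package's inputs, so we ship the
neutral default and the procedure instead.

## Training

`train_model()` minimizes

$$ \underbrace{\mathrm{BCE}}_{\text{mean cross-entropy}}
 + \lambda_{2}\sum_W \|W\|_2^2
 + \lambda_{g}\,\underbrace{\tfrac1N\sum_n \big\|\nabla_{x_n} z(x_n)\big\|_2^2}_{\text{input-gradient penalty}} $$

with Adam (lr $10^{-3}$, no decay), $\lambda_2 = 10^{-5}$ applied to
weights only, and early stopping once the validation loss has not improved
for `patience` consecutive epochs (default 30), returning the best-epoch
weights. The gradient-norm regularizer - whose published form and
coefficient are unstated - is implemented as the squared input-gradient
penalty on the logit $z$ with default $\lambda_g = 10^{-4}$, exposed in
`training_config()`. Its exact weight-gradient is computed by double
backprop (a tangent forward pass with frozen ReLU masks followed by a
reverse pass), verified against central finite differences in the test
suite. Keeping input gradients small is what keeps the DeepLift-style
attributions below well-behaved.

"Concatenating training sequences to lengths 100/1000/10000" is read as
producing one uniformly positioned fixed-length *crop* per target length
per source read (`make_length_variants()`): the stated purpose is exposure
to multiple lengths, and rectangular $N \times L \times 4$ training
batches only exist for length-homogeneous groups. Batches are
length-homogeneous and reshuffled per epoch with an epoch-indexed seed, so
training is bit-reproducible from `(data, config, seed)` on one device.
The early-stopping boundary is `max(patience, 1)` consecutive
non-improving epochs, which reconciles "patience 0 stops at the first
epoch without improvement" with the usual patience semantics.

## Threshold calibration

"Optimizing for sensitivity and specificity" is realized as Youden's
$J = \text{sensitivity} + \text{specificity} - 1$: symmetric, standard,
parameter-free. For each calibration length, validation reads at least
that long are prefix-cropped to it, scored, and every observed probability
plus $\{0,1\}$ is scanned; the smallest maximizer is returned, making
calibration deterministic and order-invariant. A validation slice with a
single class is an error; an all-tied slice yields $J = 0$ with a warning.
The naive CG baseline classifier is calibrated by the same rule on CG
fractions, so the learned-vs-naive comparison is symmetric.

## Attribution

`attribute_read()` implements DeepLift-style rescale-rule attribution of
the *pre-squashing logit* against 20 references, each a seeded random
permutation of the input's own positions (permuting preserves base
composition, so the reference differs from the input only in sequence
*order*). Every layer except ReLU is affine, and ReLU differences
propagate exactly through the rescale multiplier
$(\mathrm{ReLU}(z_x)-\mathrm{ReLU}(z_r))/(z_x-z_r)$, so completeness -
per-position scores summing to
$z(x) - \overline{z(r)}$ - holds to machine precision; targeting the
probability instead would make it only approximate. Channel scores are
summed per position (one score per nucleotide), and windows of $k = 15$
(the first-layer kernel span) are ranked; `top_kmers()` pools windows by
their base sequence across reads and reports the 5 highest and lowest
means with per-position profiles. Whether the source method pools
identical k-mers across reads or ranks window instances is unstated;
sequence-level pooling is used here.

## The synthetic generator

`generate_read_set()` emulates exactly the features of the real data that
the classifier is supposed to exploit, and no more:

* **Composition**: first-order Markov chains over A/C/G/T. The host
  profile is uniform except $P(G \mid C) = 0.01$ (mass redistributed
  within the C row); the microbe profile is uniform 0.25. First-order
  structure suffices to realize CG suppression; the stationary CG dimer
  fraction is computable by eigen-analysis and the tests verify the
  empirical chains against it (host $\approx 0.25 \times 0.01 = 0.0025$
  vs microbe $1/16 = 0.0625$).
* **Lengths**: log-normal with median 4,000 bp (`sdlog = 1`, clipped to
  [100, 30000]), the long-tailed shape of Nanopore length distributions
  and the synthetic-set median of the source evaluation.
* **Noise**: independent per-base substitution/insertion/deletion at
  configurable rates (defaults 0); the expected edit count is
  $L(p_{del} + (1-p_{del})p_{sub} + p_{ins})$, which the tests verify by
  Monte Carlo against `adist` (scaled to 1 kb x 50 seeds because
  Levenshtein is $O(L^2)$ per pair).
* **Mixtures**: `host_fraction` reproduces the 1/25/50/75/99% host
  design points; truth tables are written alongside.

What the generator does **not** emulate: homopolymer-biased Nanopore
error, higher-order genomic composition (codon structure, isochores,
repeats), real taxonomic diversity, or quality-score information (the
classifier never reads qualities; they are constant `'I'`). A green test
on synthetic data therefore establishes that the machinery - encoding,
binning, training, calibration, attribution - behaves correctly and that
the classifier recovers a planted composition signal; it does not
establish the published accuracy on real Nanopore mixtures, which depends
on trained weights and corpora outside this package's scope.

## Numerical choices and degenerate inputs

* All arithmetic is double precision; forward outputs are deterministic
  and batch-composition-independent (verified: batch equals per-read
  scoring).
* Checkpoints are uncompressed RDS containers (weights, config, format
  version): round-trips are bit-identical, and the file size tracks the
  8-bytes-per-scalar storage; `serialized_size_gb()` keeps the 4-byte
  (32-bit) accounting of the storage claim.
* Ambiguity-heavy reads are legal everywhere; an all-ambiguous read
  encodes to all zeros and scores $\sigma(\text{bias terms})$.
* Ties: threshold selection breaks toward the smaller calibration length;
  probability exactly at a threshold is microbe; calibration returns the
  smallest optimal threshold. All three exist purely for determinism.
* DeepLift multipliers fall back to the primal ReLU mask where
  $|z_x - z_r| < 10^{-12}$; such positions carry zero difference and do
  not affect completeness.

## Limitations

Single-end reads only; no gzip transparency; no paired-end or SAM/BAM
I/O; CPU-only (results are deterministic and device-independent by
construction); the shipped default thresholds are neutral 0.5 until
calibrated on labelled validation data; and the package deliberately does
not ship trained weights - `train_model()` plus the generator reproduce
the *procedure*, not the published corpus-scale weights.
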