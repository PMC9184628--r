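# hostsieve

Reference-free host read depletion for long-read metagenomics.

## The problem

Clinical metagenomic samples are dominated by host (e.g. human) DNA, and
the microbial reads of interest have to be separated out before taxonomic
classification. Alignment- and k-mer-based depletion (Minimap2, Kraken2,
Centrifuge against a host genome) needs multi-gigabyte reference indices
and degrades on noisy long reads. `hostsieve` takes the learned,
index-free route: a small convolutional neural network scores every read
with a host probability directly from its bases. The whole "database" is
the network's 745,601 parameters — 0.003 GB at 32-bit precision.

## The model

A read of length $L$ is one-hot encoded ($A,C,G,T \mapsto$ unit vectors,
ambiguity codes $\mapsto$ zero rows) and passed through

$$\big[\mathrm{conv}(k{=}15,128) \to \mathrm{ReLU} \to
\mathrm{avgpool}(5)\big]\times 4 \to \mathrm{GAP} \to \mathrm{linear}
\to \sigma,$$

where the global average pooling (GAP) layer collapses the positional
axis, so one set of weights applies to any read length — no padding, no
per-length model. At inference, reads are grouped into length bins
(increments of 50 bp up to 5,000, of 1,000 up to a 6,000 bp truncation
cap), batched under a memory budget, scored, and labelled host iff the
probability strictly exceeds a length-dependent threshold (calibrated by
Youden's $J$ on validation data). Microbial reads are written back out at
full original length for downstream classification. A DeepLift-style
attribution module (20 permuted-sequence references, 15-mer aggregation)
explains what the network learned — on CG-suppressed data it rediscovers
the depletion of the `CG` dinucleotide in vertebrate genomes.

The package is self-contained and offline: a first-order Markov-chain
read simulator with a CG-suppressed host profile and a uniform microbe
profile (plus substitution/indel noise) generates labelled test data for
every procedure. The numerical core (forward pass, backprop, the
double-backprop input-gradient regularizer, DeepLift) is implemented in
C++ via RcppArmadillo and verified against independent oracles and finite
differences in the test suite.

## Worked example

Simulate a 600-read, 50%-host sample, train a reduced model, calibrate
thresholds, and deplete the sample end to end:

```r
library(hostsieve)

spec <- read_set_spec(n_reads = 600, host_fraction = 0.5,
                      min_length = 500, max_length = 500, seed = 42)
rs <- generate_read_set(spec, dir = "demo", format = "fastq")
ds <- labeled_dataset(rs$bases, rs$label)

model <- build_model(model_config(num_conv_layers = 2L,
                                  filters_per_layer = 32L), seed = 42)
fit <- train_model(model, ds[1:400, ], ds[401:500, ],
                   training_config(max_epochs = 10, batch_size = 50,
                                   seed = 42))
tail(fit$history, 2)
#>    epoch train_loss  val_loss
#> 9      9  0.3474085 0.2934119
#> 10    10  0.2991791 0.2317188

tab <- calibrate_thresholds(fit$model, ds[401:500, ],
                            calibration_lengths = c(100, 500))
tab
#>   length threshold
#> 1    100  0.450484
#> 2    500  0.530183

res <- run_host_depletion("demo/synthetic.fastq", "fastq", "demo_out",
                          fit$model, thresholds = tab)
#> demo_out/ now holds mlprobs.txt (id, label, length), mlpaths.fastq
#> (the microbial reads, full length), and run.log:
#>   reads=600 accepted=600 rejected_short=0
#>   passes=1
#>   host=298 microbe=302

confusion_metrics(res$records$label,
                  rs$label[match(res$records$id, rs$id)])
#> accuracy 0.9700  sensitivity 0.9667  specificity 0.9733
#>   (TP 290 FP 8 TN 292 FN 10, n = 600)
```

The validation loss falls from 0.68 to 0.23 in ten epochs and the
depleted sample is 97% correctly partitioned; with the full 4 x 128
architecture and length-1000 reads the test suite's parameter-recovery
criterion reaches sensitivity and specificity 1.0 on held-out reads,
beating the Youden-calibrated naive CG-fraction classifier on the same
split. Training at full scale takes a few minutes of CPU; everything is
bit-reproducible from the seeds.

A command-line front end with the same contract as the original tool
(`run -i reads.fastq -t fastq -o outdir` plus `generate`, `train`,
`calibrate`, `evaluate`, `attribute` subcommands) is installed at
`system.file("cli", "host-deplete.R", package = "hostsieve")`.

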