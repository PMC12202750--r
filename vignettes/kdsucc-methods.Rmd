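---
title: "Dual-teacher knowledge distillation for succinylation site prediction: models and methods"
author: "kdsucc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-teacher knowledge distillation for succinylation site prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

Succinylation is a post-translational modification that attaches a succinyl
group to a lysine residue. Experimentally verified sites are scarce and
costly, so sequence-based classifiers are used to rank candidate lysines.
`kdsucc` frames the task exactly as the established site predictors do: each
candidate lysine is represented by a window of $2n+1$ residues centered on
it (default $n = 16$, window length 33), padded at protein ends with the
pseudo-residue `X`. A window is positive when its central lysine is a known
site and negative otherwise.

```{r}
library(kdsucc)
extract_fragment("AKCDE", position = 2, n = 2)
```

## From residues to tensors

Windows are split into unigrams and tokenized over a fixed 21-symbol
vocabulary: the 20 standard amino acids in alphabetical order at indices
0–19 and `X` at 20. Non-standard residues (`B`, `J`, `O`, `U`, `Z`, `*`)
collapse onto `X`, so tokenization is total. A trainable embedding maps each
token to a dense vector of dimension $d = 300$; the embedding is learned
jointly with the classifier rather than pre-trained, which removes any
feature-engineering step.

## The three networks

Two *teacher* networks and one *student* share the embedding front end and a
common classification head:

* **Teacher 1 (CNN1D)** — two length-preserving convolution layers
  (32 filters, kernel 3, ReLU). Convolutions excel at local motif patterns.
* **Teacher 2 (Bi-LSTM)** — two stacked bidirectional LSTM layers
  (32 units per direction, sequence output), capturing long-range,
  position-aware context.
* **Student** — a compact hybrid; the default `KD3` variant applies one
  convolution layer and then one Bi-LSTM layer (local motifs first, context
  second). `KD4` reverses the order; `KD1`/`KD2` are single-architecture
  controls aligned with only one teacher.

The head is global max pooling over the sequence axis, dropout 0.4, and a
dense layer emitting two logits. The head is a design choice of this package: global max pooling is the
simplest head consistent with sequence-output recurrent layers, and it is
stated explicitly because parameter totals depend on it. `count_parameters()` uses the standard
closed-form counts and is tested against instantiated weight tensors.

```{r}
tidy(build_student("KD3"))
```

## Knowledge distillation

Teachers are trained first, independently, on hard labels (softmax
cross-entropy, Adam). They are then frozen. The student sees three signals
per mini-batch: its own cross-entropy $L_{student}$ on hard labels, and one
distillation term per teacher,

$$L_{distill_i} = \tau^2 \cdot KL\left(\sigma(T_i/\tau)\,\|\,\sigma(S/\tau)\right),$$

where $\sigma$ is the softmax, $T_i$ and $S$ are teacher and student logits,
and $\tau$ is the temperature. Dividing logits by $\tau > 1$ softens the
distributions so that inter-class similarity information survives; the
$\tau^2$ factor keeps gradient magnitudes comparable across temperatures.
The combined objective is

$$L_{total} = \alpha\,L_{student} + (1-\alpha)\,(L_{distill_1} + L_{distill_2}).$$

Conventions worth stating:

* KL direction is teacher-to-student, the standard distillation convention;
  the teacher distribution is a constant (no gradient flows through it).
* The two distillation losses are *summed*, not averaged.
* $L_{student}$ is computed at temperature 1.
* Teachers are evaluated in inference mode (dropout off) inside the training
  loop; targets are not cached.
* $\alpha = 1$ makes distillation a no-op: training is then loss-identical
  to plain student training under the same seed, which the test suite checks
  bit-for-bit.

Package defaults: $\alpha = 0.5$, $\tau = 10$, Adam with
learning rate $10^{-4}$, dropout 0.4, 50 epochs, batch size 16.

## Evaluation

Predictions take the argmax of the two logits (a 0.5 probability threshold;
ties break toward the non-site class). Performance is summarized by
sensitivity, specificity, accuracy and the Matthews correlation coefficient
(MCC), the balanced statistic of choice under the heavy class imbalance of
site prediction. A zero MCC denominator returns 0 with an explicit flag.
`cross_validate()` runs stratified $k$-fold cross-validation (default 10)
and reports each metric's across-fold mean and sample standard deviation;
teachers and student are retrained inside every fold by default
(`retrain_teachers = FALSE` reuses globally trained teachers — faster but
optimistically biased). `ablation_grid()` sweeps
$\alpha \in \{0.3, 0.5, 0.7\} \times \tau \in \{3, 5, 10\}$; since teachers
do not depend on $\alpha$ or $\tau$, they are trained once per fold and
shared across the grid. `residue_enrichment()` contrasts per-position
residue frequencies between classes with a two-proportion z-test (the
two-sample-logo convention), and `tsne_project()` embeds pooled
penultimate-layer features in 2-D to visualize class separation before and
after training.

## The synthetic benchmark

Real curated datasets live behind external services, so the package carries
a generator that emulates their structure and makes every stage testable:

* **Background proteins** — i.i.d. residues, uniform over the 20 amino
  acids except lysine, whose frequency is boosted to 0.10 so each protein
  reliably offers several candidate sites (at least three are guaranteed).
* **Motif** — positives deviate from background only through
  position-specific residue enrichment, the same structure two-sample logos
  reveal in real succinylation data. A `motif_spec()` maps window offsets to
  boosted residues; several residues may share an offset (a palette). The
  default motif boosts a five-residue palette (total weight 0.95) at each
  of the six offsets $-3..3$. Palettes matter: a strong single-residue motif
  would make positive windows more than 30% identical to each other, so the
  redundancy filter itself would remove most of them, whereas palettes keep
  the class signal strong while pairwise identity stays below the cutoff.
* **Negatives** — lysines from separate background-only proteins, so
  negative flanks are pure background. Drawing negatives from the same
  proteins as positives would place implanted motifs off-center inside
  negative windows and blur the class boundary for position-invariant
  architectures (empirically this caps the CNN teacher near MCC 0.65).
* **Assembly** — through `build_dataset()`: classes are windowed and
  redundancy-filtered independently (training data only), then training
  negatives are downsampled to twice the positives, mirroring the 1:2
  convention of curated training sets; the test set is either left fully
  imbalanced or capped at a configured ratio (`synth_config()` defaults to
  10:1, emulating the heavier imbalance of real independent test sets).

The documented recovery benchmark (`default_benchmark_config()`) uses 1500
positive training sites at ratio 2 and a 300/600 test set at full motif
strength — large enough for all three networks to reach high test MCC,
small enough for minutes-scale CPU training. What passing it shows is that
the full pipeline — extraction, filtering, ratio assembly, teacher training,
distillation, evaluation — recovers a planted positional signal; it does
not certify performance on real proteomes, whose homology structure,
composition biases and weak motifs the generator deliberately does not
simulate.

## Numerical and reproducibility choices

* **Redundancy filter** — a deterministic greedy single-pass clustering at
  30% identity (a fragment is kept iff its identity to every earlier kept
  fragment is at most the cutoff), with `X` an ordinary character. CD-HIT
  itself cannot cluster below 40% identity, so a deterministic, testable
  exact filter stands in for it; an
  exhaustive pairwise audit backs the property test.
* **Initialization** — embedding uniform $(-0.05, 0.05)$; Glorot uniform
  for convolution, dense, and LSTM input kernels; block-orthogonal LSTM
  recurrent kernels; forget-gate bias 1.
* **Optimizer** — Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
  $\epsilon = 10^{-7}$), fixed epochs, no schedule, no early stopping.
* **Determinism** — all randomness (initialization, shuffling, dropout,
  negative downsampling, fold assignment) flows through R's RNG from a
  single seed; the compiled kernels are single-threaded and deterministic,
  and the test suite asserts bit-for-bit reproducibility of histories,
  folds and metrics. Analytic gradients of every architecture are checked
  against central finite differences.
* **Problem sizes in the test suite** — unit tests use reduced embeddings
  (dimension 8) and short windows; the end-to-end recovery run uses the
  default benchmark with teachers trained for the full 50 epochs and the
  student shortened to 20 (the distilled student converges markedly faster
  than its teachers, one of the practical benefits of soft targets);
  null-calibration runs use 300 positive sites and 4 epochs over three
  seeds. These sizes are the package's documented test conditions and keep
  the whole suite in the tens-of-minutes range on a single CPU.

## Known limitations

* The backend is a purpose-built RcppArmadillo engine, not a general
  deep-learning framework: only the layer vocabulary used by these
  architectures is implemented, and training is single-threaded CPU.
* Reported parameter totals reflect the global-max-pool head stated above;
  other head choices give different totals.
* The synthetic generator draws i.i.d. backgrounds: no homology, no
  compositional bias, no species structure. Conclusions about real
  proteomes require real data through the same interfaces (FASTA + site
  TSV, or pre-cut fragment files).
* With extreme class ratios a fold can lack positives only if the dataset
  is tiny; `cross_validate()` refuses fewer than $k$ examples per class.
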