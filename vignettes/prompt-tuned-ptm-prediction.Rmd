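---
title: "Multi-task PTM site prediction by prompt tuning a frozen residue encoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task PTM site prediction by prompt tuning a frozen residue encoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmtune)
```

## The problem

Post-translational modifications (PTMs) — phosphorylation, glycosylation,
ubiquitination, acetylation, methylation, SUMOylation, succinylation,
palmitoylation — are covalent changes to specific residue types that regulate
protein function. Predicting which candidate residues of a protein carry a
given PTM is a per-residue binary classification problem with two defining
features: extreme class imbalance (most serines are not phosphorylated), and
strong dependence on both local sequence motifs and longer-range context.

`ptmtune` implements a multi-task framework for this problem built around
three ideas:

1. **Prompt tuning on a frozen residue encoder.** A pre-trained protein
   language model supplies per-residue embeddings and is never updated.
   Instead, a small trainable matrix of "task prompts" (K rows of width D)
   is prepended to each protein's embedded token stream. The encoder
   processes prompts and residues jointly, so gradients flowing back through
   the (frozen) encoder adjust only the prompts, steering the residue
   embeddings toward the task.
2. **A shared decoder with task-specific heads.** Two inception modules of
   1D convolutions (three parallel kernels each), their outputs
   concatenated, feed a shared fully connected layer; one independent
   logistic head per PTM task converts the shared representation into
   per-residue probabilities.
3. **Knowledge distillation from single-task teachers.** Single-task models
   are trained first; their per-site probabilities ("soft labels") are
   blended with ground truth — target $\gamma y + (1-\gamma)p_\text{teacher}$
   — and combined across tasks with dataset-size-dependent weights to train
   one multi-task student.

## Corpus construction

Corpora are built from full-length sequences (FASTA) and per-residue
annotations (TSV with `protein_id`, `position`, `residue`,
`annotation_text`, `year`). Each annotation string is matched exactly (after
whitespace normalization) against an editable task registry; the bundled
registry covers 13 PTM tasks with their UniProt feature strings. One
annotation string may legitimately map to more than one task on the same
residue (e.g. a combined acetyl/methyl-lysine string), in which case a site
annotation is produced for each.

For one protein and one task, annotated candidate-residue positions are
positives and every other occurrence of the candidate residue is a negative;
all other positions are masked out of the loss and the metrics. This gives
the conservation invariant `|positives| + |negatives| = #candidate residues`
that the tests assert throughout.

Three processing rules matter:

* **Length cap, no truncation.** Sequences longer than 1022 residues are
  excluded entirely (`filter_by_length()`), never truncated — truncation
  could cut away the very motifs being predicted. 1022 matches the input
  limit of the ESM2-style encoders this framework targets.
* **Temporal split.** Records first annotated before the cutoff year
  (default 2010) form the training set; the rest are the test set. "Before"
  and "after" leave the boundary year itself ambiguous; we assign it to
  **test**, which keeps training strictly pre-cutoff (the conservative
  choice). A protein carries a single `annotation_year` — the earliest year
  among its annotation rows. Proteins annotated both before and after the
  cutoff therefore land in train; without the original database snapshot any
  such convention is an approximation, and ours is documented rather than
  hidden.
* **Residue validation.** Sequences may contain the 20 standard letters plus
  `X` (never a candidate residue); ambiguity codes B/Z/U are rejected at
  load with a clear error. Duplicate annotations of one site are
  deduplicated silently, making labeling idempotent.

Species filtering is accepted as a pre-filtered input; no taxonomy lookup is
performed. Sequence-similarity stratification consumes externally produced
cluster-membership files (e.g. CD-HIT-2D output) and is used only to split
evaluation reports.

## The encoder contract and the toy encoder

The framework is encoder-agnostic: anything that maps the token stream
`[CLS], prompt rows, residue rows, [EOS]` (width $K + L + 2$) to
equally-shaped embeddings, processes prompts and residues jointly, and is
differentiable with respect to its inputs satisfies the contract. After
encoding, `strip_specials()` removes the prompt and special rows so exactly
$L$ residue embeddings remain (row $i$ of the output is stream row
$1 + K + i$).

Two conventions are deliberate choices where the underlying scheme is open:

* **Token order** is `[CLS]`, prompts, residues, `[EOS]` — prompts precede
  the sequence as in standard soft-prompt tuning.
* **Prompt positions** are ordinary positions in the positional-encoding
  scheme, with no special masking. This is the simplest contract an adapter
  for a real protein language model can also satisfy.

Because no deep-learning framework is a dependency, the package ships a
deterministic **toy encoder** (`toy_encoder()`): seed-generated token
embeddings, sinusoidal positional encodings, and per layer a single-head
softmax attention block plus a tanh feed-forward block, both residual. Its
forward and backward passes are hand-written matrix algebra; the backward
pass is verified against central finite differences in the test suite
(agreement to ~1e-10 at perturbation 1e-6). The toy encoder is *not* a
protein language model — it encodes no evolutionary knowledge — but it
preserves every structural property the framework relies on: prompts
influence residue outputs (asserted by perturbation tests), encoding is a
pure function of (weights, prompt, sequence), and gradients reach the
prompts while the encoder parameters stay bit-identical.

## Prompt initialization

Prompt tuning is sensitive to initialization, so prompts start from
prototypical PTM-context vectors rather than noise:

1. Encode every training protein **without any prompt** (the prompt does not
   exist yet — this ordering is explicit because nothing else pins it down).
2. Around each positive site $i$, take the 21-residue window
   $\max(1, i-10) \dots \min(L, i+10)$. Boundary windows are clipped, not
   zero-padded.
3. Mean-pool each window column-wise: $1/21$ per row in the interior, $1/w$
   for a clipped window of $w$ rows — dividing by 21 at boundaries would
   bias those means toward zero.
4. Cluster the site means into $K$ groups with seeded K-means.
5. Stack the $K$ centroids into the initial $K \times D$ prompt.

Only positive sites feed initialization (negatives carry no PTM context),
and the pipeline runs per task; pooling several tasks' positives through one
shared prompt is possible by passing merged annotations.

K-means details, fixed because the procedure must be reproducible: k-means++
seeding, Lloyd iterations, at most 300 sweeps, convergence when assignments
stabilize or the relative inertia change drops below 1e-4; an emptied
cluster is re-seeded at the point currently farthest from its centroid. On
exit centroids are recomputed as exact member means, so the centroid/member
fixed point holds to numerical precision. `stats::kmeans` is used as an
independent cross-check in tests (same partition on well-separated data),
not as the implementation, because it provides neither k-means++ seeding nor
the empty-cluster policy above.

$K$ defaults to 500 at full scale (the regime a real encoder with D = 1280
targets); all desk-scale tests and examples use small $K$ (2–8), which the
synthetic tasks support. The sweep that would justify any particular $K$ on
real data is out of scope.

## Training

**Teachers (step 1).** One single-task model per task — prompt + shared
stack + a single head — trained with masked binary cross-entropy on that
task's labeled sites. Teachers are then frozen and produce a soft label for
every labeled training site.

**Student (step 2).** One model with per-task prompts, one shared stack, and
one head per task, trained on the weighted blended loss

$$L(\theta) = \sum_{t} w_t \sum_{(x,y) \in D_t}
  \ell\big(\gamma y + (1-\gamma) f_t(x;\theta_t),\, f_t(x;\theta)\big),$$

with $\ell$ the binary cross-entropy with a probabilistic first argument
(the natural choice for binary site classification with soft targets; the
loss kernel is otherwise unspecified). The implementation accepts
$\gamma$ in the closed interval $[0,1]$: $\gamma = 1$ reduces exactly to
hard-label multi-task training (the distillation-off ablation) and
$\gamma = 0$ is pure distillation. Two schedules are provided — fixed
$\gamma$ (default 0.5, the stated setting) and linear teacher annealing from
$\gamma_0$ to $\gamma_\text{final}$ over training, for shifting supervision
from teacher toward ground truth. Both exist because "a fixed blend of 0.5"
and "progressive annealing" are each defensible readings of the training
recipe; fixed 0.5 is the default.

**Task weights** counter the size imbalance of concatenated per-task
datasets: the default rule is $w_t \propto 1/|D_t|$, rescaled so
$\sum_t w_t = |T|$ (equal sizes give all weights 1); uniform and
proportional rules are selectable. Inverse size is the default because the
weights exist to stop large tasks from drowning small ones.

**Optimization.** Adam (lr 1e-3 by default, batch 8 proteins,
task-homogeneous batches interleaved round-robin across tasks — each batch
uses its task's prompt and head, which makes the prompt-per-task design
well-defined). Batch gradients are normalized by the number of labeled
sites in the batch. Training runs a fixed number of epochs; early stopping
is deliberately not built in, keeping runs exactly reproducible from
(data, seed, epoch count) alone. All shuffling derives from the training
seed, so identical seeds give bit-identical parameters.

Student prompts are re-initialized by the same K-means procedure rather than
inherited from teachers (inheritance is available via the `prompts`
argument); re-initialization keeps the student's starting point independent
of teacher training noise.

**What stays frozen.** The encoder is excluded from the parameter tree
entirely, so its parameters cannot change — the tests nevertheless assert
bit-identity after training and that prompt entries did change, because that
contract is the crux of prompt tuning.

## Evaluation

Metrics are computed over labeled candidate sites only — consistent with the
loss masking; accuracy over all residues would be meaninglessly inflated by
the masked majority. Threshold metrics (accuracy, precision, recall, F1,
MCC) use a default decision threshold of 0.5 (exposed as an argument; no
single threshold is canonical for these models). Degenerate denominators
produce 0 plus a `degenerate` flag rather than NaN. AUROC uses the
Mann–Whitney formulation with midrank ties; AUPRC is the step-wise
precision–recall integral, whose value for uninformative scores
concentrates at the positive prevalence — the property that makes it the
headline metric under imbalance. Stratified reports split by externally
supplied per-protein similarity bins; single-class bins report ranking
metrics as not computable instead of erroring.

## The synthetic benchmark

The simulator emulates the one property of real PTM data that makes these
models learnable at all: positives sit in recurring local motifs around the
candidate residue. Background sequences are drawn from Swiss-Prot-like
residue frequencies (uniform is available); each eligible candidate residue
receives the task's consensus motif with probability `p_plant` (default
0.3); planted sites are annotated with probability `1 - label_noise`
(default noise 0.05, emulating incomplete annotation); annotation years are
drawn from {2005, 2015} so temporal splits are non-trivial. The standard
desk-scale benchmark is 300 proteins of 40–80 residues with a serine task
(motif `RRSDE`) and a lysine task (motif `LPKRG`); these values were chosen
once as a realistic-but-solvable testbed and are part of the package's
fixed study conditions. A shared-structure variant plants co-occurring
site pairs of two tasks in overlapping 21-residue windows at a configurable
rate, as a testbed for multi-task transfer.

What the simulator does **not** emulate: real embedding statistics,
structural context (solvent accessibility, folds), kinase-family structure,
annotation biases correlated with protein families, and long-range
determinants of modification. Passing the learning smoke tests therefore
shows the machinery is correct and the optimization works — it does not
certify performance on real proteomes, which additionally requires a real
pre-trained encoder behind the adapter seam.

## Numerical choices and degenerate inputs

* Cross-entropy clamps probabilities at 1e-12 before the log; logistic heads
  cannot emit 0 or 1 exactly, so this only guards pathological inputs.
* Convolutions use same-length zero padding with odd kernels (default 3, 7,
  11), so every stack stage preserves sequence length down to L = 1.
* The two inception modules are wired serially and their outputs
  concatenated before the fully connected layer (module 1 feeds module 2;
  the FC layer sees both) — the most literal reading of "two modules whose
  outputs are concatenated"; a serial-only mode (`concat_modules = FALSE`)
  is available.
* Weight initialization is He-style scaled Gaussian, seeded; decoder widths
  (8 channels per branch, hidden 32) are configuration values with no
  canonical setting.
* Empty FASTA records, single-class training data, missing soft labels,
  over-length sequences, and unknown tasks are hard errors, not warnings.

## Problem sizes used by the tests

The suite exercises everything at desk scale, chosen so the full run
completes in a few minutes: toy encoders of D = 12–16 with 2 layers,
corpora of 15–300 proteins, K = 2–4 prompts, 2–25 training epochs with
learning rate 5e-3 for the smoke tests. The end-to-end check trains both
teachers and the distilled student on the 300-protein benchmark and
requires held-out AUPRC to beat the positive prevalence by at least 0.2 on
each task; the distillation-versus-hard-label comparison over five seeds is
reported as a directional observation rather than asserted, since at this
scale both regimes essentially solve the synthetic tasks.

## Limitations

* No real pre-trained protein language model ships with the package; all
  shipped results are on synthetic corpora through the toy encoder. The
  adapter seam (`EncoderSpec`-style contract) is the integration point.
* Pure-R training is fast at desk scale but not designed for
  proteome-scale corpora or K = 500 prompts with D = 1280; the algorithms
  are the contribution, not the throughput.
* The temporal split approximates the true first-annotation timestamp by
  the earliest year in the supplied table; reproducing any specific
  historical database split requires that database's snapshot.
* Sequence-similarity control (CD-HIT) is consumed, not implemented.
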