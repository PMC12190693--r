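# ptmtune

Multi-task prediction of post-translational modification (PTM) sites by
prompt tuning a frozen protein residue encoder, with knowledge-distilled
multi-task training.

## What problem this solves, and for whom

PTMs — phosphorylation, glycosylation, ubiquitination, acetylation,
methylation, SUMOylation, succinylation, palmitoylation — occur at specific
residue types ("candidate residues": S for phosphoserine, K for
SUMOylation, …). Predicting which candidate residues of a full-length
protein carry a modification is a per-residue binary classification problem
with severe class imbalance and strong motif/context dependence.

`ptmtune` is for computational biologists who want a fully testable,
encoder-agnostic implementation of the modern recipe for this problem:

* **Corpus construction** from FASTA + UniProt-style per-residue annotation
  tables: positive = annotated candidate residue, negative = every other
  occurrence of the same residue, loss masked elsewhere; a 1022-residue
  length cap without truncation; a temporal train/test split at a cutoff
  year (default 2010; the boundary year goes to test).
* **Prompt tuning**: a trainable `K x D` prompt matrix per task is prepended
  to the encoder's token stream (`[CLS]`, prompts, residues, `[EOS]`); the
  encoder stays frozen and only the prompts (plus decoder) receive
  gradients. Prompts are initialized by K-means: mean-pooled 21-residue
  embedding windows around positive sites, clustered into `K` groups, the
  centroids stacked:

  $$M = [\mu_1; \mu_2; \dots; \mu_K], \qquad
    \mu_k = \tfrac{1}{|C_k|} \textstyle\sum_{\bar E_i \in C_k} \bar E_i, \qquad
    \bar E_i = \tfrac{1}{21} \textstyle\sum_{j=i-10}^{i+10} E_j .$$

* **A shared decoder** (two inception modules of three 1D convolutions with
  kernels 3/7/11, concatenated, plus a fully connected layer) with one
  independent logistic head per task.
* **Knowledge distillation**: single-task teachers produce soft labels;
  the multi-task student trains on the dataset-size-weighted loss

  $$L(\theta) = \sum_{t \in T} w_t \sum_{(x,y) \in D_t}
    \ell\big(\gamma y + (1-\gamma) f_t(x;\theta_t),\; f_t(x;\theta)\big),$$

  with binary cross-entropy $\ell$, blend weight $\gamma$ (fixed 0.5 by
  default, linear teacher annealing available), and
  $w_t \propto 1/|D_t|$ rescaled to sum to $|T|$.
* **Evaluation** with the metrics that matter under imbalance: accuracy,
  precision, recall, F1, MCC at a threshold, and AUROC (midrank
  Mann–Whitney) / AUPRC (step-wise PR integration), optionally stratified
  by externally supplied sequence-similarity bins (CD-HIT-2D output).

No deep-learning framework is required: the package ships a deterministic
toy self-attention encoder and hand-derived, finite-difference-verified
gradients, so the entire pipeline — including distillation — runs and is
tested at desk scale in pure R. A real protein language model can be
plugged in behind the same encoder contract.

## Worked example

Simulate a motif-driven corpus (the package's standard synthetic benchmark
at reduced size), split it temporally, train a single-task teacher, and
evaluate on held-out proteins:

```r
library(ptmtune)

cfg <- synthetic_corpus_config(n_proteins = 120, seed = 11)
corpus <- generate_synthetic_corpus(cfg)
registry <- synthetic_task_registry(cfg)
corpus
#> <ptm_synthetic_corpus> 120 protein(s), 192 annotation(s), seed 11
#>                 task n_trials n_planted
#>  Phosphorylation (S)      427       119
#>    Succinylation (K)      317        89

split <- temporal_split(corpus$records)
split
#> <ptm_corpus_split> cutoff 2010: 51 train / 69 test record(s)

encoder <- toy_encoder(seed = 7, D = 16)
task <- registry[["Phosphorylation (S)"]]
teacher <- train_teacher(split$train, corpus$annotations, task, encoder,
                         K = 4, seed = 1,
                         hyper = train_config(epochs = 15, lr = 5e-3))
teacher
#> <ptm_teacher> Phosphorylation (S), prompt 4 x 16, final training loss 0.0002323

scores <- score_sites(teacher, split$test, corpus$annotations, task, encoder)
metric_report(scores)
#> <ptm_metric_report> n = 251 (66 pos / 185 neg), threshold 0.5
#>  accuracy precision    recall        f1       mcc     auroc     auprc
#>     0.976     0.929     0.985     0.956     0.940     0.989     0.954
```

The report reads: of the 251 labeled serines in the test proteins, 66 are
true sites; at threshold 0.5 the teacher finds essentially all of them
(recall 0.985) with few false calls (precision 0.929), and the ranking
metrics (AUPRC 0.954 against a positive prevalence of 0.26) show the planted
motif has been learned rather than memorized — these are held-out proteins
from annotation years the model never saw.

Per-protein site predictions, restricted to candidate residues:

```r
head(predict_sites(teacher, split$test[1, ], encoder, task), 3)
#>   protein_id position residue  probability
#> 1    SYN0001       10       S 9.998151e-01
#> 2    SYN0001       25       S 4.635454e-09
#> 3    SYN0001       28       S 8.565615e-09
```

For the full two-step distillation recipe — teachers for every task,
`generate_soft_labels()`, then `train_student()` with a
`blend_schedule()` — see `?train_student` and the methods vignette in
`vignettes/prompt-tuned-ptm-prediction.Rmd`. A thin command-line front end
(`inst/cli/ptmtune.R`) exposes `simulate`, `build-dataset`, `init-prompts`,
`train`, and `evaluate` subcommands.

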