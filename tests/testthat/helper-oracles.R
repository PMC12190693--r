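# Independent oracles and small fixture builders shared by the test files.
# Oracles are deliberately written in the most literal way possible (loops,
# explicit pair enumeration) and never call the package code paths they
# check.

# Confusion-matrix metrics by explicit counting.
oracle_threshold_metrics <- function(probs, labels, threshold = 0.5) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(probs)) {
    pred <- if (probs[i] >= threshold) 1 else 0
    if (pred == 1 && labels[i] == 1) tp <- tp + 1
    if (pred == 1 && labels[i] == 0) fp <- fp + 1
    if (pred == 0 && labels[i] == 0) tn <- tn + 1
    if (pred == 0 && labels[i] == 1) fn <- fn + 1
  }
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(accuracy = (tp + tn) / length(probs), precision = prec, recall = rec,
       f1 = f1, mcc = mcc)
}

# AUROC by exhaustive positive/negative pair comparison, ties counting 1/2.
oracle_auroc_pairwise <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Weighted distillation loss as a literal per-site sum.
oracle_distillation_loss <- function(sites, gamma, weights) {
  total <- 0
  for (i in seq_len(nrow(sites))) {
    target <- gamma * sites$y[i] + (1 - gamma) * sites$teacher_p[i]
    p <- sites$student_p[i]
    term <- -(target * log(max(p, 1e-12)) +
                (1 - target) * log(max(1 - p, 1e-12)))
    total <- total + weights[[sites$task[i]]] * term
  }
  total
}

# ---- fixtures --------------------------------------------------------------

phospho_s_task <- function() {
  ptm_task("Phosphorylation (S)", "S", c("Phosphoserine", "Diphosphoserine"))
}

sumo_k_task <- function() {
  ptm_task("SUMOylation (K)", "K", "Glycyl lysine isopeptide")
}

# A two-protein corpus with hand-placed annotations, written to temp files.
write_tiny_corpus_files <- function(dir = withr::local_tempdir(
                                      .local_envir = parent.frame())) {
  fasta <- file.path(dir, "seqs.fasta")
  writeLines(c(">P1 some description", "MSKSPS",
               ">P2", "MKTSYKA"), fasta)
  ann <- data.frame(protein_id = c("P1", "P1", "P2"),
                    position = c(4L, 2L, 6L),
                    residue = c("S", "S", "K"),
                    annotation_text = c("Phosphoserine", "Diphosphoserine",
                                        "Glycyl lysine isopeptide"),
                    year = c(2005L, 2005L, 2015L))
  ann_path <- file.path(dir, "ann.tsv")
  write.table(ann, ann_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, annotations = ann_path, dir = dir)
}

tiny_registry <- function() task_registry(list(phospho_s_task(),
                                               sumo_k_task()))

# Small fast settings used by training tests.
fast_encoder <- function(seed = 7L) toy_encoder(seed, D = 12L, n_layers = 2L)

fast_decoder_config <- function() {
  decoder_config(kernel_sizes = c(3L, 5L, 7L), channels_per_branch = 4L,
                 hidden = 12L)
}
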