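# Seeded synthetic corpora with planted, motif-driven PTM sites. Real PTMs
# are strongly conditioned on short local sequence motifs around the
# modified residue (kinase consensus motifs, glycosylation sequons); the
# simulator emulates exactly that structure — a consensus k-mer written
# around randomly chosen candidate residues — so every module in the
# package can be exercised end-to-end with known ground truth.

# Swiss-Prot-like amino-acid background frequencies (rounded composition of
# UniProtKB/Swiss-Prot), for more realistic negatives than a uniform draw.
AA_FREQ_SWISSPROT <- c(
  A = 0.0826, C = 0.0138, D = 0.0546, E = 0.0672, F = 0.0387, G = 0.0708,
  H = 0.0228, I = 0.0593, K = 0.0581, L = 0.0965, M = 0.0241, N = 0.0406,
  P = 0.0474, Q = 0.0394, R = 0.0553, S = 0.0665, T = 0.0536, V = 0.0686,
  W = 0.0110, Y = 0.0292)

#' Motif model for one synthetic PTM task
#'
#' @param task_name Task identifier (use a registry task name so generated
#'   corpora round-trip through [load_corpus()]).
#' @param candidate_residue The task's candidate amino acid.
#' @param motif Odd-length consensus string with the candidate residue at
#'   its center; planted verbatim around positive sites.
#' @param p_plant Probability that an eligible candidate residue receives a
#'   planted motif (default 0.3).
#' @param label_noise Probability that a planted site is left unlabeled
#'   (it then silently becomes a negative), emulating incomplete
#'   annotation; default 0.05.
#' @param annotation_text Annotation string written to the corpus for this
#'   task's sites (default: the task's first key in the bundled registry,
#'   falling back to `task_name`).
#' @return A list of class `motif_model`.
#' @export
motif_model <- function(task_name, candidate_residue, motif,
                        p_plant = 0.3, label_noise = 0.05,
                        annotation_text = NULL) {
  assert_that(nchar(motif) %% 2L == 1L, "motif length must be odd")
  center <- (nchar(motif) + 1L) %/% 2L
  assert_that(substr(motif, center, center) == candidate_residue,
              "motif must carry the candidate residue at its center")
  assert_that(all(split_sequence(motif) %in% AA_STANDARD),
              "motif letters must be standard amino acids")
  assert_that(p_plant >= 0 && p_plant <= 1 &&
                label_noise >= 0 && label_noise <= 1,
              "p_plant and label_noise must lie in [0, 1]")
  if (is.null(annotation_text)) {
    reg <- tryCatch(default_task_registry(), error = function(e) NULL)
    annotation_text <- if (!is.null(reg) && task_name %in% names(reg)) {
      reg[[task_name]]$annotation_keys[1L]
    } else {
      task_name
    }
  }
  structure(list(task_name = task_name,
                 candidate_residue = candidate_residue,
                 motif = motif, p_plant = p_plant,
                 label_noise = label_noise,
                 annotation_text = annotation_text),
            class = "motif_model")
}

default_motif_models <- function() {
  list(motif_model("Phosphorylation (S)", "S", "RRSDE"),
       motif_model("Succinylation (K)", "K", "LPKRG"))
}

#' Configuration of a synthetic PTM corpus
#'
#' The defaults define the package's standard desk-scale benchmark: 300
#' proteins of 40–80 residues with Swiss-Prot-like background composition,
#' two motif-driven tasks (a serine task and a lysine task), planting
#' probability 0.3, 5% label noise, and annotation years drawn from a
#' two-point distribution straddling the 2010 train/test cutoff.
#'
#' @param n_proteins Number of proteins (default 300).
#' @param length_range Min/max sequence length (max must be <= 1022).
#' @param tasks List of [motif_model()]s.
#' @param background `"swissprot"` (default) or `"uniform"` residue
#'   frequencies.
#' @param years Two-point annotation-year distribution (default 2005/2015,
#'   equal probability).
#' @param seed Integer seed.
#' @return A list of class `synthetic_corpus_config`.
#' @export
synthetic_corpus_config <- function(n_proteins = 300L,
                                    length_range = c(40L, 80L),
                                    tasks = default_motif_models(),
                                    background = c("swissprot", "uniform"),
                                    years = c(2005L, 2015L),
                                    seed = 1L) {
  background <- match.arg(background)
  assert_that(length_range[1L] >= 1L && length_range[2L] <= 1022L &&
                length_range[1L] <= length_range[2L],
              "length_range must lie within [1, 1022]")
  max_motif <- max(vapply(tasks, function(t) nchar(t$motif), numeric(1)))
  if (max_motif > length_range[1L]) {
    stop("motif of length ", max_motif, " does not fit the minimum ",
         "sequence length ", length_range[1L], call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 tasks = tasks, background = background,
                 years = as.integer(years), seed = as.integer(seed)),
            class = "synthetic_corpus_config")
}

background_freqs <- function(cfg) {
  if (cfg$background == "uniform") {
    stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  } else {
    AA_FREQ_SWISSPROT / sum(AA_FREQ_SWISSPROT)
  }
}

#' Generate a seeded synthetic PTM corpus
#'
#' Sequences are drawn from the background composition; for each task, each
#' eligible candidate residue (its motif window inside the sequence and not
#' overlapping an already planted motif) independently receives the task's
#' motif with probability `p_plant`. Planted sites are annotated positive
#' with probability `1 - label_noise`; unplanted (and noise-dropped)
#' candidate residues end up as negatives under [label_sites()]. Ground
#' truth for every planted site is emitted for oracle checks.
#'
#' @param cfg A [synthetic_corpus_config()].
#' @return A list of class `ptm_synthetic_corpus`: `records`,
#'   `annotations` (both in [load_corpus()] output format), `ground_truth`
#'   (`protein_id`, `position`, `task`, `labeled`), `plant_stats`
#'   (per task: eligible trials and planted count), and `cfg`.
#' @export
generate_synthetic_corpus <- function(cfg) {
  with_seed(cfg$seed, generate_corpus_impl(cfg, overlap_rate = NULL))
}

generate_corpus_impl <- function(cfg, overlap_rate = NULL) {
  freqs <- background_freqs(cfg)
  rec_rows <- vector("list", cfg$n_proteins)
  ann_rows <- list()
  truth_rows <- list()
  trials <- stats::setNames(numeric(length(cfg$tasks)),
                            vapply(cfg$tasks, `[[`, character(1),
                                   "task_name"))
  planted_n <- trials
  n_primary <- 0L
  n_cooccur <- 0L

  for (pi in seq_len(cfg$n_proteins)) {
    pid <- sprintf("SYN%04d", pi)
    L <- sample(cfg$length_range[1L]:cfg$length_range[2L], 1L)
    chars <- sample(names(freqs), L, replace = TRUE, prob = freqs)
    occupied <- logical(L)
    year <- sample(cfg$years, 1L)
    planted <- list()  # per task: positions

    for (ti in seq_along(cfg$tasks)) {
      tk <- cfg$tasks[[ti]]
      half <- (nchar(tk$motif) - 1L) %/% 2L
      motif_chars <- split_sequence(tk$motif)
      pos_list <- integer(0)
      i_range <- seq.int(half + 1L, L - half)
      for (i in i_range) {
        span <- (i - half):(i + half)
        if (chars[i] != tk$candidate_residue || any(occupied[span])) next
        trials[tk$task_name] <- trials[tk$task_name] + 1
        if (stats::runif(1L) < tk$p_plant) {
          chars[span] <- motif_chars
          occupied[span] <- TRUE
          pos_list <- c(pos_list, i)
          planted_n[tk$task_name] <- planted_n[tk$task_name] + 1
          # optional co-occurring site for the second task, planted in an
          # overlapping 21-residue window (shared-structure corpora); only
          # sites with room for the second motif count as trials
          if (!is.null(overlap_rate) && ti == 1L &&
              length(cfg$tasks) >= 2L) {
            tk2 <- cfg$tasks[[2L]]
            half2 <- (nchar(tk2$motif) - 1L) %/% 2L
            j <- i + half + half2 + 2L
            span2 <- (j - half2):(j + half2)
            if (j + half2 <= L && !any(occupied[span2])) {
              n_primary <- n_primary + 1L
              if (stats::runif(1L) < overlap_rate) {
                chars[span2] <- split_sequence(tk2$motif)
                occupied[span2] <- TRUE
                planted[[tk2$task_name]] <- c(planted[[tk2$task_name]], j)
                planted_n[tk2$task_name] <- planted_n[tk2$task_name] + 1
                n_cooccur <- n_cooccur + 1L
              }
            }
          }
        }
      }
      planted[[tk$task_name]] <- sort(c(planted[[tk$task_name]], pos_list))
    }

    rec_rows[[pi]] <- data.frame(protein_id = pid,
                                 sequence = paste(chars, collapse = ""),
                                 annotation_year = year,
                                 stringsAsFactors = FALSE)
    for (tk in cfg$tasks) {
      pos <- planted[[tk$task_name]]
      if (!length(pos)) next
      labeled <- stats::runif(length(pos)) >= tk$label_noise
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        protein_id = pid, position = pos, task = tk$task_name,
        labeled = labeled, stringsAsFactors = FALSE)
      if (any(labeled)) {
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          protein_id = pid, position = pos[labeled],
          residue = tk$candidate_residue, task = tk$task_name,
          year = year, stringsAsFactors = FALSE)
      }
    }
  }

  records <- do.call(rbind, rec_rows)
  annotations <- if (length(ann_rows)) do.call(rbind, ann_rows) else
    data.frame(protein_id = character(), position = integer(),
               residue = character(), task = character(), year = integer())
  ground_truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(protein_id = character(), position = integer(),
               task = character(), labeled = logical())
  rownames(records) <- rownames(annotations) <- rownames(ground_truth) <- NULL
  out <- list(records = records, annotations = annotations,
              ground_truth = ground_truth,
              plant_stats = data.frame(task = names(trials),
                                       n_trials = as.numeric(trials),
                                       n_planted = as.numeric(planted_n),
                                       stringsAsFactors = FALSE),
              cfg = cfg)
  if (!is.null(overlap_rate)) {
    out$overlap_stats <- data.frame(n_primary = n_primary,
                                    n_cooccur = n_cooccur,
                                    rate = overlap_rate)
  }
  structure(out, class = "ptm_synthetic_corpus")
}

#' @export
print.ptm_synthetic_corpus <- function(x, ...) {
  cat("<ptm_synthetic_corpus> ", nrow(x$records), " protein(s), ",
      nrow(x$annotations), " annotation(s), seed ", x$cfg$seed, "\n",
      sep = "")
  print(x$plant_stats, row.names = FALSE)
  invisible(x)
}

#' Generate a corpus where two tasks share local sequence structure
#'
#' Like [generate_synthetic_corpus()], but each planted site of the first
#' task additionally receives, with probability `overlap_rate`, a planted
#' site of the second task a few residues downstream, so the two sites'
#' 21-residue context windows overlap. This emulates related PTM types
#' co-occurring in shared sequence neighborhoods — the situation in which
#' multi-task training can transfer knowledge between tasks.
#'
#' @param cfg A [synthetic_corpus_config()] with at least two tasks.
#' @param overlap_rate Probability of a co-occurring second-task site per
#'   first-task site (default 0.5).
#' @return A `ptm_synthetic_corpus` with an extra `overlap_stats` field.
#' @export
make_two_task_shared_structure <- function(cfg, overlap_rate = 0.5) {
  assert_that(length(cfg$tasks) >= 2L,
              "shared-structure corpora need at least two tasks")
  assert_that(overlap_rate >= 0 && overlap_rate <= 1,
              "overlap_rate must lie in [0, 1]")
  with_seed(cfg$seed, generate_corpus_impl(cfg, overlap_rate = overlap_rate))
}

#' Write a synthetic corpus to FASTA + TSV files
#'
#' Writes `sequences.fasta`, `annotations.tsv` (columns `protein_id`,
#' `position`, `residue`, `annotation_text`, `year` — the [load_corpus()]
#' input format) and `ground_truth.tsv` into `dir`.
#'
#' @param corpus A `ptm_synthetic_corpus`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, "sequences.fasta")
  seqs <- Biostrings::AAStringSet(stats::setNames(corpus$records$sequence,
                                                  corpus$records$protein_id))
  Biostrings::writeXStringSet(seqs, fasta)

  text_of <- stats::setNames(
    vapply(corpus$cfg$tasks, `[[`, character(1), "annotation_text"),
    vapply(corpus$cfg$tasks, `[[`, character(1), "task_name"))
  ann <- data.frame(protein_id = corpus$annotations$protein_id,
                    position = corpus$annotations$position,
                    residue = corpus$annotations$residue,
                    annotation_text = text_of[corpus$annotations$task],
                    year = corpus$annotations$year,
                    stringsAsFactors = FALSE)
  ann_path <- file.path(dir, "annotations.tsv")
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  truth_path <- file.path(dir, "ground_truth.tsv")
  utils::write.table(corpus$ground_truth, truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, annotations = ann_path,
              ground_truth = truth_path))
}

#' Task registry matching a synthetic corpus configuration
#'
#' Builds a [task_registry()] whose annotation keys are exactly the
#' annotation strings the simulator writes, so generated corpora round-trip
#' through [load_corpus()] regardless of the task names chosen.
#'
#' @param cfg A [synthetic_corpus_config()].
#' @return A `ptm_task_registry`.
#' @export
synthetic_task_registry <- function(cfg) {
  task_registry(lapply(cfg$tasks, function(tk) {
    ptm_task(tk$task_name, tk$candidate_residue, tk$annotation_text)
  }))
}
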