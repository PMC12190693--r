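# Corpus construction: load full-length sequences plus per-residue PTM
# annotations, derive per-task positive/negative label sets, filter by
# length, and split train/test by annotation year.

#' Load a PTM corpus from FASTA and an annotation table
#'
#' Reads full-length protein sequences and a tab-separated annotation table
#' (columns `protein_id`, `position`, `residue`, `annotation_text`, `year`;
#' header required), maps each annotation string to the task(s) whose
#' `annotation_keys` contain it, and validates positions against the
#' sequences. Annotations matching no registered task are dropped, and
#' annotations whose sequence letter differs from the task's candidate
#' residue are rejected; both counts are reported via `message()`.
#'
#' Each record's `annotation_year` is the earliest `year` among its
#' annotation rows (`NA` if it has none), mirroring the first-annotated
#' timestamp used for temporal splitting.
#'
#' @param fasta_path Path to a FASTA file. The header token before the first
#'   whitespace is the `protein_id`.
#' @param annotation_table_path Path to the annotation TSV.
#' @param task_registry A [task_registry()]; defaults to the bundled 13-task
#'   registry.
#' @return A list with `records` (data.frame: `protein_id`, `sequence`,
#'   `annotation_year`) and `annotations` (data.frame: `protein_id`,
#'   `position`, `residue`, `task`, `year`).
#' @export
load_corpus <- function(fasta_path, annotation_table_path,
                        task_registry = default_task_registry()) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  records <- data.frame(protein_id = ids,
                        sequence = as.character(seqs),
                        annotation_year = NA_integer_,
                        stringsAsFactors = FALSE)
  assert_that(!anyDuplicated(records$protein_id),
              "duplicate protein_id in FASTA")
  validate_sequences(records)

  ann <- utils::read.delim(annotation_table_path, sep = "\t", header = TRUE,
                           quote = "", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  needed <- c("protein_id", "position", "residue", "annotation_text", "year")
  assert_that(all(needed %in% names(ann)),
              paste("annotation table must have columns:",
                    paste(needed, collapse = ", ")))

  missing <- setdiff(ann$protein_id, records$protein_id)
  if (length(missing)) {
    stop("annotation references protein_id(s) absent from FASTA: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  pos_num <- suppressWarnings(as.integer(ann$position))
  bad_pos <- which(is.na(pos_num) | pos_num < 1L)
  if (length(bad_pos)) {
    stop("malformed position in annotation table at line(s) ",
         paste(utils::head(bad_pos + 1L, 5L), collapse = ", "),
         " (1-based positive integers required)", call. = FALSE)
  }
  ann$position <- pos_num

  # map annotation strings to tasks; one annotation may match several tasks
  # that share a key (distinct tasks on the same residue can share strings)
  key_map <- do.call(rbind, lapply(task_registry, function(t) {
    data.frame(key = t$annotation_keys, task = t$task_name,
               candidate_residue = t$candidate_residue,
               stringsAsFactors = FALSE)
  }))
  ann$annotation_text <- normalize_annotation(ann$annotation_text)
  hits <- merge(ann, key_map, by.x = "annotation_text", by.y = "key")
  n_unmapped <- sum(!ann$annotation_text %in% key_map$key)
  if (n_unmapped > 0) {
    message("load_corpus: dropped ", n_unmapped,
            " annotation(s) matching no registered task")
  }

  # verify the annotated position really carries the task's candidate residue
  seq_by_id <- stats::setNames(records$sequence, records$protein_id)
  L_by_id <- nchar(seq_by_id)
  out_of_range <- hits$position > L_by_id[hits$protein_id]
  if (any(out_of_range)) {
    bad <- hits[out_of_range, ][1L, ]
    stop("annotation position ", bad$position, " exceeds length of protein ",
         bad$protein_id, call. = FALSE)
  }
  letter_at <- substr(seq_by_id[hits$protein_id], hits$position, hits$position)
  mismatch <- letter_at != hits$candidate_residue
  if (any(mismatch)) {
    message("load_corpus: rejected ", sum(mismatch),
            " annotation(s) whose residue does not match the task's ",
            "candidate residue")
    hits <- hits[!mismatch, , drop = FALSE]
    letter_at <- letter_at[!mismatch]
  }

  annotations <- data.frame(protein_id = hits$protein_id,
                            position = hits$position,
                            residue = letter_at,
                            task = hits$task,
                            year = as.integer(hits$year),
                            stringsAsFactors = FALSE)
  # silently deduplicate repeated annotations of one (protein, task, position)
  annotations <- unique(annotations[order(annotations$protein_id,
                                          annotations$task,
                                          annotations$position), ])
  rownames(annotations) <- NULL

  if (nrow(annotations)) {
    yr <- tapply(annotations$year, annotations$protein_id, min)
    records$annotation_year <- as.integer(yr[records$protein_id])
  }
  rownames(records) <- NULL
  list(records = records, annotations = annotations)
}

# Sequences may contain the 20 standard letters plus X; ambiguity codes
# B/Z/U (and anything else) are rejected at load time.
validate_sequences <- function(records) {
  ok <- grepl(paste0("^[", paste(AA_ALLOWED, collapse = ""), "]+$"),
              records$sequence)
  if (!all(ok)) {
    bad <- records$protein_id[!ok][1L]
    stop("protein ", bad, " contains letters outside the 20 standard amino ",
         "acids plus X (B/Z/U and other codes are not supported)",
         call. = FALSE)
  }
  assert_that(all(nchar(records$sequence) >= 1L), "empty sequence in FASTA")
  invisible(records)
}

#' Derive the positive/negative label set of one protein for one task
#'
#' Annotated candidate-residue positions are positives; every other
#' occurrence of the task's candidate residue in the sequence is a negative.
#' Positions carrying other residues are unlabeled and never contribute to
#' loss or metrics.
#'
#' @param record One-row data.frame (or list) with `protein_id` and
#'   `sequence`.
#' @param annotations Annotation data.frame as returned by [load_corpus()],
#'   already or not yet filtered to this protein/task (filtering is applied).
#' @param task A [ptm_task()].
#' @return An object of class `ptm_labelset`: list with `protein_id`,
#'   `task_name`, sorted integer vectors `positives` and `negatives`.
#' @export
#' @examples
#' reg <- default_task_registry()
#' rec <- list(protein_id = "P1", sequence = "MSKSPS")
#' ann <- data.frame(protein_id = "P1", position = 4,
#'                   task = "Phosphorylation (S)")
#' label_sites(rec, ann, reg[["Phosphorylation (S)"]])
label_sites <- function(record, annotations, task) {
  L <- nchar(record$sequence)
  sel <- annotations$protein_id == record$protein_id &
    annotations$task == task$task_name
  pos <- sort(unique(as.integer(annotations$position[sel])))
  if (length(pos) && max(pos) > L) {
    stop("annotation position ", max(pos), " outside sequence of length ", L,
         " for protein ", record$protein_id, call. = FALSE)
  }
  cand <- candidate_positions(record$sequence, task$candidate_residue)
  if (length(pos) && !all(pos %in% cand)) {
    stop("annotated position without the candidate residue '",
         task$candidate_residue, "' for protein ", record$protein_id,
         call. = FALSE)
  }
  structure(list(protein_id = record$protein_id,
                 task_name = task$task_name,
                 positives = pos,
                 negatives = sort(setdiff(cand, pos))),
            class = "ptm_labelset")
}

#' @export
print.ptm_labelset <- function(x, ...) {
  cat("<ptm_labelset> ", x$protein_id, " / ", x$task_name, ": ",
      length(x$positives), " positive(s), ", length(x$negatives),
      " negative(s)\n", sep = "")
  invisible(x)
}

#' Drop sequences longer than a maximum length
#'
#' Full-length modeling on a transformer encoder caps input length; the
#' default of 1022 residues matches the ESM2-style input limit. Sequences
#' are never truncated — over-length records are removed entirely.
#'
#' @param records Record data.frame from [load_corpus()].
#' @param max_len Maximum retained length (default 1022).
#' @return The retained records, original order preserved; the dropped count
#'   is reported via `message()`.
#' @export
filter_by_length <- function(records, max_len = 1022L) {
  assert_that(max_len >= 1L, "max_len must be >= 1")
  keep <- nchar(records$sequence) <= max_len
  if (any(!keep)) {
    message("filter_by_length: dropped ", sum(!keep),
            " sequence(s) longer than ", max_len, " residues")
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split records into train and test by annotation year
#'
#' Records first annotated strictly before `cutoff_year` go to training;
#' records annotated in `cutoff_year` or later go to testing, so the
#' training set is strictly pre-cutoff.
#'
#' @param records Record data.frame with a complete `annotation_year`.
#' @param cutoff_year Integer year (default 2010).
#' @return A list of class `ptm_corpus_split`: `train`, `test` (record
#'   data.frames), `cutoff_year`.
#' @export
temporal_split <- function(records, cutoff_year = 2010L) {
  if (anyNA(records$annotation_year)) {
    bad <- records$protein_id[is.na(records$annotation_year)][1L]
    stop("record ", bad, " has no annotation_year; cannot split temporally",
         call. = FALSE)
  }
  in_train <- records$annotation_year < cutoff_year
  train <- records[in_train, , drop = FALSE]
  test <- records[!in_train, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  structure(list(train = train, test = test,
                 cutoff_year = as.integer(cutoff_year)),
            class = "ptm_corpus_split")
}

#' @export
print.ptm_corpus_split <- function(x, ...) {
  cat("<ptm_corpus_split> cutoff ", x$cutoff_year, ": ",
      nrow(x$train), " train / ", nrow(x$test), " test record(s)\n", sep = "")
  invisible(x)
}

#' Per-position loss mask and hard labels for one label set
#'
#' The training loss is evaluated only at labeled candidate-residue
#' positions; all other positions are masked out. `label` is 1 at positives,
#' 0 at negatives, and `NA` at unlabeled (masked) positions.
#'
#' @param labelset A `ptm_labelset` from [label_sites()].
#' @param L Sequence length.
#' @return List with integer `mask` (length `L`, 1 at labeled positions) and
#'   numeric `label` (length `L`).
#' @export
build_loss_mask <- function(labelset, L) {
  labeled <- c(labelset$positives, labelset$negatives)
  assert_that(length(labeled) == 0L || max(labeled) <= L,
              "labeled position beyond sequence length")
  mask <- integer(L)
  mask[labeled] <- 1L
  label <- rep(NA_real_, L)
  label[labelset$positives] <- 1
  label[labelset$negatives] <- 0
  list(mask = mask, label = label)
}

#' Export per-site labels as a TSV table
#'
#' Writes one row per labeled site: `protein_id`, `position`, `residue`,
#' `task`, `label` (1/0), the package's interchange format for label sets.
#'
#' @param records Record data.frame.
#' @param annotations Annotation data.frame.
#' @param task_registry Registry of tasks to export.
#' @param path Output file path (TSV, written with a header).
#' @return Invisibly, the exported data.frame.
#' @export
export_labels <- function(records, annotations, task_registry, path) {
  rows <- list()
  for (task in task_registry) {
    for (i in seq_len(nrow(records))) {
      rec <- records[i, ]
      ls <- label_sites(rec, annotations, task)
      sites <- c(ls$positives, ls$negatives)
      if (!length(sites)) next
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = rec$protein_id,
        position = sites,
        residue = task$candidate_residue,
        task = task$task_name,
        label = rep(c(1L, 0L), c(length(ls$positives), length(ls$negatives))),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), position = integer(),
               residue = character(), task = character(), label = integer())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read an externally produced cluster-membership table
#'
#' Consumes the TSV output of an external sequence-clustering run (e.g.
#' CD-HIT / CD-HIT-2D): columns `protein_id` and `cluster_id` (or
#' `similarity_bin`). Used only to stratify evaluation; no clustering is
#' performed by this package.
#'
#' @param path Path to the membership TSV.
#' @return A data.frame with `protein_id` and `bin`.
#' @export
read_cluster_membership <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  assert_that("protein_id" %in% names(tab),
              "membership table needs a protein_id column")
  bin_col <- intersect(c("similarity_bin", "cluster_id"), names(tab))
  assert_that(length(bin_col) >= 1L,
              "membership table needs a cluster_id or similarity_bin column")
  data.frame(protein_id = tab$protein_id,
             bin = as.character(tab[[bin_col[1L]]]),
             stringsAsFactors = FALSE)
}
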