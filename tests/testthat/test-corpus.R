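test_that("load_corpus reads sequences, maps annotations, and assigns years", {
  files <- write_tiny_corpus_files()
  corpus <- suppressMessages(load_corpus(files$fasta, files$annotations,
                                         tiny_registry()))
  expect_equal(nrow(corpus$records), 2L)
  expect_equal(corpus$records$protein_id, c("P1", "P2"))
  expect_equal(nrow(corpus$annotations), 3L)
  # "Phosphoserine" and "Diphosphoserine" both map to the serine task
  p1 <- corpus$annotations[corpus$annotations$protein_id == "P1", ]
  expect_true(all(p1$task == "Phosphorylation (S)"))
  expect_setequal(p1$position, c(2L, 4L))
  # record year = earliest annotation year
  expect_equal(corpus$records$annotation_year, c(2005L, 2015L))
})

test_that("load_corpus rejects residue mismatches and drops unknown annotations", {
  dir <- withr::local_tempdir()
  writeLines(c(">P1", "MSKT"), file.path(dir, "s.fasta"))
  ann <- data.frame(protein_id = "P1", position = 4L, residue = "K",
                    annotation_text = "Glycyl lysine isopeptide", year = 2000L)
  write.table(ann, file.path(dir, "a.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  # position 4 of MSKT is T, not the K-task's candidate residue
  expect_message(
    corpus <- load_corpus(file.path(dir, "s.fasta"), file.path(dir, "a.tsv"),
                          tiny_registry()),
    "rejected 1")
  expect_equal(nrow(corpus$annotations), 0L)

  ann$annotation_text <- "Some unknown modification"
  write.table(ann, file.path(dir, "a.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_message(
    corpus <- load_corpus(file.path(dir, "s.fasta"), file.path(dir, "a.tsv"),
                          tiny_registry()),
    "dropped 1")
})

test_that("load_corpus hard-errors on unknown ids, bad positions, bad letters", {
  dir <- withr::local_tempdir()
  writeLines(c(">P1", "MSKT"), file.path(dir, "s.fasta"))
  ann <- data.frame(protein_id = "P9", position = 1L, residue = "S",
                    annotation_text = "Phosphoserine", year = 2000L)
  write.table(ann, file.path(dir, "a.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_corpus(file.path(dir, "s.fasta"), file.path(dir, "a.tsv"),
                           tiny_registry()), "P9")

  ann <- data.frame(protein_id = "P1", position = "x", residue = "S",
                    annotation_text = "Phosphoserine", year = 2000L)
  write.table(ann, file.path(dir, "a.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_corpus(file.path(dir, "s.fasta"), file.path(dir, "a.tsv"),
                           tiny_registry()), "line")

  writeLines(c(">P1", "MSBZ"), file.path(dir, "s.fasta"))
  expect_error(load_corpus(file.path(dir, "s.fasta"), file.path(dir, "a.tsv"),
                           tiny_registry()), "B/Z/U")
})

test_that("label_sites: positives are annotated, negatives the complement", {
  task <- phospho_s_task()
  rec <- list(protein_id = "P1", sequence = "MSKSPS")
  ann <- data.frame(protein_id = "P1", position = 4L,
                    task = "Phosphorylation (S)")
  ls <- label_sites(rec, ann, task)
  expect_equal(ls$positives, 4L)
  expect_equal(ls$negatives, c(2L, 6L))

  # no candidate residue -> both sets empty
  ls0 <- label_sites(list(protein_id = "P1", sequence = "MKT"),
                     ann[0, ], task)
  expect_length(ls0$positives, 0L)
  expect_length(ls0$negatives, 0L)

  # all candidate residues annotated -> no negatives
  ann_all <- data.frame(protein_id = "P1", position = c(2L, 4L, 6L),
                        task = "Phosphorylation (S)")
  ls_all <- label_sites(rec, ann_all, task)
  expect_length(ls_all$negatives, 0L)
  expect_equal(ls_all$positives, c(2L, 4L, 6L))

  expect_error(label_sites(rec, data.frame(protein_id = "P1", position = 40L,
                                           task = "Phosphorylation (S)"),
                           task), "outside")
})

test_that("label_sites is idempotent, order-independent, and conserving", {
  task <- phospho_s_task()
  set.seed(11)
  for (i in 1:20) {
    L <- sample(10:60, 1)
    seq <- paste(sample(c("A", "S", "K", "T", "R"), L, replace = TRUE),
                 collapse = "")
    cand <- which(strsplit(seq, "")[[1]] == "S")
    pos <- if (length(cand)) sample(cand, sample(0:length(cand), 1)) else
      integer(0)
    rec <- list(protein_id = "PX", sequence = seq)
    ann <- data.frame(protein_id = rep("PX", 2 * length(pos)),
                      position = c(pos, rev(pos)),   # duplicated, shuffled
                      task = rep("Phosphorylation (S)", 2 * length(pos)))
    ls <- label_sites(rec, ann, task)
    # conservation: |pos| + |neg| = candidate count
    expect_equal(length(ls$positives) + length(ls$negatives), length(cand))
    expect_equal(ls$positives, sort(unique(pos)))
    # independent of order and duplication
    ls2 <- label_sites(rec, ann[sample(nrow(ann)), , drop = FALSE], task)
    expect_identical(ls, ls2)
  }
})

test_that("a residue can be positive for one task and negative for another", {
  # an O-glycosylated serine is a negative for the phosphorylation task
  glyco <- ptm_task("O-Linked Glycosylation (S)", "S", "O-linked serine")
  rec <- list(protein_id = "P1", sequence = "ASTSA")
  ann <- data.frame(protein_id = "P1", position = 2L,
                    task = "O-Linked Glycosylation (S)")
  ls_glyco <- label_sites(rec, ann, glyco)
  ls_phos <- label_sites(rec, ann, phospho_s_task())
  expect_equal(ls_glyco$positives, 2L)
  expect_true(2L %in% ls_phos$negatives)
  expect_length(ls_phos$positives, 0L)
})

test_that("filter_by_length keeps <= max_len, preserves order, logs drops", {
  mk <- function(lens) data.frame(
    protein_id = paste0("P", seq_along(lens), recycle0 = TRUE),
    sequence = vapply(lens, function(L) paste(rep("A", L), collapse = ""),
                      character(1)),
    annotation_year = rep(2000L, length(lens)))
  recs <- mk(c(1022L, 1023L))
  expect_message(kept <- filter_by_length(recs), "dropped 1")
  expect_equal(kept$protein_id, "P1")

  expect_equal(nrow(filter_by_length(mk(integer(0)))), 0L)

  recs5 <- mk(c(5L, 1500L, 800L, 2000L, 1022L))
  kept5 <- suppressMessages(filter_by_length(recs5))
  expect_equal(nrow(kept5), 3L)
  expect_equal(kept5$protein_id, c("P1", "P3", "P5"))
})

test_that("temporal_split partitions by year with 2010 going to test", {
  recs <- data.frame(protein_id = c("A", "B", "C"),
                     sequence = "MS",
                     annotation_year = c(2005L, 2012L, 2010L))
  sp <- temporal_split(recs)
  expect_equal(sp$train$protein_id, "A")
  expect_setequal(sp$test$protein_id, c("B", "C"))   # boundary year -> test

  recs21 <- data.frame(protein_id = paste0("P", 2000:2020), sequence = "MS",
                       annotation_year = 2000:2020)
  sp21 <- temporal_split(recs21, cutoff_year = 2010L)
  expect_equal(nrow(sp21$train), 10L)
  expect_equal(nrow(sp21$train) + nrow(sp21$test), nrow(recs21))
  # deterministic partition
  expect_identical(sp21, temporal_split(recs21, cutoff_year = 2010L))

  recs$annotation_year[2] <- NA
  expect_error(temporal_split(recs), "B")
})

test_that("build_loss_mask marks exactly the labeled positions", {
  task <- phospho_s_task()
  rec <- list(protein_id = "P1", sequence = "MSKSPS")
  ann <- data.frame(protein_id = "P1", position = 4L,
                    task = "Phosphorylation (S)")
  ls <- label_sites(rec, ann, task)
  m <- build_loss_mask(ls, 6L)
  expect_equal(m$mask, c(0L, 1L, 0L, 1L, 0L, 1L))
  expect_equal(m$label[c(2, 4, 6)], c(0, 1, 0))
  expect_true(all(is.na(m$label[c(1, 3, 5)])))
  expect_equal(sum(m$mask), length(ls$positives) + length(ls$negatives))

  empty <- structure(list(protein_id = "P", task_name = "t",
                          positives = integer(0), negatives = integer(0)),
                     class = "ptm_labelset")
  expect_equal(build_loss_mask(empty, 4L)$mask, rep(0L, 4L))
})

test_that("export_labels writes one row per labeled site", {
  files <- write_tiny_corpus_files()
  corpus <- suppressMessages(load_corpus(files$fasta, files$annotations,
                                         tiny_registry()))
  out_path <- file.path(files$dir, "labels.tsv")
  out <- export_labels(corpus$records, corpus$annotations, tiny_registry(),
                       out_path)
  expect_true(file.exists(out_path))
  reread <- read.delim(out_path)
  expect_equal(nrow(reread), nrow(out))
  # P1 = MSKSPS: S at 2,4,6 for phospho; P2 = MKTSYKA: K at 2,6 for sumo
  p1 <- out[out$protein_id == "P1" & out$task == "Phosphorylation (S)", ]
  expect_equal(sort(p1$position), c(2L, 4L, 6L))
  expect_equal(p1$label[order(p1$position)], c(1L, 1L, 0L))
})
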