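# Training-side unit tests. The heavier end-to-end learning checks live in
# test-acceptance.R; here each operation is checked against small oracles.

test_that("blend_targets computes gamma*y + (1-gamma)*p and validates inputs", {
  expect_equal(blend_targets(1, 0.3, 1), 1.0)
  expect_equal(blend_targets(1, 0.3, 0), 0.3)
  expect_equal(blend_targets(1, 0.6, 0.5), 0.8)
  expect_equal(blend_targets(c(0, 1), c(0.2, 0.4), 0.25),
               c(0.75 * 0.2, 0.25 + 0.75 * 0.4))
  expect_error(blend_targets(0.5, 0.3, 0.5), "0 or 1")
  expect_error(blend_targets(1, 1.3, 0.5), "\\[0, 1\\]")
  expect_error(blend_targets(1, 0.3, 1.5), "\\[0, 1\\]")
})

test_that("task weights follow the inverse-size rule and alternatives", {
  expect_equal(compute_task_weights(c(a = 50, b = 50)), c(a = 1, b = 1))
  expect_equal(compute_task_weights(c(a = 100, b = 300)),
               c(a = 1.5, b = 0.5))
  expect_equal(compute_task_weights(c(solo = 123)), c(solo = 1))
  expect_equal(compute_task_weights(c(a = 100, b = 300), rule = "uniform"),
               c(a = 1, b = 1))
  expect_equal(compute_task_weights(c(a = 100, b = 300),
                                    rule = "proportional"),
               c(a = 0.5, b = 1.5))
  expect_error(compute_task_weights(c(a = 0, b = 10)), "positive")
})

test_that("anneal_gamma: fixed and linear schedules", {
  fixed <- blend_schedule("fixed", 0.5)
  for (s in c(0, 10, 1000)) expect_equal(anneal_gamma(s, fixed), 0.5)

  lin <- blend_schedule("linear_anneal", 0, 1, total_steps = 100)
  expect_equal(anneal_gamma(0, lin), 0)
  expect_equal(anneal_gamma(100, lin), 1)
  expect_equal(anneal_gamma(50, lin), 0.5)
  expect_error(anneal_gamma(101, lin), "outside")
  expect_error(blend_schedule("fixed", 1.2), "\\[0, 1\\]")
})

test_that("distillation loss matches the brute-force oracle", {
  sites <- data.frame(
    task = c("A", "A", "B", "B", "A", "B"),
    y = c(1, 0, 1, 0, 1, 1),
    teacher_p = c(0.9, 0.2, 0.7, 0.1, 0.6, 0.95),
    student_p = c(0.8, 0.3, 0.5, 0.2, 0.55, 0.9))
  weights <- c(A = 1.4, B = 0.6)
  for (gamma in c(0, 0.25, 0.5, 1)) {
    expect_equal(multitask_distillation_loss(sites, gamma, weights),
                 oracle_distillation_loss(sites, gamma, weights),
                 tolerance = 1e-10)
  }

  # gamma = 1: identical to the hard-label masked cross-entropy
  hard <- sum(weights[sites$task] *
                ptmtune:::binary_cross_entropy(sites$y, sites$student_p))
  expect_equal(multitask_distillation_loss(sites, 1, weights), hard,
               tolerance = 1e-10)

  # teacher equal to truth -> loss independent of gamma
  sites2 <- sites
  sites2$teacher_p <- sites2$y
  expect_equal(multitask_distillation_loss(sites2, 0.2, weights),
               multitask_distillation_loss(sites2, 0.9, weights),
               tolerance = 1e-12)

  # weighted-loss linearity: doubling one task's weight doubles its part
  wA <- multitask_distillation_loss(sites[sites$task == "A", ], 0.5, weights)
  wB <- multitask_distillation_loss(sites[sites$task == "B", ], 0.5, weights)
  w2 <- weights; w2["A"] <- 2 * w2["A"]
  expect_equal(multitask_distillation_loss(sites, 0.5, w2), 2 * wA + wB,
               tolerance = 1e-10)

  sites$teacher_p[2] <- NA
  expect_error(multitask_distillation_loss(sites, 0.5, weights),
               "soft label")
})

test_that("student probabilities respect 0.5 at a zeroed head and soft-label purity", {
  cfg <- synthetic_corpus_config(n_proteins = 25L, seed = 31L)
  co <- generate_synthetic_corpus(cfg)
  reg <- synthetic_task_registry(cfg)
  enc <- fast_encoder()
  task <- reg[[1]]
  teacher <- train_teacher(co$records, co$annotations, task, enc, K = 2,
                           seed = 4,
                           hyper = train_config(epochs = 2, lr = 5e-3),
                           cfg = fast_decoder_config())

  soft <- generate_soft_labels(teacher, co$records, co$annotations, task, enc)
  expect_true(all(soft$probability > 0 & soft$probability < 1))

  # soft labels equal an independent site-by-site forward pass
  for (i in sample(nrow(soft), 5)) {
    rec <- co$records[co$records$protein_id == soft$protein_id[i], ]
    p <- predict_sites(teacher, rec, enc, task)
    expect_equal(soft$probability[i],
                 p$probability[p$position == soft$position[i]],
                 tolerance = 1e-12)
  }

  # zeroed head -> every probability 0.5
  zeroed <- teacher
  zeroed$heads[[task$task_name]] <- list(w = rep(0, fast_decoder_config()$hidden),
                                         b = 0)
  soft0 <- generate_soft_labels(zeroed, co$records, co$annotations, task, enc)
  expect_true(all(soft0$probability == 0.5))
})

test_that("teacher training reduces loss, is seed-deterministic, frozen-encoder", {
  cfg <- synthetic_corpus_config(n_proteins = 30L, seed = 8L)
  co <- generate_synthetic_corpus(cfg)
  reg <- synthetic_task_registry(cfg)
  enc <- fast_encoder()
  before <- ptmtune:::encoder_param_snapshot(enc)
  hyper <- train_config(epochs = 5, lr = 5e-3)
  t1 <- train_teacher(co$records, co$annotations, reg[[1]], enc, K = 2,
                      seed = 12, hyper = hyper, cfg = fast_decoder_config())
  t2 <- train_teacher(co$records, co$annotations, reg[[1]], enc, K = 2,
                      seed = 12, hyper = hyper, cfg = fast_decoder_config())

  # loss decreases over training
  expect_lt(tail(t1$loss_trace, 1), t1$loss_trace[1])
  # bit-identical reruns with the same seed
  expect_identical(t1$prompts, t2$prompts)
  expect_identical(t1$decoder, t2$decoder)
  expect_identical(t1$heads, t2$heads)
  # encoder untouched
  expect_identical(ptmtune:::encoder_param_snapshot(enc), before)

  # single-class data is a hard error
  ann_pos_only <- co$annotations[0, ]
  expect_error(train_teacher(co$records, ann_pos_only, reg[[1]], enc,
                             K = 2, seed = 1), "positive")
})

test_that("masking: adding unlabeled candidate residues leaves the loss unchanged", {
  # two sequences identical except for extra unannotated serines; per-site
  # loss terms at the labeled positions must coincide
  enc <- fast_encoder()
  cfg <- fast_decoder_config()
  task <- phospho_s_task()
  model <- list(prompts = stats::setNames(list(matrix(0.05, 2, enc$D)),
                                          task$task_name),
                decoder = decoder_init(enc$D, cfg, seed = 9),
                heads = stats::setNames(list(head_init(cfg$hidden, seed = 10)),
                                        task$task_name),
                cfg = cfg)
  rec <- list(protein_id = "P1", sequence = "MASKAPTRQW")
  ann <- data.frame(protein_id = "P1", position = 3L,
                    task = task$task_name)
  ls <- label_sites(rec, ann, task)
  expect_equal(ls$negatives, integer(0))
  fwd <- ptmtune:::model_forward_protein(model, enc, rec, task$task_name)
  loss_labeled <- sum(ptmtune:::binary_cross_entropy(1, fwd$p[3]))

  # same protein, more serines; position 3 keeps its label, the rest are
  # unlabeled for the loss (not in positives/negatives of this label set)
  sites <- data.frame(task = task$task_name, y = 1,
                      teacher_p = 1, student_p = fwd$p[3])
  expect_equal(multitask_distillation_loss(sites, 1,
                                           stats::setNames(1, task$task_name)),
               loss_labeled, tolerance = 1e-12)
})

test_that("student training runs, is deterministic, and supports the KD-off limit", {
  cfg <- synthetic_corpus_config(n_proteins = 40L, seed = 23L)
  co <- generate_synthetic_corpus(cfg)
  reg <- synthetic_task_registry(cfg)
  enc <- fast_encoder()
  hyper <- train_config(epochs = 3, lr = 5e-3)
  dcfg <- fast_decoder_config()

  teachers <- lapply(reg, function(task) {
    train_teacher(co$records, co$annotations, task, enc, K = 2,
                  seed = 2, hyper = hyper, cfg = dcfg)
  })
  soft <- do.call(rbind, lapply(names(reg), function(tn) {
    generate_soft_labels(teachers[[tn]], co$records, co$annotations,
                         reg[[tn]], enc)
  }))

  s1 <- train_student(co$records, co$annotations, reg, enc,
                      soft_labels = soft, K = 2, seed = 3, hyper = hyper,
                      cfg = dcfg)
  s2 <- train_student(co$records, co$annotations, reg, enc,
                      soft_labels = soft, K = 2, seed = 3, hyper = hyper,
                      cfg = dcfg)
  expect_identical(s1$prompts, s2$prompts)
  expect_identical(s1$decoder, s2$decoder)
  expect_named(s1$heads, names(reg))
  expect_equal(sum(s1$weights), length(reg))

  # KD-off: gamma fixed at 1 needs no soft labels and runs hard-label training
  s_hard <- train_student(co$records, co$annotations, reg, enc,
                          soft_labels = NULL, K = 2, seed = 3,
                          schedule = blend_schedule("fixed", 1),
                          hyper = hyper, cfg = dcfg)
  expect_s3_class(s_hard, "ptm_student")

  # missing soft label is a hard error
  expect_error(train_student(co$records, co$annotations, reg, enc,
                             soft_labels = soft[1:3, ], K = 2, seed = 3,
                             hyper = hyper, cfg = dcfg), "soft label")
})
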