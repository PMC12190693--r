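# Two-step distillation training: single-task teachers are trained on
# hard labels, their per-site probabilities become soft labels, and one
# multi-task student is trained on a dataset-size-weighted loss over targets
# that blend ground truth with the teacher probabilities (fixed gamma or
# teacher annealing). The frozen encoder is shared by every model; only
# prompts, the shared decoder stack, and the task heads are trained.

#' Training hyperparameters
#'
#' @param epochs Number of passes over the data (default 30).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Proteins per optimization step (default 8).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 30L, lr = 1e-3, batch_size = 8L) {
  assert_that(epochs >= 1L && lr > 0 && batch_size >= 1L,
              "invalid training configuration")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size)),
            class = "train_config")
}

#' Blend-weight schedule for distillation targets
#'
#' `gamma` weights the ground-truth hard label against the teacher's soft
#' label in the target `gamma * y + (1 - gamma) * p_teacher`. The fixed mode
#' (default `gamma0 = 0.5`) keeps gamma constant; the linear teacher
#' annealing mode moves it from `gamma0` to `gamma_final` over
#' `total_steps`, typically shifting supervision from the teacher toward
#' ground truth as training progresses. The closed interval [0, 1] is
#' accepted so the ablation limits (pure hard labels at gamma = 1, pure
#' distillation at gamma = 0) are expressible.
#'
#' @param mode `"fixed"` or `"linear_anneal"`.
#' @param gamma0 Starting (or constant) blend weight in [0, 1].
#' @param gamma_final End value for the linear mode (defaults to `gamma0`).
#' @param total_steps Steps over which the linear schedule runs; filled in
#'   by the trainer if `NULL`.
#' @return A list of class `blend_schedule`.
#' @export
blend_schedule <- function(mode = c("fixed", "linear_anneal"),
                           gamma0 = 0.5, gamma_final = gamma0,
                           total_steps = NULL) {
  mode <- match.arg(mode)
  assert_that(gamma0 >= 0 && gamma0 <= 1 &&
                gamma_final >= 0 && gamma_final <= 1,
              "gamma values must lie in [0, 1]")
  structure(list(mode = mode, gamma0 = gamma0, gamma_final = gamma_final,
                 total_steps = total_steps),
            class = "blend_schedule")
}

#' Blend weight at a training step
#'
#' @param step Current step, `0 <= step <= total_steps`.
#' @param schedule A [blend_schedule()] with `total_steps` set (ignored in
#'   fixed mode).
#' @return The blend weight gamma in [0, 1].
#' @export
anneal_gamma <- function(step, schedule) {
  if (schedule$mode == "fixed") return(schedule$gamma0)
  total <- schedule$total_steps
  assert_that(!is.null(total) && total >= 1L,
              "linear annealing needs total_steps")
  assert_that(step >= 0 && step <= total, "step outside [0, total_steps]")
  schedule$gamma0 + (schedule$gamma_final - schedule$gamma0) * step / total
}

#' Blend a hard label with a teacher probability
#'
#' The supervision target of distillation training:
#' `gamma * y + (1 - gamma) * p`.
#'
#' @param y Hard label(s) in \{0, 1\}.
#' @param p Teacher probability(ies) in [0, 1].
#' @param gamma Blend weight in [0, 1].
#' @return Blended target(s) in [0, 1].
#' @export
blend_targets <- function(y, p, gamma) {
  assert_that(all(y %in% c(0, 1)), "hard labels must be 0 or 1")
  assert_that(all(p >= 0 & p <= 1), "teacher probabilities must lie in [0, 1]")
  assert_that(length(gamma) == 1L && gamma >= 0 && gamma <= 1,
              "gamma must lie in [0, 1]")
  gamma * y + (1 - gamma) * p
}

#' Per-task loss weights from dataset sizes
#'
#' The multi-task loss weights each task to counter the size imbalance that
#' arises from concatenating very differently sized PTM datasets. The
#' default rule weights tasks by inverse dataset size, rescaled so the
#' weights sum to the number of tasks; `"uniform"` gives every task weight
#' 1 and `"proportional"` weights by size (same rescaling).
#'
#' @param sizes Named positive numeric vector of per-task labeled-site
#'   counts.
#' @param rule `"inverse_size_normalized"` (default), `"uniform"`, or
#'   `"proportional"`.
#' @return Named numeric weights summing to `length(sizes)`.
#' @export
compute_task_weights <- function(sizes,
                                 rule = c("inverse_size_normalized",
                                          "uniform", "proportional")) {
  rule <- match.arg(rule)
  assert_that(all(sizes > 0), "task dataset sizes must be positive")
  raw <- switch(rule,
                inverse_size_normalized = 1 / sizes,
                uniform = rep(1, length(sizes)),
                proportional = as.numeric(sizes))
  w <- raw / sum(raw) * length(sizes)
  stats::setNames(w, names(sizes))
}

#' Multi-task distillation loss on a batch of labeled sites
#'
#' For every labeled site the per-site term is the binary cross-entropy of
#' the student probability against the blended target
#' `gamma * y + (1 - gamma) * p_teacher`; terms are summed within tasks and
#' combined with the per-task weights:
#' \deqn{L = \sum_t w_t \sum_{(x,y) \in D_t} \ell(\gamma y + (1-\gamma)
#'   f_t(x;\theta_t),\; f_t(x;\theta)).}
#'
#' @param sites Data.frame with columns `task`, `y` (0/1), `teacher_p`
#'   (teacher probability; may be `NA`-free only), `student_p`.
#' @param gamma Blend weight in [0, 1].
#' @param weights Named per-task weight vector covering every task present.
#' @return Scalar non-negative loss (a sum, not a mean).
#' @export
multitask_distillation_loss <- function(sites, gamma, weights) {
  assert_that(nrow(sites) >= 1L, "empty site batch")
  if (anyNA(sites$teacher_p)) {
    stop("site(s) missing a teacher soft label", call. = FALSE)
  }
  assert_that(all(sites$task %in% names(weights)),
              "every site's task needs a weight")
  target <- blend_targets(sites$y, sites$teacher_p, gamma)
  terms <- binary_cross_entropy(target, sites$student_p)
  sum(weights[sites$task] * terms)
}

# ---- dataset preparation ---------------------------------------------------

#' Assemble the per-protein training dataset of one task
#'
#' One entry per protein that has at least one labeled site for the task:
#' the record, the labeled positions, and their hard labels.
#'
#' @param records Record data.frame.
#' @param annotations Annotation data.frame.
#' @param task A [ptm_task()].
#' @return List of class `ptm_task_dataset` with attributes `task_name` and
#'   `n_sites`.
#' @export
build_task_dataset <- function(records, annotations, task) {
  entries <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    ls <- label_sites(rec, annotations, task)
    positions <- c(ls$positives, ls$negatives)
    if (!length(positions)) next
    entries[[length(entries) + 1L]] <- list(
      protein_id = rec$protein_id,
      sequence = rec$sequence,
      positions = positions,
      y = rep(c(1, 0), c(length(ls$positives), length(ls$negatives))))
  }
  structure(entries, class = "ptm_task_dataset",
            task_name = task$task_name,
            n_sites = sum(vapply(entries, function(e) length(e$positions),
                                 numeric(1))))
}

dataset_has_both_classes <- function(dataset) {
  ys <- unlist(lapply(dataset, `[[`, "y"))
  length(ys) > 0 && any(ys == 1) && any(ys == 0)
}

# ---- shared fitting loop ---------------------------------------------------
# `target_fn(task_name, entry, step)` returns the per-site supervision
# targets for one protein at the current optimization step. Batches are
# task-homogeneous (each uses its task's prompt and head) and interleaved
# round-robin across tasks.

fit_model <- function(model, encoder, datasets, target_fn, weights, hyper,
                      seed) {
  params <- list(prompts = model$prompts, decoder = model$decoder,
                 heads = model$heads)
  state <- adam_state_init(params)
  task_names <- names(datasets)
  n_batches_task <- vapply(datasets, function(d) {
    ceiling(length(d) / hyper$batch_size)
  }, numeric(1))
  steps_per_epoch <- sum(n_batches_task)
  loss_trace <- numeric(hyper$epochs)
  step <- 0L

  set.seed(seed)
  for (epoch in seq_len(hyper$epochs)) {
    # per-task shuffled batches, interleaved round-robin across tasks
    batches <- list()
    per_task <- lapply(task_names, function(tn) {
      idx <- sample(seq_along(datasets[[tn]]))
      split(idx, ceiling(seq_along(idx) / hyper$batch_size))
    })
    names(per_task) <- task_names
    for (b in seq_len(max(n_batches_task))) {
      for (tn in task_names) {
        if (b <= length(per_task[[tn]])) {
          batches[[length(batches) + 1L]] <- list(task = tn,
                                                  idx = per_task[[tn]][[b]])
        }
      }
    }

    epoch_loss <- 0
    epoch_sites <- 0
    for (batch in batches) {
      tn <- batch$task
      w_t <- weights[[tn]]
      grads <- tree_zeros_like(params)
      n_sites <- sum(vapply(batch$idx, function(i) {
        length(datasets[[tn]][[i]]$positions)
      }, numeric(1)))
      for (i in batch$idx) {
        entry <- datasets[[tn]][[i]]
        fwd <- model_forward_protein(model, encoder, entry, tn,
                                     keep_cache = TRUE)
        target <- target_fn(tn, entry, step)
        # masked weighted BCE: gradient w.r.t. the logit is p - target at
        # labeled positions, zero elsewhere; normalized per batch site count
        dz <- numeric(entry$L %||% nchar(entry$sequence))
        p_lab <- fwd$p[entry$positions]
        dz[entry$positions] <- w_t * (p_lab - target) / n_sites
        epoch_loss <- epoch_loss +
          sum(w_t * binary_cross_entropy(target, p_lab))
        bw <- model_backward_protein(model, encoder, entry, tn, fwd, dz)
        grads$prompts[[tn]] <- grads$prompts[[tn]] + bw$prompt
        grads$decoder <- tree_map2(`+`, grads$decoder, bw$decoder)
        grads$heads[[tn]] <- tree_map2(`+`, grads$heads[[tn]], bw$head)
      }
      upd <- adam_update(params, grads, state, hyper$lr)
      params <- upd$params
      state <- upd$state
      model$prompts <- params$prompts
      model$decoder <- params$decoder
      model$heads <- params$heads
      epoch_sites <- epoch_sites + n_sites
      step <- step + 1L
    }
    loss_trace[epoch] <- epoch_loss / epoch_sites
  }
  model$loss_trace <- loss_trace
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- teachers --------------------------------------------------------------

#' Train a single-task teacher model
#'
#' A teacher is the shared stack with a single classification head, trained
#' on one task's labeled sites with masked binary cross-entropy. The
#' encoder stays frozen; the prompt (K-means-initialized unless supplied)
#' and the decoder/head weights are optimized with Adam. Teachers are the
#' knowledge source for the multi-task student and also serve as the
#' single-task baseline in ablation comparisons.
#'
#' @param records Training record data.frame.
#' @param annotations Annotation data.frame.
#' @param task A [ptm_task()].
#' @param encoder Frozen encoder.
#' @param K Prompt length (default 4 at desk scale; 500 at paper scale).
#' @param seed Integer seed controlling prompt initialization, weight
#'   initialization, and batch shuffling.
#' @param hyper A [train_config()].
#' @param cfg A [decoder_config()].
#' @param prompt Optional pre-built prompt matrix (skips initialization).
#' @return An object of class `ptm_teacher` (fields `task_name`, `prompts`,
#'   `decoder`, `heads`, `cfg`, `loss_trace`, `seed`).
#' @export
train_teacher <- function(records, annotations, task, encoder, K = 4L,
                          seed = 1L, hyper = train_config(),
                          cfg = decoder_config(), prompt = NULL) {
  dataset <- build_task_dataset(records, annotations, task)
  if (!dataset_has_both_classes(dataset)) {
    stop("task '", task$task_name, "' needs at least one positive and one ",
         "negative labeled site to train a teacher", call. = FALSE)
  }
  if (is.null(prompt)) {
    prompt <- init_task_prompts(records, annotations, task, encoder,
                                K = K, seed = seed)
  }
  model <- list(prompts = stats::setNames(list(unclass_prompt(prompt)),
                                          task$task_name),
                decoder = decoder_init(encoder$D, cfg, seed = seed),
                heads = stats::setNames(list(head_init(cfg$hidden,
                                                       seed = seed + 1L)),
                                        task$task_name),
                cfg = cfg)
  datasets <- stats::setNames(list(dataset), task$task_name)
  weights <- stats::setNames(1, task$task_name)
  model <- fit_model(model, encoder, datasets,
                     target_fn = function(tn, entry, step) entry$y,
                     weights = weights, hyper = hyper, seed = seed)
  model$task_name <- task$task_name
  model$seed <- seed
  class(model) <- "ptm_teacher"
  model
}

unclass_prompt <- function(prompt) {
  attr(prompt, "task_name") <- NULL
  attr(prompt, "trainable") <- NULL
  prompt
}

#' @export
print.ptm_teacher <- function(x, ...) {
  cat("<ptm_teacher> ", x$task_name, ", prompt ",
      nrow(x$prompts[[1L]]), " x ", ncol(x$prompts[[1L]]),
      ", final training loss ",
      format(utils::tail(x$loss_trace, 1L), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Generate teacher soft labels for a task dataset
#'
#' Pure inference: runs the frozen teacher over every labeled site of its
#' task and records the predicted probability. These probabilities are the
#' distillation targets for student training.
#'
#' @param teacher A trained [train_teacher()] model.
#' @param records Record data.frame (normally the training split).
#' @param annotations Annotation data.frame.
#' @param task The teacher's [ptm_task()].
#' @param encoder Frozen encoder.
#' @return Data.frame with `task`, `protein_id`, `position`, `probability`.
#' @export
generate_soft_labels <- function(teacher, records, annotations, task,
                                 encoder) {
  dataset <- build_task_dataset(records, annotations, task)
  rows <- lapply(dataset, function(entry) {
    fwd <- model_forward_protein(teacher, encoder, entry, task$task_name)
    data.frame(task = task$task_name,
               protein_id = entry$protein_id,
               position = entry$positions,
               probability = fwd$p[entry$positions],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- student ---------------------------------------------------------------

#' Train the multi-task student by knowledge distillation
#'
#' Merges the labeled data of all tasks and trains one model — per-task
#' prompts, a shared decoder stack, and one head per task — on the weighted
#' distillation loss. Per-site targets blend ground truth with the teacher
#' soft labels according to the schedule's gamma; with `gamma0 = 1` fixed,
#' training reduces exactly to hard-label multi-task training (the
#' distillation-off ablation), and `soft_labels` may then be `NULL`.
#'
#' @param records Training record data.frame.
#' @param annotations Annotation data.frame.
#' @param tasks A `ptm_task_registry` (or list of [ptm_task()]) to train on.
#' @param encoder Frozen encoder.
#' @param soft_labels Soft-label data.frame from [generate_soft_labels()]
#'   covering every labeled training site of every task (may be `NULL` only
#'   for pure hard-label training).
#' @param K Prompt length per task.
#' @param seed Integer seed.
#' @param schedule A [blend_schedule()] (default fixed gamma = 0.5).
#' @param weight_rule Task-weight rule, see [compute_task_weights()].
#' @param hyper A [train_config()].
#' @param cfg A [decoder_config()].
#' @param prompts Optional named list of pre-built prompt matrices (e.g.
#'   inherited from teachers); re-initialized per task when `NULL`.
#' @return An object of class `ptm_student` (fields as `ptm_teacher` plus
#'   `weights`, `schedule`).
#' @export
train_student <- function(records, annotations, tasks, encoder,
                          soft_labels = NULL, K = 4L, seed = 1L,
                          schedule = blend_schedule("fixed", 0.5),
                          weight_rule = "inverse_size_normalized",
                          hyper = train_config(), cfg = decoder_config(),
                          prompts = NULL) {
  task_list <- if (inherits(tasks, "ptm_task_registry")) tasks else
    task_registry(tasks)
  task_names <- names(task_list)

  datasets <- lapply(task_list, function(task) {
    build_task_dataset(records, annotations, task)
  })
  for (tn in task_names) {
    if (!dataset_has_both_classes(datasets[[tn]])) {
      stop("task '", tn, "' lacks positive or negative training sites",
           call. = FALSE)
    }
  }
  sizes <- vapply(datasets, function(d) attr(d, "n_sites"), numeric(1))
  weights <- compute_task_weights(sizes, rule = weight_rule)

  hard_only <- schedule$mode == "fixed" && schedule$gamma0 == 1
  soft_lookup <- NULL
  if (!hard_only) {
    assert_that(!is.null(soft_labels),
                "soft_labels are required unless gamma is fixed at 1")
    soft_lookup <- new.env(parent = emptyenv())
    assign_keys <- paste(soft_labels$task, soft_labels$protein_id,
                         soft_labels$position, sep = "\r")
    for (i in seq_along(assign_keys)) {
      assign(assign_keys[i], soft_labels$probability[i], envir = soft_lookup)
    }
  }

  if (is.null(prompts)) {
    prompts <- stats::setNames(lapply(seq_along(task_list), function(i) {
      unclass_prompt(init_task_prompts(records, annotations,
                                       task_list[[i]], encoder,
                                       K = K, seed = seed + i))
    }), task_names)
  } else {
    prompts <- lapply(prompts, unclass_prompt)
    assert_that(all(task_names %in% names(prompts)),
                "supplied prompts must cover every task")
    prompts <- prompts[task_names]
  }

  n_batches <- sum(vapply(datasets, function(d) {
    ceiling(length(d) / hyper$batch_size)
  }, numeric(1)))
  if (is.null(schedule$total_steps)) {
    schedule$total_steps <- hyper$epochs * n_batches
  }

  model <- list(prompts = prompts,
                decoder = decoder_init(encoder$D, cfg, seed = seed),
                heads = stats::setNames(lapply(seq_along(task_list),
                                               function(i) {
                                                 head_init(cfg$hidden,
                                                           seed = seed + 100L + i)
                                               }), task_names),
                cfg = cfg)

  target_fn <- function(tn, entry, step) {
    gamma <- anneal_gamma(min(step, schedule$total_steps), schedule)
    if (gamma == 1) return(entry$y)
    keys <- paste(tn, entry$protein_id, entry$positions, sep = "\r")
    p <- vapply(keys, function(k) {
      if (!exists(k, envir = soft_lookup, inherits = FALSE)) {
        stop("missing soft label for ", gsub("\r", "/", k), call. = FALSE)
      }
      get(k, envir = soft_lookup)
    }, numeric(1), USE.NAMES = FALSE)
    blend_targets(entry$y, p, gamma)
  }

  model <- fit_model(model, encoder, datasets, target_fn, weights, hyper,
                     seed = seed)
  model$weights <- weights
  model$schedule <- schedule
  model$seed <- seed
  class(model) <- "ptm_student"
  model
}

#' @export
print.ptm_student <- function(x, ...) {
  cat("<ptm_student> ", length(x$heads), " task(s): ",
      paste(names(x$heads), collapse = ", "), "\n  final training loss ",
      format(utils::tail(x$loss_trace, 1L), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Score every labeled site of a task with a trained model
#'
#' Produces the site score table evaluation consumes: one row per labeled
#' candidate site with the model probability and the hard label.
#'
#' @param model A `ptm_teacher` or `ptm_student`.
#' @param records Record data.frame (e.g. the held-out test split).
#' @param annotations Annotation data.frame.
#' @param task A [ptm_task()].
#' @param encoder Frozen encoder.
#' @return Data.frame with `task`, `protein_id`, `position`, `probability`,
#'   `label`.
#' @export
score_sites <- function(model, records, annotations, task, encoder) {
  dataset <- build_task_dataset(records, annotations, task)
  rows <- lapply(dataset, function(entry) {
    fwd <- model_forward_protein(model, encoder, entry, task$task_name)
    data.frame(task = task$task_name,
               protein_id = entry$protein_id,
               position = entry$positions,
               probability = fwd$p[entry$positions],
               label = entry$y,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a soft-label table as TSV
#'
#' @param soft_labels Data.frame from [generate_soft_labels()].
#' @param path Output path.
#' @export
write_soft_labels <- function(soft_labels, path) {
  utils::write.table(soft_labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
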