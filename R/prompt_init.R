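# Prompt initialization: 21-residue windows around PTM sites, mean pooling,
# K-means clustering of the site means, and stacking of the K centroids into
# the initial K x D task prompt. Prompt tuning is highly sensitive to
# initialization; seeding the prompt with prototypical PTM-context vectors
# gives each prompt row a biologically meaningful starting point.

#' Extract context windows around positive PTM sites
#'
#' For each positive site at position `i`, extracts the rows of the residue
#' embedding matrix covering positions `max(1, i - half_width)` to
#' `min(L, i + half_width)` — a 21-row window for interior sites at the
#' default `half_width = 10`, clipped (never zero-padded) at sequence
#' boundaries.
#'
#' @param embeddings An `L x D` residue-embedding matrix (see
#'   [encode_sequence()]).
#' @param positives Integer vector of 1-based positive site positions.
#' @param half_width Window half-width (default 10, i.e. 21-residue windows).
#' @return A list of window objects, each with `site_id` (list of
#'   `protein_id`, `position`) and `rows` (`w x D` matrix, `w <= 2 *
#'   half_width + 1`).
#' @export
collect_site_windows <- function(embeddings, positives, half_width = 10L) {
  L <- nrow(embeddings)
  assert_that(all(positives >= 1L & positives <= L),
              "positive site position outside the sequence")
  pid <- attr(embeddings, "protein_id")
  lapply(positives, function(i) {
    lo <- max(1L, i - half_width)
    hi <- min(L, i + half_width)
    list(site_id = list(protein_id = pid, position = i),
         rows = embeddings[lo:hi, , drop = FALSE])
  })
}

#' Mean-pool one site window into a single context vector
#'
#' Column-wise arithmetic mean over the window's `w` rows (1/21 per row for
#' interior windows; 1/w for clipped boundary windows, so boundary sites are
#' not biased toward zero).
#'
#' @param window A window object from [collect_site_windows()].
#' @return A numeric vector of length `D`.
#' @export
mean_pool_window <- function(window) {
  assert_that(is.matrix(window$rows) && nrow(window$rows) >= 1L,
              "cannot mean-pool an empty window")
  colMeans(window$rows)
}

#' Cluster site mean vectors by seeded K-means
#'
#' Groups the mean-pooled PTM-context vectors into `K` clusters with
#' k-means++ seeding followed by Lloyd iterations (at most `max_iter`
#' sweeps; convergence when the assignments stop changing or the relative
#' inertia change drops below `tol`). An emptied cluster is re-seeded at the
#' point farthest from its nearest centroid. On exit, centroids are
#' recomputed as the exact means of their final member sets.
#'
#' @param means Numeric matrix (sites x D) or list of site mean vectors.
#' @param K Number of clusters (default 500, the full-scale prompt length;
#'   use small K at desk scale).
#' @param seed Integer seed; clustering is deterministic given it.
#' @param max_iter,tol Lloyd iteration controls.
#' @return An object of class `ptm_cluster_model`: `K`, `assignments`
#'   (integer vector), `centroids` (`K x D`), `inertia`, `iterations`,
#'   `seed`.
#' @export
cluster_windows <- function(means, K = 500L, seed, max_iter = 300L,
                            tol = 1e-4) {
  X <- if (is.list(means) && !is.matrix(means)) do.call(rbind, means) else
    as.matrix(means)
  n <- nrow(X)
  assert_that(all(is.finite(X)), "non-finite site mean vectors")
  if (n < K) {
    stop("only ", n, " site vectors for K = ", K,
         " clusters; reduce K to at most the number of positive sites",
         call. = FALSE)
  }
  with_seed(seed, {
    C <- kmeanspp_init(X, K)
    assign_old <- rep(0L, n)
    inertia_old <- Inf
    iter <- 0L
    repeat {
      iter <- iter + 1L
      d2 <- pairwise_sqdist(X, C)
      assign_new <- max.col(-d2, ties.method = "first")
      # re-seed emptied clusters at the point farthest from its centroid
      for (k in which(tabulate(assign_new, K) == 0L)) {
        far <- which.max(d2[cbind(seq_len(n), assign_new)])
        C[k, ] <- X[far, ]
        assign_new[far] <- k
      }
      for (k in seq_len(K)) {
        C[k, ] <- colMeans(X[assign_new == k, , drop = FALSE])
      }
      inertia <- sum((X - C[assign_new, , drop = FALSE])^2)
      converged <- all(assign_new == assign_old) ||
        (is.finite(inertia_old) &&
           abs(inertia_old - inertia) <= tol * max(inertia_old, .Machine$double.eps))
      assign_old <- assign_new
      inertia_old <- inertia
      if (converged || iter >= max_iter) break
    }
    structure(list(K = as.integer(K), assignments = assign_old,
                   centroids = C, inertia = inertia_old,
                   iterations = iter, seed = as.integer(seed)),
              class = "ptm_cluster_model")
  })
}

# k-means++ seeding: first center uniform, then sample proportional to the
# squared distance to the nearest chosen center.
kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (K == 1L) return(centers)
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  for (k in 2L:K) {
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[k, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[k, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers
}

pairwise_sqdist <- function(X, C) {
  # ||x||^2 + ||c||^2 - 2 x.c, clamped at 0 against rounding
  d2 <- outer(rowSums(X^2), rowSums(C^2), `+`) - 2 * X %*% t(C)
  pmax(d2, 0)
}

#' @export
print.ptm_cluster_model <- function(x, ...) {
  cat("<ptm_cluster_model> K = ", x$K, ", ", length(x$assignments),
      " site(s), inertia ", format(x$inertia, digits = 6), ", ",
      x$iterations, " iteration(s)\n", sep = "")
  invisible(x)
}

#' Stack cluster centroids into a task prompt matrix
#'
#' Row `k` of the prompt is centroid `k`; the result is the `K x D`
#' trainable prompt for the task.
#'
#' @param model A `ptm_cluster_model` from [cluster_windows()].
#' @param task_name Task the prompt belongs to.
#' @return A `K x D` matrix with attributes `task_name` and
#'   `trainable = TRUE`.
#' @export
assemble_prompt_matrix <- function(model, task_name) {
  M <- model$centroids
  attr(M, "task_name") <- task_name
  attr(M, "trainable") <- TRUE
  M
}

#' Initialize a task prompt from training data
#'
#' End-to-end prompt initialization for one task: encode every training
#' protein *without* a prompt (the prompt does not exist yet), extract
#' 21-residue windows around that task's positive training sites, mean-pool
#' each window, cluster the site means into `K` groups, and stack the
#' centroids into the initial prompt.
#'
#' Only positive sites feed initialization; negatives carry no PTM context.
#' The pipeline runs per task; to build a single shared prompt from several
#' tasks' positive sites, pass merged annotations under one pooled task.
#'
#' @param records Training-side record data.frame.
#' @param annotations Annotation data.frame.
#' @param task A [ptm_task()].
#' @param encoder Frozen encoder (see [toy_encoder()]).
#' @param K Prompt length / cluster count.
#' @param seed Integer seed for clustering.
#' @param half_width Window half-width (default 10).
#' @return A `K x D` prompt matrix (see [assemble_prompt_matrix()]).
#' @export
init_task_prompts <- function(records, annotations, task, encoder, K, seed,
                              half_width = 10L) {
  means <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    ls <- label_sites(rec, annotations, task)
    if (!length(ls$positives)) next
    emb <- encode_sequence(rec, encoder)
    wins <- collect_site_windows(emb, ls$positives, half_width)
    means <- c(means, lapply(wins, mean_pool_window))
  }
  if (length(means) < K) {
    stop("task '", task$task_name, "' has ", length(means),
         " positive training site(s), fewer than K = ", K,
         "; reduce K", call. = FALSE)
  }
  model <- cluster_windows(means, K = K, seed = seed)
  assemble_prompt_matrix(model, task$task_name)
}
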