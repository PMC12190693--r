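# Hybrid decoder: two 1D-convolution inception modules and a shared fully
# connected layer produce a length-preserving shared representation; one
# independent logistic head per PTM task turns it into per-residue
# probabilities. The decoder scores every position; restriction to labeled
# or candidate-residue positions happens at loss/prediction time, keeping
# the decoder task-agnostic in shape.

#' Decoder configuration
#'
#' @param kernel_sizes Three odd kernel widths for the inception branches
#'   (default 3, 7, 11); odd widths with same-length zero padding preserve
#'   sequence length and residue alignment.
#' @param channels_per_branch Output channels of each branch (default 8).
#' @param hidden Width of the shared fully connected layer (default 32).
#' @param concat_modules If `TRUE` (default) the outputs of both inception
#'   modules are concatenated before the fully connected layer; if `FALSE`
#'   only the second (serial) module output feeds it.
#' @return A list of class `decoder_config`.
#' @export
decoder_config <- function(kernel_sizes = c(3L, 7L, 11L),
                           channels_per_branch = 8L,
                           hidden = 32L,
                           concat_modules = TRUE) {
  assert_that(length(kernel_sizes) == 3L && all(kernel_sizes %% 2L == 1L),
              "exactly three odd kernel sizes are required")
  assert_that(channels_per_branch >= 1L && hidden >= 1L,
              "channels_per_branch and hidden must be positive")
  structure(list(kernel_sizes = as.integer(kernel_sizes),
                 channels_per_branch = as.integer(channels_per_branch),
                 hidden = as.integer(hidden),
                 concat_modules = isTRUE(concat_modules)),
            class = "decoder_config")
}

# ---- 1D convolution with same-length zero padding --------------------------

conv1d_forward <- function(X, W, b) {
  L <- nrow(X)
  ks <- dim(W)[1L]
  h <- (ks - 1L) %/% 2L
  Cout <- dim(W)[3L]
  Y <- matrix(b, L, Cout, byrow = TRUE)
  for (j in seq_len(ks)) {
    off <- j - h - 1L
    rows <- max(1L, 1L - off):min(L, L - off)
    if (length(rows) < 1L || rows[1L] > rows[length(rows)]) next
    Y[rows, ] <- Y[rows, ] + X[rows + off, , drop = FALSE] %*% W[j, , ]
  }
  Y
}

conv1d_backward <- function(X, W, dY) {
  L <- nrow(X)
  ks <- dim(W)[1L]
  h <- (ks - 1L) %/% 2L
  dX <- X * 0
  dW <- W * 0
  for (j in seq_len(ks)) {
    off <- j - h - 1L
    rows <- max(1L, 1L - off):min(L, L - off)
    if (length(rows) < 1L || rows[1L] > rows[length(rows)]) next
    dX[rows + off, ] <- dX[rows + off, ] +
      dY[rows, , drop = FALSE] %*% t(W[j, , ])
    dW[j, , ] <- t(X[rows + off, , drop = FALSE]) %*% dY[rows, , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

# ---- weight initialization -------------------------------------------------

init_conv_module <- function(C_in, cfg) {
  lapply(cfg$kernel_sizes, function(ks) {
    sd <- sqrt(2 / (ks * C_in))
    list(W = array(stats::rnorm(ks * C_in * cfg$channels_per_branch, sd = sd),
                   dim = c(ks, C_in, cfg$channels_per_branch)),
         b = numeric(cfg$channels_per_branch))
  })
}

#' Initialize decoder (shared-stack) weights
#'
#' Seeded He-style Gaussian initialization of the two inception modules and
#' the fully connected layer for an encoder of embedding width `D`.
#'
#' @param D Input embedding width.
#' @param cfg A [decoder_config()].
#' @param seed Integer seed.
#' @return A parameter list (`inc1`, `inc2`, `fc`).
#' @export
decoder_init <- function(D, cfg = decoder_config(), seed = 1L) {
  with_seed(seed, {
    C1 <- 3L * cfg$channels_per_branch
    fc_in <- if (cfg$concat_modules) 2L * C1 else C1
    list(inc1 = init_conv_module(D, cfg),
         inc2 = init_conv_module(C1, cfg),
         fc = list(W = matrix(stats::rnorm(fc_in * cfg$hidden,
                                           sd = sqrt(2 / fc_in)),
                              fc_in, cfg$hidden),
                   b = numeric(cfg$hidden)))
  })
}

#' Initialize one task head
#'
#' A single affine map from the shared hidden width to one logit plus a
#' logistic output.
#'
#' @param hidden Shared hidden width.
#' @param seed Integer seed.
#' @return List with weight vector `w` and scalar bias `b`.
#' @export
head_init <- function(hidden, seed = 1L) {
  with_seed(seed, list(w = stats::rnorm(hidden, sd = sqrt(1 / hidden)),
                       b = 0))
}

#' Forward pass of one inception module
#'
#' Three 1D convolutions with different kernel widths run in parallel along
#' the sequence axis; their outputs are concatenated on the channel axis.
#' Returned values are pre-activation; the shared stack applies ReLU.
#'
#' @param x `L x C_in` input matrix.
#' @param module Branch weights as built by [decoder_init()] (fields
#'   `inc1`/`inc2`).
#' @return `L x (3 * channels_per_branch)` matrix.
#' @export
inception_forward <- function(x, module) {
  do.call(cbind, lapply(module, function(br) conv1d_forward(x, br$W, br$b)))
}

# Shared-stack forward with cache (used by training); see shared_forward()
# for the user-facing wrapper.
shared_forward_cached <- function(H0, decoder, cfg) {
  pre1 <- inception_forward(H0, decoder$inc1)
  out1 <- relu(pre1)
  pre2 <- inception_forward(out1, decoder$inc2)
  out2 <- relu(pre2)
  cat_ <- if (cfg$concat_modules) cbind(out1, out2) else out2
  fcpre <- cat_ %*% decoder$fc$W +
    matrix(decoder$fc$b, nrow(cat_), cfg$hidden, byrow = TRUE)
  S <- relu(fcpre)
  list(S = S,
       cache = list(H0 = H0, pre1 = pre1, out1 = out1, pre2 = pre2,
                    out2 = out2, cat = cat_, fcpre = fcpre))
}

#' Shared representation of a protein's residue embeddings
#'
#' Runs residue embeddings through the shared decoder stack (two inception
#' modules, concatenation, fully connected layer, ReLU). Length-preserving:
#' the output has one row per residue.
#'
#' @param residues `L x D` residue-embedding matrix.
#' @param decoder Decoder weights from [decoder_init()].
#' @param cfg The matching [decoder_config()].
#' @return `L x hidden` shared representation.
#' @export
shared_forward <- function(residues, decoder, cfg = decoder_config()) {
  assert_that(all(is.finite(residues)), "non-finite residue embeddings")
  shared_forward_cached(residues, decoder, cfg)$S
}

#' Per-residue probabilities from one task head
#'
#' @param shared `L x hidden` shared representation.
#' @param head Head weights from [head_init()].
#' @return Numeric vector of length `L` with values strictly in (0, 1).
#' @export
head_forward <- function(shared, head) {
  sigmoid(drop(shared %*% head$w) + head$b)
}

# Backward through head + shared stack. dz is dLoss/dlogit (length L).
# Returns gradients for the head, the decoder, and the input embeddings.
shared_backward <- function(cache, decoder, head, cfg, dz, S) {
  dw <- drop(t(S) %*% dz)
  db <- sum(dz)
  dS <- outer(dz, head$w)
  dfcpre <- dS * (cache$fcpre > 0)
  dWfc <- t(cache$cat) %*% dfcpre
  dbfc <- colSums(dfcpre)
  dcat <- dfcpre %*% t(decoder$fc$W)
  C1 <- ncol(cache$out1)
  if (cfg$concat_modules) {
    dout1 <- dcat[, seq_len(C1), drop = FALSE]
    dout2 <- dcat[, C1 + seq_len(C1), drop = FALSE]
  } else {
    dout1 <- cache$out1 * 0
    dout2 <- dcat
  }
  dpre2 <- dout2 * (cache$pre2 > 0)
  bw2 <- inception_backward(cache$out1, decoder$inc2, dpre2)
  dout1 <- dout1 + bw2$dX
  dpre1 <- dout1 * (cache$pre1 > 0)
  bw1 <- inception_backward(cache$H0, decoder$inc1, dpre1)
  list(decoder = list(inc1 = bw1$dmodule, inc2 = bw2$dmodule,
                      fc = list(W = dWfc, b = dbfc)),
       head = list(w = dw, b = db),
       dH0 = bw1$dX)
}

inception_backward <- function(X, module, dY) {
  Cb <- dim(module[[1L]]$W)[3L]
  dX <- X * 0
  dmodule <- vector("list", length(module))
  for (i in seq_along(module)) {
    cols <- (i - 1L) * Cb + seq_len(Cb)
    bw <- conv1d_backward(X, module[[i]]$W, dY[, cols, drop = FALSE])
    dX <- dX + bw$dX
    dmodule[[i]] <- list(W = bw$dW, b = bw$db)
  }
  list(dX = dX, dmodule = dmodule)
}

# ---- full model forward/backward for one protein ---------------------------
# A "model" bundles prompts (per task), shared decoder weights, heads (per
# task), a decoder_config, and the training seed. Teachers carry exactly one
# head; students carry one per task.

model_forward_protein <- function(model, encoder, record, task_name,
                                  keep_cache = FALSE) {
  if (is.null(model$heads[[task_name]]) ||
      is.null(model$prompts[[task_name]])) {
    stop("unknown task '", task_name, "'; registered heads: ",
         paste(names(model$heads), collapse = ", "), call. = FALSE)
  }
  prompt <- model$prompts[[task_name]]
  L <- nchar(record$sequence)
  if (L > encoder$max_sequence_len) {
    stop("sequence of length ", L, " exceeds the encoder limit of ",
         encoder$max_sequence_len, call. = FALSE)
  }
  X0 <- build_input_stream(encoder, record$sequence, prompt)
  enc <- toy_encoder_forward(encoder, X0)
  K <- nrow(prompt)
  H0 <- strip_specials(enc$out, K = K, L = L,
                       adds_cls_eos = encoder$adds_cls_eos)
  sf <- shared_forward_cached(H0, model$decoder, model$cfg)
  head <- model$heads[[task_name]]
  z <- drop(sf$S %*% head$w) + head$b
  p <- sigmoid(z)
  out <- list(p = p, z = z)
  if (keep_cache) {
    out$cache <- list(enc = enc$caches, shared = sf$cache, S = sf$S,
                      K = K, L = L)
  }
  out
}

# dz: gradient of the loss with respect to the logit vector (length L).
# Returns the gradient with respect to this task's prompt, the shared
# decoder, and this task's head. Encoder parameters receive no gradient.
model_backward_protein <- function(model, encoder, record, task_name,
                                   fwd, dz) {
  cache <- fwd$cache
  bw <- shared_backward(cache$shared, model$decoder,
                        model$heads[[task_name]], model$cfg, dz, cache$S)
  # scatter residue-embedding gradients back into the encoder stream
  n_special <- if (encoder$adds_cls_eos) 2L else 0L
  dStream <- matrix(0, cache$K + cache$L + n_special, encoder$D)
  offset <- if (encoder$adds_cls_eos) 1L else 0L
  dStream[(offset + cache$K + 1L):(offset + cache$K + cache$L), ] <- bw$dH0
  dX0 <- toy_encoder_backward(encoder, cache$enc, dStream)
  dPrompt <- if (cache$K > 0L)
    dX0[(offset + 1L):(offset + cache$K), , drop = FALSE]
  else matrix(0, 0L, encoder$D)
  list(prompt = dPrompt, decoder = bw$decoder, head = bw$head)
}

#' Predict PTM site probabilities for one protein
#'
#' Runs the full pipeline (prompt + frozen encoder + shared decoder + task
#' head) and reports probabilities at the task's candidate-residue positions
#' only, in 1-based coordinates.
#'
#' @param model A trained model ([train_teacher()] or [train_student()]).
#' @param record List or one-row data.frame with `protein_id`, `sequence`.
#' @param encoder The frozen encoder the model was trained with.
#' @param task A [ptm_task()]; must be registered in the model.
#' @return Data.frame with `protein_id`, `position`, `residue`,
#'   `probability` — one row per candidate residue (possibly zero rows).
#' @export
predict_sites <- function(model, record, encoder, task) {
  cand <- candidate_positions(record$sequence, task$candidate_residue)
  if (!length(cand)) {
    return(data.frame(protein_id = character(), position = integer(),
                      residue = character(), probability = numeric()))
  }
  fwd <- model_forward_protein(model, encoder, record, task$task_name)
  data.frame(protein_id = record$protein_id,
             position = cand,
             residue = task$candidate_residue,
             probability = fwd$p[cand],
             stringsAsFactors = FALSE)
}

#' Write a prediction table as TSV
#'
#' Columns `protein_id`, `position`, `residue`, `task`, `probability`
#' (6 decimal places).
#'
#' @param predictions Data.frame of predictions (with a `task` column, as
#'   assembled by the caller).
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  predictions$probability <- sprintf("%.6f", predictions$probability)
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
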