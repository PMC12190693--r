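# Frozen encoder contract and a deterministic toy self-attention encoder.
#
# The framework treats the residue-embedding encoder as a frozen black box
# satisfying a small contract: it maps a token stream
# [CLS], prompt rows, residue rows, [EOS] of width K + L + 2 to an equally
# wide stream of D-dimensional embeddings, processing prompts and residues
# jointly so that prompts influence the residue outputs. Gradients may flow
# *through* the encoder into the prompt rows, but its own parameters are
# never updated. The toy encoder below implements this contract in a few
# thousand parameters so the full pipeline runs at desk scale; an adapter
# for a real protein language model can satisfy the same contract.

#' Construct a deterministic toy residue encoder
#'
#' A small multi-layer self-attention encoder with fixed, seed-generated
#' weights: token embeddings for the 20 amino acids plus X, sinusoidal
#' positional encodings, and per layer a single-head softmax attention block
#' and a tanh feed-forward block, both with residual connections. The
#' encoder is frozen by construction — no training routine in this package
#' touches its weights — yet it is differentiable with respect to its
#' inputs, so prompt rows receive gradients.
#'
#' @param seed Integer seed generating the weights; identical seeds give
#'   bit-identical encoders.
#' @param D Embedding width (>= 4; default 16).
#' @param n_layers Number of attention+feed-forward layers (default 2).
#' @param max_sequence_len Longest accepted residue sequence (default 1022).
#' @return An object of class `toy_encoder` implementing the encoder
#'   contract (`D`, `adds_cls_eos = TRUE`, `max_sequence_len`,
#'   `frozen = TRUE`).
#' @export
toy_encoder <- function(seed, D = 16L, n_layers = 2L,
                        max_sequence_len = 1022L) {
  assert_that(D >= 4L, "toy encoder needs D >= 4")
  assert_that(n_layers >= 1L, "toy encoder needs at least one layer")
  Dh <- 2L * D
  params <- with_seed(seed, {
    embed <- matrix(stats::rnorm(length(AA_ALLOWED) * D, sd = 1), ncol = D,
                    dimnames = list(AA_ALLOWED, NULL))
    cls <- stats::rnorm(D)
    eos <- stats::rnorm(D)
    layers <- lapply(seq_len(n_layers), function(l) {
      list(Wq = matrix(stats::rnorm(D * D, sd = 1 / sqrt(D)), D, D),
           Wk = matrix(stats::rnorm(D * D, sd = 1 / sqrt(D)), D, D),
           Wv = matrix(stats::rnorm(D * D, sd = 0.5 / sqrt(D)), D, D),
           W1 = matrix(stats::rnorm(D * Dh, sd = 1 / sqrt(D)), D, Dh),
           W2 = matrix(stats::rnorm(Dh * D, sd = 0.5 / sqrt(Dh)), Dh, D))
    })
    list(embed = embed, cls = cls, eos = eos, layers = layers)
  })
  structure(list(D = as.integer(D), n_layers = as.integer(n_layers),
                 adds_cls_eos = TRUE,
                 max_sequence_len = as.integer(max_sequence_len),
                 frozen = TRUE, seed = as.integer(seed), params = params),
            class = "toy_encoder")
}

#' @export
print.toy_encoder <- function(x, ...) {
  cat("<toy_encoder> D = ", x$D, ", ", x$n_layers,
      " layer(s), frozen, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Sinusoidal positional encodings for positions 1..n (rows) in width D.
positional_encoding <- function(n, D) {
  pos <- seq_len(n)
  i <- seq_len(D)
  freq <- 1 / 10000^((2 * floor((i - 1) / 2)) / D)
  ang <- outer(pos, freq)
  pe <- ang
  odd <- seq(1, D, by = 2)       # sine components
  even <- seq(2, D, by = 2)      # cosine components
  pe[, odd] <- sin(ang[, odd])
  pe[, even] <- cos(ang[, even])
  pe
}

# Assemble the input stream [CLS], prompt rows, residue rows, [EOS] with
# positional encodings added at every (ordinary) position, prompts included.
build_input_stream <- function(encoder, sequence, prompt) {
  letters_vec <- split_sequence(sequence)
  E <- encoder$params$embed[letters_vec, , drop = FALSE]
  K <- nrow(prompt)
  L <- length(letters_vec)
  X0 <- rbind(matrix(encoder$params$cls, nrow = 1L),
              prompt,
              E,
              matrix(encoder$params$eos, nrow = 1L))
  X0 + positional_encoding(nrow(X0), encoder$D)
}

# Forward pass caching what the backward pass needs. Each layer:
#   attention:   A = softmax(Q K' / sqrt(D)),  X1 = X + A V
#   feedforward: X2 = X1 + tanh(X1 W1) W2
toy_encoder_forward <- function(encoder, X0) {
  D <- encoder$D
  X <- X0
  caches <- vector("list", encoder$n_layers)
  for (l in seq_len(encoder$n_layers)) {
    p <- encoder$params$layers[[l]]
    Q <- X %*% p$Wq
    Km <- X %*% p$Wk
    V <- X %*% p$Wv
    A <- softmax_rows(Q %*% t(Km) / sqrt(D))
    X1 <- X + A %*% V
    Z <- tanh(X1 %*% p$W1)
    X2 <- X1 + Z %*% p$W2
    caches[[l]] <- list(X = X, Q = Q, Km = Km, V = V, A = A, Z = Z)
    X <- X2
  }
  list(out = X, caches = caches)
}

# Backward pass: gradient of a downstream loss with respect to the input
# stream X0, given its gradient with respect to the output stream. Encoder
# weights receive no gradient by construction (frozen contract).
toy_encoder_backward <- function(encoder, caches, dOut) {
  D <- encoder$D
  dX <- dOut
  for (l in rev(seq_len(encoder$n_layers))) {
    p <- encoder$params$layers[[l]]
    cc <- caches[[l]]
    # feed-forward block
    dZ <- dX %*% t(p$W2)
    dZpre <- dZ * (1 - cc$Z^2)
    dX1 <- dX + dZpre %*% t(p$W1)
    # attention block
    dV <- t(cc$A) %*% dX1
    dA <- dX1 %*% t(cc$V)
    dS <- cc$A * (dA - rowSums(dA * cc$A))   # row-wise softmax Jacobian
    dQ <- dS %*% cc$Km / sqrt(D)
    dKm <- t(dS) %*% cc$Q / sqrt(D)
    dX <- dX1 + dQ %*% t(p$Wq) + dKm %*% t(p$Wk) + dV %*% t(p$Wv)
  }
  dX
}

#' Encode a protein with a task prompt attached
#'
#' Builds the token stream `[CLS]`, prompt rows, residue rows, `[EOS]`,
#' runs it through the frozen encoder, and strips the prompt and special
#' rows so that exactly the L residue embeddings remain. Prompts occupy
#' ordinary positions in the positional-encoding scheme and attend jointly
#' with the residues, so the returned residue embeddings depend on the
#' prompt — the mechanism prompt tuning exploits.
#'
#' @param record List or one-row data.frame with `protein_id` and `sequence`.
#' @param prompt A `K x D` prompt matrix (`K = 0` rows encode without any
#'   prompt, as during prompt initialization).
#' @param encoder A [toy_encoder()] (or any object with the same contract
#'   fields and a `toy_encoder_forward`-compatible method).
#' @return An `L x D` matrix of residue embeddings with attribute
#'   `protein_id`.
#' @export
encode_with_prompts <- function(record, prompt, encoder) {
  L <- nchar(record$sequence)
  if (L > encoder$max_sequence_len) {
    stop("sequence of length ", L, " exceeds the encoder limit of ",
         encoder$max_sequence_len,
         " residues; over-length sequences are excluded, never truncated",
         call. = FALSE)
  }
  assert_that(is.matrix(prompt) && ncol(prompt) == encoder$D,
              "prompt width must equal the encoder embedding dimension")
  X0 <- build_input_stream(encoder, record$sequence, prompt)
  stream <- toy_encoder_forward(encoder, X0)$out
  out <- strip_specials(stream, K = nrow(prompt), L = L,
                        adds_cls_eos = encoder$adds_cls_eos)
  attr(out, "protein_id") <- record$protein_id
  out
}

#' Encode a protein without any prompt
#'
#' Convenience wrapper around [encode_with_prompts()] with an empty prompt;
#' used to produce the embeddings that feed prompt initialization (the
#' prompt does not exist yet at that stage).
#'
#' @inheritParams encode_with_prompts
#' @return An `L x D` residue-embedding matrix.
#' @export
encode_sequence <- function(record, encoder) {
  encode_with_prompts(record, matrix(0, 0L, encoder$D), encoder)
}

#' Strip prompt and special-token rows from an encoder output stream
#'
#' The encoder's internal stream has width `K + L + 2` (`[CLS]` first, then
#' the `K` prompt rows, the `L` residue rows, `[EOS]` last). Downstream
#' modules consume residue rows only; row `i` of the result is row
#' `1 + K + i` of the stream.
#'
#' @param stream Matrix of encoder outputs.
#' @param K Number of prompt rows.
#' @param L Number of residue rows.
#' @param adds_cls_eos Whether the stream carries `[CLS]`/`[EOS]` rows.
#' @return The `L x D` residue block, order preserved.
#' @export
strip_specials <- function(stream, K, L, adds_cls_eos = TRUE) {
  n_special <- if (adds_cls_eos) 2L else 0L
  if (nrow(stream) != K + L + n_special) {
    stop("stream width ", nrow(stream), " inconsistent with K = ", K,
         ", L = ", L, ", specials = ", n_special, call. = FALSE)
  }
  offset <- if (adds_cls_eos) 1L else 0L
  stream[(offset + K + 1L):(offset + K + L), , drop = FALSE]
}

# Snapshot of all encoder parameters; training code uses this to assert the
# frozen contract (bit-identical before/after).
encoder_param_snapshot <- function(encoder) encoder$params
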