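# Internal numerical and bookkeeping helpers shared across modules.

# The 20 standard amino acids; X is tolerated in sequences but can never be
# a candidate residue.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALLOWED <- c(AA_STANDARD, "X")

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# log with clamping so cross-entropy never returns -Inf for a saturated
# probability; 1e-12 is far below any probability the logistic heads emit.
safe_log <- function(p) log(pmax(p, 1e-12))

binary_cross_entropy <- function(target, p) {
  -(target * safe_log(p) + (1 - target) * safe_log(1 - p))
}

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# ---- parameter-tree helpers ------------------------------------------------
# Trainable parameters are nested named lists with numeric arrays at the
# leaves; these map over one or two trees of identical shape.

tree_map <- function(f, tree) {
  if (is.list(tree)) return(lapply(tree, function(x) tree_map(f, x)))
  f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    return(out)
  }
  f(a, b)
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_max_abs_diff <- function(a, b) {
  if (is.list(a)) {
    return(max(vapply(seq_along(a),
                      function(i) tree_max_abs_diff(a[[i]], b[[i]]),
                      numeric(1))))
  }
  if (length(a) == 0L) return(0)
  max(abs(a - b))
}

tree_n_changed <- function(a, b) {
  if (is.list(a)) {
    return(sum(vapply(seq_along(a),
                      function(i) tree_n_changed(a[[i]], b[[i]]),
                      numeric(1))))
  }
  sum(a != b)
}

# ---- Adam optimizer --------------------------------------------------------

adam_state_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step_tree <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                         state$m, state$v)
  params <- tree_map2(`-`, params, step_tree)
  list(params = params, state = state)
}

split_sequence <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

candidate_positions <- function(sequence, residue) {
  which(split_sequence(sequence) == residue)
}
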