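# Small dense-layer toolkit used by the encoder and heads. All gradients in
# this package are hand-derived; see the methods vignette for the loss and
# the stop-gradient treatment of the correlation matrix.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

sigmoid <- function(x) stats::plogis(x)

glorot <- function(n_in, n_out, rng) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(rng(n_in * n_out, -lim, lim), nrow = n_in, ncol = n_out)
}

# Initialize an Adam state for a named list of parameter arrays.
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
}

# One Adam update. `grads` must carry the same names as `params`; entries
# missing from `grads` are left untouched (used to freeze weight groups).
adam_step <- function(params, grads, state, clip = 10) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (!is.finite(gn)) stop("non-finite gradient norm", call. = FALSE)
  scale <- if (gn > clip) clip / gn else 1
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]] * scale
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      state$lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + state$eps)
  }
  list(params = params, state = state)
}

# Sum rows of `mat` (one row per directed edge) into their destination atoms.
atom_sum <- function(mat, dst, n_atoms) {
  d <- ncol(mat)
  out <- matrix(0, nrow = n_atoms, ncol = d)
  if (nrow(mat) == 0) return(out)
  rs <- rowsum(mat, group = dst)
  out[as.integer(rownames(rs)), ] <- rs
  out
}
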