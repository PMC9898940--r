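#' Create readout head parameters
#'
#' The readout has a shared fully connected trunk followed by two parallel
#' output layers: the mean layer and the variance layer. In atom mode the
#' heads act on each atomic fingerprint and the variance layer outputs the
#' atomic standard deviation (through softplus); in molecule mode the
#' fingerprints are sum-pooled first and the variance layer outputs the
#' molecular variance (through softplus). A scalar `log_scale`, part of the
#' variance-layer parameter group, multiplies the standard deviation by
#' `exp(log_scale)` (initialized at 0, i.e. no scaling).
#'
#' @param hidden_dim Fingerprint width coming out of the encoder.
#' @param trunk_dim Width of the shared trunk layer (default `hidden_dim`).
#' @param mode `"atom"` for per-atom readout, `"molecule"` for pooled readout.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `head_params`.
#' @export
head_params <- function(hidden_dim, trunk_dim = hidden_dim,
                        mode = c("atom", "molecule"), seed = 1) {
  mode <- match.arg(mode)
  withr::with_seed(as.integer(seed), {
    p <- list(
      W_t = glorot(hidden_dim, trunk_dim, stats::runif),
      b_t = numeric(trunk_dim),
      w_mu = glorot(trunk_dim, 1, stats::runif),
      b_mu = 0,
      w_vl = glorot(trunk_dim, 1, stats::runif),
      b_vl = 0,
      log_scale = 0
    )
    structure(
      c(p, list(hidden_dim = hidden_dim, trunk_dim = trunk_dim, mode = mode)),
      class = "head_params"
    )
  })
}

# names of the parameter arrays that belong to the variance layer; post-hoc
# calibration may touch these and nothing else
vl_param_names <- function() c("w_vl", "b_vl", "log_scale")

.sigma_floor <- 1e-6   # floor added to softplus output (standard deviation)
.var_floor <- 1e-8     # floor applied to molecular variance before the NLL

# Shared trunk + parallel heads on a fingerprint matrix; returns mean and
# raw (pre-positivity) variance-layer outputs plus cache.
heads_forward <- function(Fp, hp, keep_cache = TRUE) {
  Upre <- sweep(Fp %*% hp$W_t, 2, hp$b_t, "+")
  U <- relu(Upre)
  mu <- drop(U %*% hp$w_mu) + hp$b_mu
  raw <- drop(U %*% hp$w_vl) + hp$b_vl
  out <- list(mu = mu, raw = raw)
  if (keep_cache) out$cache <- list(Fp = Fp, Upre = Upre, U = U)
  out
}

# Backprop through trunk + heads. g_mu, g_raw are per-row gradients.
heads_backward <- function(g_mu, g_raw, hp, cache) {
  gU <- outer(g_mu, drop(hp$w_mu)) + outer(g_raw, drop(hp$w_vl))
  gUpre <- gU * (cache$Upre > 0)
  list(
    grads = list(
      W_t = crossprod(cache$Fp, gUpre),
      b_t = colSums(gUpre),
      w_mu = crossprod(cache$U, g_mu),
      b_mu = sum(g_mu),
      w_vl = crossprod(cache$U, g_raw),
      b_vl = sum(g_raw)
    ),
    gF = gUpre %*% t(hp$W_t)
  )
}

#' Per-atom readout of means and standard deviations
#'
#' Passes each fingerprint row through the shared trunk, then the mean layer
#' (atomic mean) and the variance layer (atomic standard deviation via
#' softplus, scaled by `exp(log_scale)` and floored at 1e-6).
#'
#' @param fp Fingerprint matrix from [encode_atoms()].
#' @param params A [head_params()] object with `mode = "atom"`.
#' @return An object of class `atomic_prediction`: list with `mu_atoms`,
#'   `sigma_atoms` (both length `n_atoms`) and `fingerprints`.
#' @export
atom_readout <- function(fp, params) {
  if (!identical(params$mode, "atom")) {
    rlang::abort("atom_readout() requires head parameters with mode = 'atom'")
  }
  hf <- heads_forward(fp, params, keep_cache = FALSE)
  sigma <- exp(params$log_scale) * (softplus(hf$raw) + .sigma_floor)
  structure(
    list(mu_atoms = hf$mu, sigma_atoms = sigma, fingerprints = fp),
    class = "atomic_prediction"
  )
}

#' Pearson correlation of atomic fingerprints
#'
#' Computes the pairwise Pearson correlation coefficient across the `d`
#' fingerprint coordinates of every pair of atoms. If either row is constant
#' across its coordinates the correlation is undefined (0/0) and is set to 0
#' by convention; the diagonal is always 1.
#'
#' @param fp An `n_atoms x d` fingerprint matrix with `d >= 2`.
#' @return A symmetric `n_atoms x n_atoms` correlation matrix with unit
#'   diagonal.
#' @export
pairwise_correlation <- function(fp) {
  if (ncol(fp) < 2) {
    rlang::abort("fingerprint width must be >= 2 to define a correlation")
  }
  R <- suppressWarnings(stats::cor(t(fp)))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  R
}

#' Aggregate atomic Gaussians into a molecular Gaussian
#'
#' The molecular mean is the sum of the atomic means. The molecular variance
#' is the full quadratic form over the atomic covariance matrix whose
#' diagonal holds the atomic variances and whose off-diagonal entries are
#' `rho_ij * sigma_i * sigma_j`, with `rho_ij` the Pearson correlation of
#' the learned atomic fingerprints. The result is floored at 1e-8.
#'
#' @param ap An [atom_readout()] result.
#' @return An object of class `molecular_distribution`: list with `mu`,
#'   `sigma2` and the `correlation` matrix used.
#' @export
aggregate_molecular_distribution <- function(ap) {
  stopifnot(inherits(ap, "atomic_prediction"))
  R <- pairwise_correlation(ap$fingerprints)
  s <- ap$sigma_atoms
  sigma2 <- max(drop(crossprod(s, R %*% s)), .var_floor)
  structure(
    list(mu = sum(ap$mu_atoms), sigma2 = sigma2, correlation = R),
    class = "molecular_distribution"
  )
}

#' Molecule-level readout (pooled baseline)
#'
#' Sums the fingerprint rows into a molecular fingerprint, then applies the
#' shared trunk and the parallel mean/variance layers; the variance layer
#' output maps through softplus (scaled by `exp(2 log_scale)`, floored) to
#' the molecular variance directly. No correlation matrix is involved.
#'
#' @param fp Fingerprint matrix from [encode_atoms()].
#' @param params A [head_params()] object with `mode = "molecule"`.
#' @return A `molecular_distribution` with `correlation = NULL`.
#' @export
molecule_readout <- function(fp, params) {
  if (!identical(params$mode, "molecule")) {
    rlang::abort("molecule_readout() requires head parameters with mode = 'molecule'")
  }
  fm <- matrix(colSums(fp), nrow = 1)
  hf <- heads_forward(fm, params, keep_cache = FALSE)
  sigma2 <- exp(2 * params$log_scale) * (softplus(hf$raw) + .sigma_floor)
  sigma2 <- max(sigma2, .var_floor)
  structure(
    list(mu = hf$mu, sigma2 = sigma2, correlation = NULL),
    class = "molecular_distribution"
  )
}

#' Heteroscedastic Gaussian negative log-likelihood
#'
#' Per-sample negative log-likelihood of `y` under `N(mu, sigma2)`:
#' `(y - mu)^2 / (2 sigma2) + log(sigma2) / 2 + log(2 pi) / 2`. Vectorized;
#' the batch training loss is the mean of these values.
#'
#' @param mu,sigma2,y Numeric vectors (recycled to common length);
#'   `sigma2` must be strictly positive.
#' @return Numeric vector of per-sample NLL values.
#' @export
heteroscedastic_nll <- function(mu, sigma2, y) {
  if (any(sigma2 <= 0)) rlang::abort("sigma2 must be strictly positive")
  (y - mu)^2 / (2 * sigma2) + 0.5 * log(sigma2) + 0.5 * log(2 * pi)
}
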