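hp_atom <- head_params(8, mode = "atom", seed = 31)
hp_mol <- head_params(8, mode = "molecule", seed = 31)

test_that("atom readout maps each fingerprint row independently", {
  fp <- matrix(rep(c(0.3, -0.1, 0.5, 0.2, 0, 1, -1, 0.7), 3), nrow = 3, byrow = TRUE)
  ap <- atom_readout(fp, hp_atom)
  expect_s3_class(ap, "atomic_prediction")
  expect_length(ap$mu_atoms, 3)
  expect_true(all(ap$sigma_atoms > 0))
  # identical rows give identical outputs
  expect_equal(ap$mu_atoms, rep(ap$mu_atoms[1], 3))
  expect_equal(ap$sigma_atoms, rep(ap$sigma_atoms[1], 3))

  # zero weights + softplus: sigma = softplus(0) = log(2) for every atom
  hp0 <- hp_atom
  for (nm in c("W_t", "b_t", "w_mu", "b_mu", "w_vl", "b_vl", "log_scale")) {
    hp0[[nm]] <- hp0[[nm]] * 0
  }
  ap0 <- atom_readout(fp, hp0)
  expect_equal(ap0$sigma_atoms, rep(log(2), 3), tolerance = 1e-5)
  expect_equal(ap0$mu_atoms, rep(0, 3))

  # single atom gives length-1 vectors
  ap1 <- atom_readout(fp[1, , drop = FALSE], hp_atom)
  expect_length(ap1$mu_atoms, 1)
  expect_error(atom_readout(fp, hp_mol), "mode")
})

test_that("pairwise correlation matches the direct summation oracle", {
  u <- c(1, 2, 3, 5, 4, 7, 6, 9)
  expect_equal(pairwise_correlation(rbind(u, u))[1, 2], 1)
  expect_equal(pairwise_correlation(rbind(u, -u + 3))[1, 2], -1)
  w <- rep(2, 8)
  R <- pairwise_correlation(rbind(u, w))
  expect_equal(R[1, 2], 0)   # constant-row convention
  expect_equal(diag(R), c(1, 1), ignore_attr = TRUE)

  withr::with_seed(17, {
    fp <- matrix(rnorm(32), 4, 8)
    expect_equal(pairwise_correlation(fp), pearson_brute(fp),
                 tolerance = 1e-12, ignore_attr = TRUE)
  })
  expect_error(pairwise_correlation(matrix(1:4, 4, 1)), ">= 2")
})

test_that("correlation matrices of random fingerprints are PSD", {
  withr::with_seed(99, {
    for (k in 1:50) {
      fp <- matrix(rnorm(sample(2:8, 1) * 8), ncol = 8)
      R <- pairwise_correlation(fp)
      expect_true(isSymmetric(R, tol = 1e-12))
      expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
    }
  })
})

test_that("molecular aggregation computes the full quadratic form", {
  mk <- function(mu, sigma, fp) {
    structure(list(mu_atoms = mu, sigma_atoms = sigma, fingerprints = fp),
              class = "atomic_prediction")
  }
  u <- c(1, 2, 3, 5, 4, 7, 6, 9)
  # n = 1: no covariance terms
  d1 <- aggregate_molecular_distribution(mk(2, 3, matrix(u, 1)))
  expect_equal(d1$mu, 2)
  expect_equal(d1$sigma2, 9)
  # perfect correlation: (sigma1 + sigma2)^2
  d2 <- aggregate_molecular_distribution(mk(c(1, 1), c(1, 1), rbind(u, u)))
  expect_equal(d2$mu, 2)
  expect_equal(d2$sigma2, 4)
  # perfect anticorrelation collapses to the floor
  d3 <- aggregate_molecular_distribution(mk(c(1, 1), c(1, 1), rbind(u, -u)))
  expect_equal(d3$sigma2, 1e-8)

  withr::with_seed(23, {
    for (k in 1:20) {
      fp <- matrix(rnorm(40), 5, 8)
      sigma <- rexp(5) + 0.1
      dm <- aggregate_molecular_distribution(mk(rnorm(5), sigma, fp))
      expect_equal(dm$sigma2, molvar_brute(sigma, pairwise_correlation(fp)),
                   tolerance = 1e-10)
    }
  })
})

test_that("aggregated variance is non-negative before flooring", {
  withr::with_seed(77, {
    worst <- Inf
    for (k in 1:1000) {
      n <- sample(2:7, 1)
      fp <- matrix(rnorm(n * 6), n, 6)
      sigma <- rexp(n)
      R <- pairwise_correlation(fp)
      worst <- min(worst, drop(crossprod(sigma, R %*% sigma)))
    }
    expect_gte(worst, -1e-10)
  })
})

test_that("molecule readout is a permutation-invariant pooled head", {
  withr::with_seed(41, fp <- matrix(rnorm(4 * 8), 4, 8))
  d <- molecule_readout(fp, hp_mol)
  d_perm <- molecule_readout(fp[c(3, 1, 4, 2), ], hp_mol)
  expect_equal(d$mu, d_perm$mu)
  expect_equal(d$sigma2, d_perm$sigma2)
  expect_null(d$correlation)
  # zero weights + softplus gives sigma2 = softplus(0) = log(2)
  hp0 <- hp_mol
  for (nm in c("W_t", "b_t", "w_mu", "b_mu", "w_vl", "b_vl", "log_scale")) {
    hp0[[nm]] <- hp0[[nm]] * 0
  }
  expect_equal(molecule_readout(fp, hp0)$sigma2, log(2), tolerance = 1e-5)
  expect_error(molecule_readout(fp, hp_atom), "mode")
})

test_that("heteroscedastic NLL has its closed-form values and minimizer", {
  expect_equal(heteroscedastic_nll(1, 1, 1), 0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(heteroscedastic_nll(0, 1, 1), 0.5 + 0.5 * log(2 * pi), tolerance = 1e-12)
  expect_error(heteroscedastic_nll(0, 0, 1), "positive")
  expect_error(heteroscedastic_nll(0, -1, 1), "positive")

  # for fixed residual r the minimizer over sigma2 is r^2
  for (r in c(0.3, 1, 2.5)) {
    opt <- stats::optimize(function(v) heteroscedastic_nll(0, v, r),
                           interval = c(1e-4, 50))
    expect_equal(opt$minimum, r^2, tolerance = 1e-4)
  }

  # convex in mu for fixed sigma2 (nonnegative second difference)
  mus <- seq(-3, 3, by = 0.1)
  vals <- heteroscedastic_nll(mus, 0.7, 0.4)
  second <- diff(diff(vals))
  expect_true(all(second > -1e-12))

  # vectorized; batch loss is the mean
  v <- heteroscedastic_nll(c(0, 1), c(1, 2), c(1, 1))
  expect_length(v, 2)
})
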