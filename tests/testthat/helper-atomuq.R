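# Shared fixtures and independent oracles, all built in code.

suppressMessages({
  requireNamespace("dplyr")
  requireNamespace("tibble")
})

# tiny deterministic record set for IO/split tests
tiny_records <- function(n = 10, seed = 42) {
  smis <- c("C", "CO", "CCO", "CCN", "CC(=O)O", "c1ccccc1", "CCCF",
            "CNC", "OCCO", "CC(C)O", "CCOC", "NCCN")
  withr::with_seed(seed, tibble::tibble(
    id = sprintf("r%02d", seq_len(n)),
    smiles = rep_len(smis, n),
    y = stats::rnorm(n)
  ))
}

small_config <- function(seed = 1, mode = "atom", epochs = 12, d = 8) {
  train_config(mode = mode, hidden_dim = d, depth = 2, max_epochs = epochs,
               patience = 15, batch_size = 25, learning_rate = 2e-3, seed = seed)
}

# brute-force Pearson over rows, the direct double-loop form
pearson_brute <- function(fp) {
  n <- nrow(fp); d <- ncol(fp)
  R <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    xi <- fp[i, ]; xj <- fp[j, ]
    num <- sum((xi - mean(xi)) * (xj - mean(xj)))
    den <- sqrt(sum((xi - mean(xi))^2)) * sqrt(sum((xj - mean(xj))^2))
    R[i, j] <- if (den == 0) 0 else num / den
  }
  R
}

# brute-force molecular variance: explicit double sum over the covariance
# matrix built from sigmas and a correlation matrix
molvar_brute <- function(sigma, R) {
  n <- length(sigma)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    total <- total + R[i, j] * sigma[i] * sigma[j]
  }
  total
}

# naive confidence-curve ECE by explicit per-level looping
ece_brute <- function(mu, sigma2, y, levels) {
  efs <- numeric(length(levels))
  for (b in seq_along(levels)) {
    z <- stats::qnorm((1 + levels[b]) / 2)
    inside <- 0
    for (k in seq_along(y)) {
      lo <- mu[k] - z * sqrt(sigma2[k]); hi <- mu[k] + z * sqrt(sigma2[k])
      if (y[k] >= lo && y[k] <= hi) inside <- inside + 1
    }
    efs[b] <- inside / length(y)
  }
  list(ef = efs, ece = mean(abs(levels - efs)))
}

# naive sort-and-loop error curve
ence_brute <- function(mu, sigma2, y, bins) {
  ord <- order(sigma2)
  n <- length(y)
  sizes <- rep(n %/% bins, bins)
  if (n %% bins > 0) sizes[seq_len(n %% bins)] <- sizes[seq_len(n %% bins)] + 1
  rmse_b <- rmu_b <- numeric(bins)
  pos <- 1
  for (b in seq_len(bins)) {
    idx <- ord[pos:(pos + sizes[b] - 1)]
    pos <- pos + sizes[b]
    rmse_b[b] <- sqrt(mean((mu[idx] - y[idx])^2))
    rmu_b[b] <- sqrt(mean(sigma2[idx]))
  }
  list(rmse = rmse_b, rmu = rmu_b, ence = mean(abs(rmse_b - rmu_b) / rmu_b))
}

# permute the atoms of a mol_graph (relabeling oracle for equivariance)
permute_graph <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  g2 <- g
  g2$atom_features <- g$atom_features[perm, , drop = FALSE]
  g2$element <- g$element[perm]
  g2$edge_src <- inv[g$edge_src]
  g2$edge_dst <- inv[g$edge_dst]
  g2
}

# cache one small trained atom ensemble shared across test files
shared_env <- new.env(parent = emptyenv())

shared_split <- function() {
  if (is.null(shared_env$split)) {
    spec <- synthetic_spec(n_molecules = 220, seed = 404)
    data <- generate_molecules(spec)
    shared_env$split <- split_molecules(data, seed = 405)
  }
  shared_env$split
}

shared_ensemble <- function() {
  if (is.null(shared_env$ens)) {
    s <- shared_split()
    shared_env$ens <- train_ensemble(
      s[s$split == "train", ], s[s$split == "valid", ],
      M = 3, config = small_config(seed = 11, epochs = 15, d = 8)
    )
  }
  shared_env$ens
}
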