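test_that("training is deterministic given identical seeds and data", {
  d <- generate_molecules(synthetic_spec(n_molecules = 60, seed = 2))
  s <- split_molecules(d, 3)
  tr <- s[s$split == "train", ]; va <- s[s$split == "valid", ]
  cfg <- small_config(seed = 9, epochs = 6)
  m1 <- train_uncertainty_model(tr, va, cfg)
  m2 <- train_uncertainty_model(tr, va, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$par, m2$par)
})

test_that("a constant-target dataset is fit with shrinking variance", {
  d <- generate_molecules(synthetic_spec(n_molecules = 80, seed = 5))
  d$y <- 0
  s <- split_molecules(d, 4)
  cfg <- train_config(mode = "atom", hidden_dim = 8, depth = 2, max_epochs = 120,
                      patience = 25, batch_size = 25, learning_rate = 1e-3, seed = 2)
  m <- train_uncertainty_model(s[s$split == "train", ], s[s$split == "valid", ], cfg)
  p <- predict(m, s[s$split == "test", ])
  expect_lt(mae(p$mu, rep(0, nrow(p))), 0.2)
  expect_lt(mean(p$sigma2), 0.05)
  # the validation NLL keeps improving well past the warm-up epochs
  h <- m$history
  expect_lt(min(h$valid_nll), h$valid_nll[h$warmup][1])
  expect_gt(m$best_epoch, 20)
})

test_that("the model beats the mean-predictor baseline on additive data", {
  spec <- synthetic_spec(n_molecules = 300,
                         noise_scales = c(C = 0, N = 0, O = 0, F = 0), seed = 8)
  d <- generate_molecules(spec)
  s <- split_molecules(d, 6)
  tr <- s[s$split == "train", ]; te <- s[s$split == "test", ]
  cfg <- train_config(mode = "atom", hidden_dim = 16, max_epochs = 30,
                      batch_size = 50, seed = 3)
  m <- train_uncertainty_model(tr, s[s$split == "valid", ], cfg)
  p <- predict(m, te)
  baseline <- mean(abs(mean(tr$y) - te$y))
  expect_lt(mae(p$mu, te$y), 0.5 * baseline)
})

test_that("prediction is deterministic and atomic means sum to the molecular mean", {
  ens <- shared_ensemble()
  m <- ens$members[[1]]
  s <- shared_split()
  te <- s[s$split == "test", ]
  p1 <- predict(m, te)
  p2 <- predict(m, te)
  expect_identical(p1$mu, p2$mu)
  expect_identical(p1$sigma2, p2$sigma2)
  sums <- vapply(p1$atoms, function(a) sum(a$mu_atom), numeric(1))
  expect_equal(sums, p1$mu, tolerance = 1e-8)
  expect_true(all(p1$sigma2 > 0))
})

test_that("early stopping returns the best-validation checkpoint", {
  ens <- shared_ensemble()
  for (m in ens$members) {
    expect_equal(m$valid_nll, min(m$history$valid_nll))
    expect_equal(m$best_epoch, m$history$epoch[which.min(m$history$valid_nll)])
  }
})

test_that("checkpoints round-trip and reproduce the recorded validation loss", {
  ens <- shared_ensemble()
  m <- ens$members[[2]]
  path <- withr::local_tempfile(fileext = ".ckpt")
  write_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- read_checkpoint(path)
  expect_identical(m2$par, m$par)
  s <- shared_split()
  va <- s[s$split == "valid", ]
  bg <- atomuq:::batch_graphs(atomuq:::featurize_all(va$smiles))
  y_std <- (va$y - m2$norm$mean) / m2$norm$sd
  nll <- atomuq:::model_valid_nll(bg, m2$par, m2$meta, y_std)
  expect_equal(nll, m2$valid_nll, tolerance = 1e-6)
})

test_that("predicted variance separates two structural noise regimes in order", {
  # regime A: C/N molecules, quiet labels; regime B: C/O molecules with
  # strong oxygen-keyed noise. The regimes are identifiable from structure,
  # so a heteroscedastic model should rank them correctly.
  correct <- logical(5)
  for (i in 1:5) {
    a <- generate_molecules(synthetic_spec(
      n_molecules = 150, noise_scales = c(C = 0.1, N = 0.1, O = 0.1, F = 0.1),
      element_weights = c(C = 0.7, N = 0.3, O = 0, F = 0), seed = 50 + i
    ))
    b <- generate_molecules(synthetic_spec(
      n_molecules = 150, noise_scales = c(C = 0.1, N = 0.1, O = 1.2, F = 0.1),
      element_weights = c(C = 0.7, N = 0, O = 0.3, F = 0), seed = 950 + i
    ))
    b$id <- sub("syn", "oxy", b$id)
    d <- dplyr::bind_rows(a, b)
    s <- split_molecules(d, 1000 + i)
    cfg <- train_config(mode = "atom", hidden_dim = 16, depth = 2,
                        max_epochs = 40, patience = 15, batch_size = 25,
                        learning_rate = 2e-3, seed = i)
    m <- train_uncertainty_model(s[s$split == "train", ], s[s$split == "valid", ], cfg)
    te <- s[s$split == "test", ]
    p <- predict(m, te)
    in_b <- grepl("^oxy", te$id)
    correct[i] <- mean(p$sigma2[in_b]) > mean(p$sigma2[!in_b])
  }
  expect_gte(mean(correct), 0.9)
})

test_that("the molecule-based baseline trains and predicts without atomic detail", {
  s <- shared_split()
  tr <- s[s$split == "train", ]; va <- s[s$split == "valid", ]
  m <- train_uncertainty_model(tr, va, small_config(seed = 4, mode = "molecule",
                                                    epochs = 10))
  expect_equal(m$meta$mode, "molecule")
  p <- predict(m, s[s$split == "test", ])
  expect_false("atoms" %in% names(p))
  expect_true(all(p$sigma2 > 0))
  expect_true(all(is.finite(p$mu)))
})

test_that("degenerate training inputs raise errors", {
  d <- tiny_records(6)
  expect_error(
    train_uncertainty_model(d[0, ], d, small_config()),
    "non-empty"
  )
})
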