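test_that("ensemble moments satisfy the total-variance identity", {
  # two members (mu, sigma2) = (1, 1), (3, 1)
  mom <- ensemble_moments(matrix(c(1, 3), 1), matrix(c(1, 1), 1))
  expect_equal(mom$mu_ens, 2)
  expect_equal(mom$sigma2_ale, 1)
  expect_equal(mom$sigma2_epi, 1)
  # second moment form: (1+1+1+9)/2 - 4 = 2 = ale + epi
  expect_equal((1 + 1 + 1 + 9) / 2 - 4, mom$sigma2_ale + mom$sigma2_epi)

  # single member: no disagreement
  mom1 <- ensemble_moments(matrix(5, 1), matrix(2, 1))
  expect_equal(mom1$sigma2_epi, 0)
  expect_equal(mom1$sigma2_ale, 2)

  # both printed forms agree on random ensembles
  withr::with_seed(12, {
    for (k in 1:1000) {
      M <- sample(2:8, 1)
      mu <- matrix(rnorm(M), 1)
      v <- matrix(rexp(M), 1)
      mom <- ensemble_moments(mu, v)
      lhs <- mean(v + mu^2) - mom$mu_ens^2
      expect_equal(lhs, mom$sigma2_ale + mom$sigma2_epi, tolerance = 1e-10)
    }
  })
})

test_that("ensemble prediction aggregates members and decomposes per atom", {
  ens <- shared_ensemble()
  s <- shared_split()
  te <- s[s$split == "test", ]
  p <- ensemble_predict(ens, te)
  expect_equal(nrow(p), nrow(te))
  expect_true(all(p$sigma2_ale > 0))
  expect_true(all(p$sigma2_epi >= 0))
  expect_equal(p$sigma2_total, p$sigma2_ale + p$sigma2_epi)

  # mu_ens is the mean of member means
  member_mu <- vapply(ens$members, function(m) predict(m, te)$mu, numeric(nrow(te)))
  expect_equal(p$mu_ens, rowMeans(member_mu), tolerance = 1e-12)

  # per-atom ensemble means sum to the molecular ensemble mean
  sums <- vapply(p$atoms, function(a) sum(a$mu_atom), numeric(1))
  expect_equal(sums, p$mu_ens, tolerance = 1e-8)

  # molecular aleatoric minus summed atomic aleatoric equals the mean
  # member covariance contribution (off-diagonal part of the quadratic form)
  member_off <- vapply(ens$members, function(m) {
    pm <- predict(m, te)
    pm$sigma2 - vapply(pm$atoms, function(a) sum(a$sigma_atom^2), numeric(1))
  }, numeric(nrow(te)))
  expect_equal(p$sigma2_ale - vapply(p$atoms, function(a) sum(a$sigma2_ale_atom), numeric(1)),
               rowMeans(member_off), tolerance = 1e-8)
})

test_that("identical members produce zero epistemic uncertainty", {
  ens <- shared_ensemble()
  clone <- ens
  clone$members <- ens$members[c(1, 1, 1)]
  s <- shared_split()
  te <- s[s$split == "test", ][1:5, ]
  p <- ensemble_predict(clone, te)
  expect_equal(p$sigma2_epi, rep(0, 5))
  for (a in p$atoms) expect_equal(a$sigma2_epi_atom, rep(0, nrow(a)))
})

test_that("single-atom molecules have atomic values equal to molecular values", {
  ens <- shared_ensemble()
  rec <- tibble::tibble(id = "m1", smiles = "C", y = 0)
  p <- ensemble_predict(ens, rec)
  a <- p$atoms[[1]]
  expect_equal(nrow(a), 1)
  expect_equal(a$sigma2_ale_atom, p$sigma2_ale, tolerance = 1e-10)
  expect_equal(a$sigma2_epi_atom, p$sigma2_epi, tolerance = 1e-10)
  expect_equal(a$mu_atom, p$mu_ens, tolerance = 1e-10)

  d <- decompose_atomic_uncertainty(ens, rec)
  expect_equal(d, a)
})

test_that("mode mismatches and empty ensembles are rejected", {
  ens <- shared_ensemble()
  expect_error(as_mix <- ensemble_predict(
    structure(list(members = list(), M = 0L, mode = "atom"),
              class = "atomuq_ensemble"),
    tiny_records(3)
  ))
  mol_member <- ens$members[[1]]
  mol_member$meta$mode <- "molecule"
  mixed <- ens
  mixed$members[[2]] <- mol_member
  expect_error(ensemble_predict(mixed, tiny_records(3)), "share one mode")
  expect_error(decompose_atomic_uncertainty(list(mol_member), tiny_records(1)),
               "atom-based")
})

test_that("ensemble directories round-trip with the documented layout", {
  ens <- shared_ensemble()
  dir <- withr::local_tempdir()
  write_ensemble(ens, dir)
  expect_true(all(file.exists(file.path(dir, sprintf("member_%03d.ckpt", 0:2)))))
  expect_true(file.exists(file.path(dir, "ensemble.json")))
  ens2 <- read_ensemble(dir)
  expect_equal(ens2$M, 3L)
  expect_identical(ens2$members[[1]]$par, ens$members[[1]]$par)
  meta <- jsonlite::read_json(file.path(dir, "ensemble.json"), simplifyVector = TRUE)
  expect_false(meta$calibrated)
  expect_equal(meta$seeds, vapply(ens$members, function(m) m$config$seed, integer(1)))
})

test_that("variance inflation scales predictive variances exactly", {
  ens <- shared_ensemble()
  s <- shared_split()
  te <- s[s$split == "test", ][1:6, ]
  p0 <- ensemble_predict(ens, te)
  p4 <- ensemble_predict(inflate_variance(ens, 4), te)
  expect_equal(p4$sigma2_ale, 4 * p0$sigma2_ale, tolerance = 1e-10)
  expect_identical(p4$mu_ens, p0$mu_ens)
  expect_identical(p4$sigma2_epi, p0$sigma2_epi)
})
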