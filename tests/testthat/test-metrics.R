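test_that("mae and rmse match their definitions", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(2, 0), c(1, 1)), 1)
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  withr::with_seed(3, {
    a <- rnorm(50); b <- rnorm(50)
    expect_equal(mae(a, b), mean(vapply(seq_along(a), function(i) abs(a[i] - b[i]), 1)),
                 tolerance = 1e-12)
    expect_gte(rmse(a, b), mae(a, b))   # Jensen
  })
  expect_error(mae(1:3, 1:2), "equal length")
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
})

test_that("confidence curve covers its closed-form cases", {
  # y = mu exactly: every interval contains y
  cc <- confidence_curve(rep(1, 5), rep(1, 5), rep(1, 5))
  expect_true(all(cc$curve$fraction == 1))
  expect_equal(cc$ece, mean(1 - cc$curve$level), tolerance = 1e-12)

  # two points straddling the median interval: z(0.5) ~ 0.674 separates them
  cc2 <- confidence_curve(c(0, 0), c(1, 1), c(0.1, 10), levels = 0.5)
  expect_equal(cc2$curve$fraction, 0.5)
  expect_equal(cc2$ece, 0)

  expect_error(confidence_curve(0, -1, 0), "positive")
  expect_error(confidence_curve(c(0, 1), c(1, 1), 0), "equal length")
})

test_that("confidence curve matches the brute-force oracle and is monotone", {
  withr::with_seed(8, {
    mu <- rnorm(40); s2 <- rexp(40); y <- rnorm(40, mu, 1)
    levels <- seq(0.05, 0.95, by = 0.05)
    cc <- confidence_curve(mu, s2, y, levels)
    oracle <- ece_brute(mu, s2, y, levels)
    expect_equal(cc$curve$fraction, oracle$ef, tolerance = 1e-12)
    expect_equal(cc$ece, oracle$ece, tolerance = 1e-12)
    # nested intervals: EF non-decreasing in CL
    expect_true(all(diff(cc$curve$fraction) >= 0))
    # doubling variances increases coverage at every level not yet saturated
    cc2 <- confidence_curve(mu, 2 * s2, y, levels)
    not_full <- cc$curve$fraction < 1
    expect_true(all(cc2$curve$fraction[not_full] > cc$curve$fraction[not_full] - 1e-12))
    expect_true(all(cc2$curve$fraction >= cc$curve$fraction))
    expect_gte(cc$ece, 0); expect_lte(cc$ece, 1)
  })
})

test_that("well-specified Gaussian predictions are calibrated at large N", {
  withr::with_seed(2024, {
    n <- 20000
    mu <- rnorm(n)
    s2 <- rexp(n, rate = 2) + 0.05
    y <- rnorm(n, mean = mu, sd = sqrt(s2))
    expect_lt(ece(mu, s2, y), 0.02)
    expect_lt(ence(mu, s2, y, bins = 10), 0.1)
  })
})

test_that("error curve follows the sort-and-bin construction", {
  # constant sigma2 = c with all squared residuals = c: perfect parity
  mu <- rep(0, 12); y <- rep(2, 12); s2 <- rep(4, 12)
  ec <- error_curve(mu, s2, y, bins = 3)
  expect_equal(ec$curve$rmu, rep(2, 3))
  expect_equal(ec$curve$rmse, rep(2, 3))
  expect_equal(ec$ence, 0)

  # one bin, RMU 2, RMSE 1 -> ENCE = 1/2
  ec1 <- error_curve(0, 4, 1, bins = 1)
  expect_equal(ec1$ence, 0.5)

  expect_error(error_curve(1:3, 1:3, 1:3, bins = 4), "bins")

  withr::with_seed(14, {
    mu <- rnorm(47); s2 <- rexp(47); y <- rnorm(47)
    for (b in c(1, 5, 10)) {
      ec <- error_curve(mu, s2, y, bins = b)
      oracle <- ence_brute(mu, s2, y, b)
      expect_equal(ec$curve$rmse, oracle$rmse, tolerance = 1e-12)
      expect_equal(ec$curve$rmu, oracle$rmu, tolerance = 1e-12)
      expect_equal(ec$ence, oracle$ence, tolerance = 1e-12)
      expect_gte(ec$ence, 0)
      # bins ordered by ascending RMU, sizes near-equal
      expect_true(all(diff(ec$curve$rmu) >= -1e-12))
      expect_lte(diff(range(ec$curve$n)), 1)
    }
  })
})

test_that("evaluation report has the documented schema", {
  withr::with_seed(5, {
    preds <- tibble::tibble(
      mu_ens = rnorm(30), sigma2_ale = rexp(30), sigma2_epi = rexp(30) * 0.1
    )
    preds$sigma2_total <- preds$sigma2_ale + preds$sigma2_epi
    rep <- evaluate_predictions(preds, rnorm(30))
    expect_named(rep, c("mae", "rmse", "ece_ale", "ece_epi", "ence_ale", "ence_epi", "n"))
    expect_equal(rep$n, 30)
  })
})

test_that("tidy/glance/autoplot methods work on curve objects", {
  withr::with_seed(6, {
    cc <- confidence_curve(rnorm(20), rexp(20), rnorm(20))
    ec <- error_curve(rnorm(20), rexp(20), rnorm(20), bins = 4)
  })
  expect_s3_class(tidy(cc), "tbl_df")
  expect_equal(glance(cc)$ece, cc$ece)
  expect_equal(glance(ec)$ence, ec$ence)
  expect_s3_class(ggplot2::autoplot(cc), "ggplot")
  expect_s3_class(ggplot2::autoplot(ec), "ggplot")
})
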