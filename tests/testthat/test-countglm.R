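test_that("log pmfs agree with direct formulas and normalize", {
  expect_equal(poisson_logpmf(0, 2), -2)
  expect_equal(poisson_logpmf(3, 2), 3 * log(2) - 2 - log(6), tolerance = 1e-12)
  expect_equal(sum(exp(poisson_logpmf(0:200, 5))), 1, tolerance = 1e-12)

  expect_equal(nb2_logpmf(0, r = 5, p = 0.5), 5 * log(0.5), tolerance = 1e-12)
  # generalized binomial coefficient via log-gamma, checked directly
  y <- 7
  r <- 10.68
  p <- 0.4
  direct <- lgamma(y + r) - lgamma(r) - lgamma(y + 1) + r * log(p) + y * log(1 - p)
  expect_equal(nb2_logpmf(y, r, p), direct, tolerance = 1e-12)
  expect_equal(sum(exp(nb2_logpmf(0:5000, r = 10.68, p = 0.4))), 1,
    tolerance = 1e-10
  )
  # p near 1 concentrates all mass at zero
  expect_equal(nb2_logpmf(0, r = 3, p = 1 - 1e-12), 0, tolerance = 1e-9)

  expect_error(poisson_logpmf(2, -1), "positive")
  expect_error(poisson_logpmf(2.5, 1), "integer")
  expect_error(nb2_logpmf(1, r = -2, p = 0.5), "positive")
  expect_error(nb2_logpmf(1, r = 2, p = 1.2), "\\(0, 1\\)")
})

test_that("Poisson MLE matches closed forms and satisfies the score identity", {
  fit <- count_glm(toy_count_data(), y ~ 1, family = "poisson")
  expect_equal(unname(coef(fit)), log(8.6), tolerance = 1e-8)

  fit2 <- count_glm(toy_count_data(), y ~ x, family = "poisson")
  expect_lt(abs(sum(fit2$Y - fit2$fitted)), 1e-6)
  expect_true(fit2$converged)

  zeros <- tibble::tibble(species = letters[1:5], y = 0L)
  expect_error(count_glm(zeros, y ~ 1, family = "poisson"), "divergent")
})

test_that("NB2 fitting handles over- and underdispersion", {
  withr::local_seed(21)
  n <- 150
  x <- rnorm(n)
  mu <- exp(1 + 0.6 * x)
  over <- tibble::tibble(y = rnbinom(n, size = 3, mu = mu), x = x)
  fit <- count_glm(over, y ~ x, family = "nb2")
  expect_gt(fit$r, 1)
  expect_lt(fit$r, 20)
  # NB2 log-likelihood beats the Poisson-matched one on overdispersed data
  poi <- count_glm(over, y ~ x, family = "poisson")
  expect_gt(fit$loglik, poi$loglik)

  # equidispersed (Poisson) data: large r, coefficients at the Poisson MLE
  under <- tibble::tibble(y = rpois(n, mu), x = x)
  fitu <- suppressWarnings(count_glm(under, y ~ x, family = "nb2"))
  expect_gt(fitu$r, 10)
  poiu <- count_glm(under, y ~ x, family = "poisson")
  expect_lt(max(abs(coef(fitu) - coef(poiu))), 1e-2)

  # genuinely underdispersed (near-deterministic) counts push r to the cap
  det <- tibble::tibble(y = round(mu), x = x)
  expect_warning(fitd <- count_glm(det, y ~ x, family = "nb2"), "capped")
  expect_equal(fitd$r, 1e6)
  poid <- count_glm(det, y ~ x, family = "poisson")
  expect_lt(max(abs(coef(fitd) - coef(poid))), 1e-2)

  # intercept-only NB2 matches the sample mean exactly, whatever r
  fit0 <- count_glm(over, y ~ 1, family = "nb2", r = 2.5)
  expect_equal(unname(exp(coef(fit0))), mean(over$y), tolerance = 1e-8)
})

test_that("aicc follows the small-sample formula and validates inputs", {
  # AIC = 10 at k = 2 means loglik = (2k - 10)/2 = -3
  expect_equal(aicc(-3, k = 2, n = 10), 10 + 12 / 7, tolerance = 1e-12)
  expect_equal(aicc(-7, k = 0, n = 25), 14) # k = 0: AICc equals AIC
  expect_error(aicc(-3, k = 9, n = 10), "n > k")

  # stored AICc always reproducible from stored loglik/k/n
  fit <- count_glm(toy_count_data(), y ~ x, family = "poisson")
  expect_identical(fit$aicc, aicc(fit$loglik, fit$k, fit$n))
})

test_that("akaike weights normalize, shift-invariantly", {
  w <- akaike_weights(c(116.81, 116.43))
  expect_equal(sum(w), 1)
  expect_equal(round(w, 2), c(0.45, 0.55))
  w2 <- akaike_weights(c(228.84, 229.52))
  expect_equal(round(w2, 2), c(0.58, 0.42))

  expect_equal(akaike_weights(c(10, 12, 14) + 137), akaike_weights(c(10, 12, 14)))
  expect_equal(akaike_weights(rep(3.3, 4)), rep(0.25, 4))
  expect_error(akaike_weights(numeric(0)), "nonempty")
})

test_that("model comparison table carries response summaries and weights", {
  withr::local_seed(8)
  n <- 60
  x <- rnorm(n)
  d <- tibble::tibble(
    species = paste0("s", 1:n),
    y = rnbinom(n, size = 2, mu = exp(1.5 + 0.4 * x)), x = x
  )
  tab <- compare_count_models(d, y ~ x)
  expect_s3_class(tab, "tbl_df")
  expect_equal(tab$family, c("poisson", "nb2"))
  expect_equal(tab$mean_y, rep(mean(d$y), 2))
  expect_equal(tab$var_y, rep(var(d$y), 2))
  expect_equal(sum(tab$weight), 1)
  # strongly overdispersed data must favour NB2
  expect_gt(tab$weight[tab$family == "nb2"], 0.5)
})
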