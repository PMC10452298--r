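test_that("family specs satisfy their mean/variance identities", {
  poi <- gee_family("poisson")
  eta <- c(-1, 0, 2)
  expect_equal(poi$linkinv(eta), exp(eta))
  expect_equal(poi$variance(exp(eta)), exp(eta))
  expect_equal(poi$mu_eta(eta), exp(eta))

  can <- gee_family("nb2", link = "canonical", r = 10.68)
  eta <- c(-3, -1, -0.2)
  mu <- 10.68 * exp(eta) / (1 - exp(eta))
  expect_equal(can$linkinv(eta), mu)
  expect_equal(can$variance(mu), mu + mu^2 / 10.68)
  # canonical link: dmu/deta equals the variance
  expect_equal(can$mu_eta(eta), can$variance(mu), tolerance = 1e-12)
  expect_equal(can$linkfun(mu), eta, tolerance = 1e-12)
  expect_false(any(can$in_domain(c(0, 0.5))))

  logl <- gee_family("nb2", link = "log", r = 4)
  expect_equal(logl$variance(2), 2 + 1)
  expect_error(gee_family("nb2"), "positive dispersion")
})

test_that("with identity C the estimating function reduces to the GLM score", {
  d <- toy_count_data()
  Y <- d$y
  X <- cbind(1, d$x)
  C <- diag(5)
  fam <- gee_family("poisson")
  for (beta in list(c(0, 0), c(1, 0.05), c(-0.5, 0.1))) {
    expect_equal(
      gee_score(beta, Y, X, C, fam),
      drop(crossprod(X, Y - exp(drop(X %*% beta)))),
      tolerance = 1e-8
    )
  }
  # at the independent MLE the score vanishes
  mle <- coef(count_glm(d, y ~ x, family = "poisson"))
  expect_lt(max(abs(gee_score(unname(mle), Y, X, C, fam))), 1e-6)
})

test_that("canonical-link domain violations name the offending tips", {
  d <- toy_count_data()
  X <- cbind(1, d$x)
  rownames(X) <- d$species
  fam <- gee_family("nb2", link = "canonical", r = 3)
  expect_error(
    gee_score(c(0.1, 0), d$y, X, diag(5), fam),
    "eta must be < 0"
  )
})

test_that("star-tree GEE estimates coincide with the independent GLM", {
  withr::local_seed(101)
  for (k in 1:5) {
    sd_poi <- make_star_data(20, family = "poisson")
    g <- count_glm(sd_poi$data, y ~ x, family = "poisson")
    pg <- phylo_glm(sd_poi$data, y ~ x, sd_poi$tree, family = "poisson")
    expect_lt(max(abs(coef(g) - coef(pg))), 1e-6)

    sd_nb <- make_star_data(20, family = "nb2", r = 5)
    gn <- count_glm(sd_nb$data, y ~ x, family = "nb2", r = 5)
    pgn <- phylo_glm(sd_nb$data, y ~ x, sd_nb$tree, family = "nb2", r = 5)
    expect_lt(max(abs(coef(gn) - coef(pgn))), 1e-5)
  }
})

test_that("uniform rescaling of C leaves the GEE root unchanged", {
  withr::local_seed(5)
  tr <- generate_tree("coalescent", 12)
  C <- tree_covariance(tr)
  x <- simulate_bm_covariate(C, 0, 1)
  fam <- gee_family("poisson")
  Y <- rcount_copula(exp(1 + 0.8 * x), C, fam)
  X <- cbind(1, x)
  f1 <- fit_gee(Y, X, C, fam)
  f2 <- fit_gee(Y, X, 7.3 * C, fam)
  expect_true(f1$converged && f2$converged)
  expect_lt(max(abs(f1$beta - f2$beta)), 1e-7)
})

test_that("jointly permuting tips leaves the estimates unchanged", {
  withr::local_seed(12)
  tr <- generate_tree("coalescent", 10)
  C <- tree_covariance(tr)
  x <- simulate_bm_covariate(C, 0, 1)
  fam <- gee_family("poisson")
  Y <- rcount_copula(exp(1 + 0.5 * x), C, fam)
  X <- cbind(1, x)
  f1 <- fit_gee(Y, X, C, fam)
  perm <- sample(10)
  f2 <- fit_gee(Y[perm], X[perm, ], C[perm, perm], fam)
  expect_lt(max(abs(f1$beta - f2$beta)), 1e-6)
})

test_that("rank-deficient C takes the pseudo-inverse path and still fits", {
  withr::local_seed(3)
  tr <- generate_tree("coalescent", 8)
  C <- tree_covariance(tr)
  C[2, ] <- C[1, ] # duplicate one tip's row/column: exactly singular
  C[, 2] <- C[, 1]
  C[2, 2] <- C[1, 1]
  x <- rnorm(8)
  Y <- rpois(8, exp(1 + 0.4 * x))
  fit <- fit_gee(Y, cbind(1, x), C, gee_family("poisson"))
  expect_true(fit$working_rank_deficient)
  expect_true(is.finite(fit$working_cond))
  expect_true(all(is.finite(fit$beta)))
})

test_that("solver roots agree with a brute-force grid + bisection oracle", {
  withr::local_seed(77)
  fam <- gee_family("poisson")
  n_checked <- 0
  for (k in 1:6) {
    tr <- generate_tree("coalescent", 3)
    C <- tree_covariance(tr)
    x <- simulate_bm_covariate(C, 0, 1)
    Y <- rcount_copula(exp(1 + 0.8 * x), C, fam)
    if (all(Y == 0)) next
    X <- cbind(1, x)
    fit <- fit_gee(Y, X, C, fam)
    oracle <- oracle_gee_root(Y, X, C, fam)
    if (is.null(oracle) || !fit$converged) next
    n_checked <- n_checked + 1
    expect_lt(oracle_distance(fit$beta, oracle), 1e-4)
  }
  expect_gte(n_checked, 3)
})

test_that("fitted values follow the family inverse link", {
  d <- toy_count_data()
  fit <- phylo_glm(d, y ~ x, five_taxon_tree(), family = "poisson")
  X <- cbind(1, d$x)
  expect_equal(fitted_values(fit, X), exp(drop(X %*% fit$beta)),
    tolerance = 1e-12
  )
  expect_equal(fitted_values(fit), fit$fitted)

  # canonical NB2 mean at eta = -1, r = 10.68
  can <- gee_family("nb2", link = "canonical", r = 10.68)
  expect_equal(can$linkinv(-1), 10.68 * exp(-1) / (1 - exp(-1)),
    tolerance = 1e-12
  )
  expect_equal(can$linkinv(-1), 6.2153, tolerance = 1e-4)

  # zero coefficients, log link: all means are one
  fit0 <- fit_gee(d$y, X, diag(5), gee_family("poisson"),
    beta_init = c(0, 0), control = gee_control(max_iter = 0L)
  )
  expect_equal(fitted_values(fit0, X), rep(1, 5))
})

test_that("iteration exhaustion is reported, never hidden", {
  withr::local_seed(2)
  tr <- generate_tree("coalescent", 10)
  C <- tree_covariance(tr)
  x <- simulate_bm_covariate(C, 0, 1)
  fam <- gee_family("poisson")
  Y <- rcount_copula(exp(2 + x), C, fam)
  fit <- fit_gee(Y, cbind(1, x), C, fam,
    beta_init = c(-3, 3), control = gee_control(max_iter = 1L)
  )
  expect_false(fit$converged)
  expect_true(is.finite(fit$score_norm))
  d <- tibble::tibble(species = tr$tip.label, y = Y, x = x)
  expect_warning(
    phylo_glm(d, y ~ x, tr, family = "poisson", control = gee_control(max_iter = 0L)),
    "did not converge"
  )
})

test_that("the literal mean-only working variance is available for NB2", {
  withr::local_seed(9)
  tr <- generate_tree("coalescent", 16)
  C <- tree_covariance(tr)
  x <- simulate_bm_covariate(C, 0, 1)
  fam <- gee_family("nb2", link = "log", r = 3)
  Y <- rcount_copula(exp(1 + 0.5 * x), C, fam)
  X <- cbind(1, x)
  f_var <- fit_gee(Y, X, C, fam, working_var = "family")
  f_mu <- fit_gee(Y, X, C, fam, working_var = "mean")
  expect_true(f_var$converged && f_mu$converged)
  # different working weights move the root (slightly) on a correlated tree
  expect_gt(max(abs(f_var$beta - f_mu$beta)), 1e-8)
  # on a star tree, mean-only weights make the NB2 score collapse to the
  # Poisson score (D = W = diag(mu)), so the root is the Poisson MLE
  st <- make_star_data(20, family = "nb2", r = 3)
  al <- align_data(st$data, st$tree, y ~ x)
  g <- count_glm(st$data, y ~ x, family = "poisson")
  fs <- fit_gee(al$Y, al$X, al$C, fam, working_var = "mean")
  expect_lt(max(abs(fs$beta - coef(g))), 1e-5)
})

test_that("tidy and glance expose estimates and diagnostics", {
  fit <- phylo_glm(toy_count_data(), y ~ x, five_taxon_tree(), family = "poisson")
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "x"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, 5L)
  expect_true(gl$score_norm < 1e-6)
})
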