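#' Solver settings for the GEE root-finder
#'
#' @param score_tol Convergence tolerance on the maximum absolute component of
#'   the estimating function (and of its standardized form).
#' @param rel_tol Convergence tolerance on the relative change in the
#'   coefficients between iterations.
#' @param max_iter Maximum number of damped Newton (Fisher-scoring) steps.
#' @param max_halvings Maximum number of step halvings per iteration.
#' @param svd_tol Relative eigenvalue cutoff below which the working
#'   covariance is inverted by pseudo-inverse rather than exactly.
#' @return A list of class `gee_control`.
#' @export
gee_control <- function(score_tol = 1e-8, rel_tol = 1e-10, max_iter = 100L,
                        max_halvings = 30L, svd_tol = 1e-10) {
  structure(
    list(
      score_tol = score_tol, rel_tol = rel_tol, max_iter = as.integer(max_iter),
      max_halvings = as.integer(max_halvings), svd_tol = svd_tol
    ),
    class = "gee_control"
  )
}

# eigendecomposition of the tree covariance C with a relative cutoff;
# computed once per fit (C does not change across iterations). Inverting
# through C rather than the full working covariance W = S^{1/2} C S^{1/2}
# keeps the estimating function accurate when the means span many orders of
# magnitude: the diagonal factor S is applied analytically, so round-off is
# governed by cond(C) alone.
cov_factor <- function(C, svd_tol = 1e-10) {
  ee <- eigen(C, symmetric = TRUE)
  d <- ee$values
  dmax <- max(d, 0)
  if (dmax <= 0) stop("`C` is not positive semi-definite.", call. = FALSE)
  keep <- d > svd_tol * dmax
  list(
    Q = ee$vectors,
    dinv = ifelse(keep, 1 / d, 0),
    cond = dmax / min(d[keep]),
    rank_deficient = !all(keep)
  )
}

# score, Fisher-type slope matrix and diagnostics at beta; quiet about domain
# violations (valid = FALSE) so the line search can back off.
# score = U^t C^{-1} u with U = diag(dmu/s) X and u = (Y - mu)/s, s = sqrt(V):
# algebraically D^t W^{-1} (Y - mu).
gee_parts <- function(beta, Y, X, C, fam, svd_tol = 1e-10,
                      working_var = c("family", "mean"), cf = NULL) {
  working_var <- match.arg(working_var)
  if (is.null(cf)) cf <- cov_factor(C, svd_tol)
  eta <- drop(X %*% beta)
  if (!all(fam$in_domain(eta))) {
    return(list(valid = FALSE))
  }
  mu <- fam$linkinv(eta)
  dmu <- fam$mu_eta(eta)
  v <- if (working_var == "mean") mu else fam$variance(mu)
  if (!all(is.finite(mu)) || !all(is.finite(v)) || any(v <= 0)) {
    return(list(valid = FALSE))
  }
  s <- sqrt(v)
  U <- (dmu / s) * X
  u <- (Y - mu) / s
  tU <- crossprod(cf$Q, U)
  tu <- drop(crossprod(cf$Q, u))
  score <- drop(crossprod(tU, cf$dinv * tu))
  J <- crossprod(tU, cf$dinv * tU)
  if (!all(is.finite(score))) {
    return(list(valid = FALSE))
  }
  list(
    valid = TRUE, score = score, J = J, mu = mu, v = v,
    cond_C = cf$cond, rank_deficient = cf$rank_deficient
  )
}
#' Estimating function of the phylogenetic count GEE
#'
#' Evaluates the quasi-score \eqn{D^T W^{-1} (Y - \mu)} at `beta`, where
#' \eqn{D = \mathrm{diag}(d\mu/d\eta) X} and the working covariance is
#' \eqn{W = S^{1/2} C S^{1/2}} with \eqn{S = \mathrm{diag}(V(\mu))}. For the
#' Poisson family S is `diag(mu)`; for NB2 the default is the NB2 variance
#' `diag(mu + mu^2/r)`, with a literal `diag(mu)` working variance available
#' via `working_var = "mean"` for comparison. When C is the identity the score
#' reduces exactly to the independent GLM score `t(X) %*% (Y - mu)` divided
#' through by nothing — i.e. the same root.
#'
#' @param beta Coefficient vector of length `ncol(X)`.
#' @param Y Integer count response (length n).
#' @param X n x (p+1) design matrix whose first column is the intercept.
#' @param C n x n shared-branch-length covariance matrix aligned to `Y`.
#' @param family A [gee_family()].
#' @param working_var `"family"` (default: the family variance) or `"mean"`
#'   (literal `diag(mu)` for NB2).
#' @param svd_tol Relative eigenvalue cutoff for pseudo-inversion of W.
#' @return Numeric vector of length `ncol(X)`.
#' @examples
#' d <- toy_count_data()
#' X <- cbind(1, d$x)
#' fam <- gee_family("poisson")
#' gee_score(c(1, 0.05), d$y, X, tree_covariance(five_taxon_tree()), fam)
#' @export
gee_score <- function(beta, Y, X, C, family, working_var = c("family", "mean"),
                      svd_tol = 1e-10) {
  working_var <- match.arg(working_var)
  check_gee_inputs(Y, X, C)
  eta <- drop(X %*% beta)
  check_domain(family, eta, labels = rownames(X) %||% colnames(C))
  p <- gee_parts(beta, Y, X, C, family, svd_tol, working_var)
  if (!p$valid) {
    stop("Estimating function is not finite at `beta`.", call. = FALSE)
  }
  p$score
}

check_gee_inputs <- function(Y, X, C) {
  n <- length(Y)
  if (!is.matrix(X) || nrow(X) != n) {
    stop("`X` must be a matrix with one row per observation.", call. = FALSE)
  }
  if (!is.matrix(C) || any(dim(C) != n)) {
    stop("`C` must be an n x n matrix aligned to `Y`.", call. = FALSE)
  }
  if (any(Y < 0) || any(Y != round(Y))) {
    stop("`Y` must contain nonnegative integer counts.", call. = FALSE)
  }
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C)))) {
    stop("`C` must be symmetric.", call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the phylogenetic count GEE (matrix interface)
#'
#' Solves the estimating equations [gee_score()] `= 0` for the regression
#' coefficients by damped Fisher scoring with step halving, starting from the
#' corresponding independent GLM fit. The working covariance is inverted by
#' eigendecomposition with a relative cutoff, so rank-deficient C (duplicated
#' tips, star trees with zero-length tips) degrades to a pseudo-inverse rather
#' than failing. Non-convergence is reported, never silently dropped.
#'
#' Most users want the data-frame interface [phylo_glm()]; this function is
#' the computational core, useful for simulation loops.
#'
#' @inheritParams gee_score
#' @param beta_init Optional starting coefficients; defaults to the
#'   independent GLM estimate for the same family (Poisson GLM transformed
#'   through the canonical NB link when needed).
#' @param control A [gee_control()].
#' @return An object of class `phylo_gee` with elements `beta`, `family`,
#'   `fitted`, `converged`, `iterations`, `score`, `score_norm`,
#'   `working_cond` (condition number of W at the solution), `n`, and the
#'   inputs needed to refit (for the bootstrap).
#' @examples
#' d <- toy_count_data()
#' X <- cbind(`(Intercept)` = 1, x = d$x)
#' C <- tree_covariance(five_taxon_tree())
#' fit <- fit_gee(d$y, X, C, gee_family("poisson"))
#' coef(fit)
#' @export
fit_gee <- function(Y, X, C, family, beta_init = NULL,
                    working_var = c("family", "mean"),
                    control = gee_control()) {
  working_var <- match.arg(working_var)
  check_gee_inputs(Y, X, C)
  fam <- family
  if (!inherits(fam, "gee_family")) {
    stop("`family` must be a gee_family() object.", call. = FALSE)
  }
  if (is.null(beta_init)) beta_init <- gee_init(Y, X, fam)
  beta <- as.numeric(beta_init)
  if (length(beta) != ncol(X)) {
    stop("`beta_init` must have one entry per column of `X`.", call. = FALSE)
  }

  cf <- cov_factor(C, control$svd_tol)
  parts <- gee_parts(beta, Y, X, C, fam, control$svd_tol, working_var, cf = cf)
  if (!parts$valid) {
    stop("Initial coefficients are outside the family domain; supply `beta_init`.",
      call. = FALSE
    )
  }
  converged <- FALSE
  iter <- 0L
  repeat {
    score <- parts$score
    J <- parts$J
    z <- abs(score) / sqrt(pmax(diag(J), .Machine$double.eps))
    if (max(abs(score)) < control$score_tol || max(z) < control$score_tol) {
      converged <- TRUE
      break
    }
    if (iter >= control$max_iter) break
    iter <- iter + 1L
    old_norm <- sqrt(sum(score^2))
    try_direction <- function(delta) {
      # step halving on the euclidean norm of the score
      step <- 1
      for (h in seq_len(control$max_halvings + 1L)) {
        cand <- beta + step * delta
        cand_parts <- gee_parts(cand, Y, X, C, fam, control$svd_tol, working_var,
          cf = cf
        )
        if (cand_parts$valid && sqrt(sum(cand_parts$score^2)) < old_norm) {
          return(list(beta = cand, parts = cand_parts, size = max(abs(step * delta))))
        }
        step <- step / 2
      }
      NULL
    }
    rel_size <- function(res) {
      if (is.null(res)) 0 else res$size / (1 + max(abs(beta)))
    }
    delta_fisher <- tryCatch(
      solve(J, score),
      error = function(e) drop(MASS::ginv(J) %*% score)
    )
    res <- try_direction(delta_fisher)
    if (rel_size(res) < control$rel_tol) {
      # Fisher scoring drops the dW/dbeta part of the Jacobian and stalls a
      # hair short of the root; polish with a finite-difference Newton step
      Jfd <- fd_jacobian(beta, Y, X, C, fam, control$svd_tol, working_var, cf)
      if (!is.null(Jfd)) {
        delta_fd <- tryCatch(
          solve(Jfd, score),
          error = function(e) drop(MASS::ginv(Jfd) %*% score)
        )
        res_fd <- try_direction(delta_fd)
        if (rel_size(res_fd) > rel_size(res)) res <- res_fd
      }
    }
    if (is.null(res)) {
      # no direction makes progress: at the root to achievable precision or
      # genuinely stuck; decide by the standardized score
      converged <- max(z) < 1e-4
      break
    }
    stalled <- rel_size(res) < control$rel_tol
    beta <- res$beta
    parts <- res$parts
    if (stalled) {
      z <- abs(parts$score) / sqrt(pmax(diag(parts$J), .Machine$double.eps))
      converged <- max(abs(parts$score)) < control$score_tol || max(z) < 1e-4
      break
    }
  }

  nm <- colnames(X) %||% paste0("b", seq_len(ncol(X)) - 1L)
  sfin <- sqrt(parts$v)
  W <- sfin * C * rep(sfin, each = length(sfin))
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  working_cond <- max(ev) / max(min(ev), control$svd_tol * max(ev))
  structure(
    list(
      beta = setNames(beta, nm),
      family = fam,
      fitted = parts$mu,
      converged = converged,
      iterations = iter,
      score = parts$score,
      score_norm = max(abs(parts$score)),
      working_cond = working_cond,
      working_rank_deficient = parts$rank_deficient,
      working_var = working_var,
      n = length(Y), p = ncol(X) - 1L,
      Y = Y, X = X, C = C,
      control = control
    ),
    class = "phylo_gee"
  )
}

# central-difference Jacobian of the estimating function (negated so that
# solve(J, score) is a descent step like the Fisher one); NULL if any
# perturbed point is invalid
fd_jacobian <- function(beta, Y, X, C, fam, svd_tol, working_var, cf = NULL) {
  p1 <- length(beta)
  J <- matrix(NA_real_, p1, p1)
  for (j in seq_len(p1)) {
    h <- 1e-6 * (1 + abs(beta[j]))
    up <- dn <- beta
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    pu <- gee_parts(up, Y, X, C, fam, svd_tol, working_var, cf)
    pd <- gee_parts(dn, Y, X, C, fam, svd_tol, working_var, cf)
    if (!pu$valid || !pd$valid) {
      return(NULL)
    }
    J[, j] <- (pd$score - pu$score) / (2 * h)
  }
  J
}

# independent-GLM starting values for the GEE
gee_init <- function(Y, X, fam) {
  if (all(Y == 0)) {
    stop("Response is identically zero; the count MLE is divergent.", call. = FALSE)
  }
  g0 <- suppressWarnings(stats::glm.fit(X, Y, family = stats::poisson()))
  if (fam$family == "poisson" || fam$link == "log") {
    if (fam$family == "nb2") {
      g1 <- tryCatch(
        suppressWarnings(
          stats::glm.fit(X, Y, family = MASS::negative.binomial(theta = fam$r))
        ),
        error = function(e) NULL
      )
      if (!is.null(g1)) {
        return(coef(g1))
      }
    }
    return(coef(g0))
  }
  # canonical NB link: map the Poisson fitted means through the link
  mu0 <- pmax(g0$fitted.values, 1e-8)
  eta0 <- fam$linkfun(mu0)
  drop(qr.solve(X, eta0))
}

#' Phylogenetic Poisson / negative binomial regression
#'
#' Data-frame-first interface to the phylogenetic count GEE. The trait table
#' is aligned to the tree tips by species label, the shared-branch-length
#' matrix C is computed from the tree, and the estimating equations with
#' working covariance `S^{1/2} C S^{1/2}` are solved for the coefficients.
#' With a star tree (C proportional to the identity) the estimates coincide
#' with the independent GLM.
#'
#' @param data A data frame with one row per species: a species-label column,
#'   the count response and the covariates.
#' @param formula Model formula, e.g. `y ~ x`.
#' @param tree An [ape] `phylo` whose tip labels match the label column.
#' @param family `"poisson"` or `"nb2"`.
#' @param link `"log"` or `"canonical"` (NB2 only; Poisson always log).
#' @param r NB2 dispersion. When `NULL` it is estimated once by the
#'   independent NB2 MLE ([MASS::glm.nb()]) and then held fixed in the GEE
#'   (reported via a message).
#' @param label Name of the species-label column; defaults to the first
#'   character column.
#' @param working_var,control Passed to [fit_gee()].
#' @return A `phylo_gee` fit (see [fit_gee()]) with `labels` and `call`
#'   attached. Use [tidy()] / [glance()] / [fitted()] on it.
#' @examples
#' fit <- phylo_glm(toy_count_data(), y ~ x, five_taxon_tree(), family = "poisson")
#' tidy(fit)
#' @export
phylo_glm <- function(data, formula, tree, family = c("poisson", "nb2"),
                      link = c("log", "canonical"), r = NULL, label = NULL,
                      working_var = c("family", "mean"),
                      control = gee_control()) {
  family <- match.arg(family)
  link <- match.arg(link)
  working_var <- match.arg(working_var)
  al <- align_data(data, tree, formula = formula, label = label)
  if (family == "nb2" && is.null(r)) {
    r <- estimate_nb2_dispersion(al$Y, al$X)
    message(sprintf(
      "NB2 dispersion r not supplied; using the independent MLE r = %.4g (held fixed in the GEE).",
      r
    ))
  }
  fam <- gee_family(family, link = link, r = r)
  fit <- fit_gee(al$Y, al$X, al$C, fam,
    working_var = working_var, control = control
  )
  fit$labels <- al$labels
  fit$dropped <- al$dropped
  fit$call <- match.call()
  if (!fit$converged) {
    warning("GEE did not converge; inspect score_norm and iterations.", call. = FALSE)
  }
  fit
}

estimate_nb2_dispersion <- function(Y, X, r_max = 1e6, r_min = 1e-3) {
  g <- tryCatch(
    suppressWarnings(MASS::glm.nb(Y ~ X - 1)),
    error = function(e) NULL
  )
  th <- if (is.null(g)) r_max else g$theta
  min(max(th, r_min), r_max)
}

#' Fitted means from a GEE fit
#'
#' Applies the inverse link of the fit's family to `X %*% beta`: `exp(eta)`
#' for the log link and `r e^eta / (1 - e^eta)` for the canonical NB2 link.
#'
#' @param fit A `phylo_gee` object.
#' @param X Optional design matrix; defaults to the one used in fitting.
#' @return Vector of positive fitted means.
#' @export
fitted_values <- function(fit, X = NULL) {
  stopifnot(inherits(fit, "phylo_gee"))
  if (is.null(X)) {
    return(fit$fitted)
  }
  eta <- drop(X %*% fit$beta)
  check_domain(fit$family, eta, labels = rownames(X))
  fit$family$linkinv(eta)
}

#' @export
fitted.phylo_gee <- function(object, ...) object$fitted

#' @export
coef.phylo_gee <- function(object, ...) object$beta

#' @export
print.phylo_gee <- function(x, ...) {
  cat(sprintf(
    "<phylo_gee> %s (%s link%s), n = %d\n", x$family$family, x$family$link,
    if (is.null(x$family$r)) "" else sprintf(", r = %g", x$family$r), x$n
  ))
  print(round(x$beta, 6))
  cat(sprintf(
    "converged: %s after %d iterations (max |score| = %.3g, cond(W) = %.3g)\n",
    x$converged, x$iterations, x$score_norm, x$working_cond
  ))
  invisible(x)
}

#' @method tidy phylo_gee
#' @export
tidy.phylo_gee <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' @method glance phylo_gee
#' @export
glance.phylo_gee <- function(x, ...) {
  tibble::tibble(
    family = x$family$family, link = x$family$link,
    r = x$family$r %||% NA_real_,
    n = x$n, converged = x$converged, iterations = x$iterations,
    score_norm = x$score_norm, working_cond = x$working_cond
  )
}
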