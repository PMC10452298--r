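#' Log probability mass functions for the two count families
#'
#' `poisson_logpmf(y, lambda)` is `log(exp(-lambda) lambda^y / y!)`;
#' `nb2_logpmf(y, r, p)` is `log(C(y + r - 1, y) p^r (1 - p)^y)` with the
#' generalized binomial coefficient (real-valued `r` allowed), support
#' `y = 0, 1, 2, ...`. Both are evaluated stably through log-gamma (via the
#' standard distribution functions). The NB2 mean is `mu = r (1 - p) / p` and
#' the variance `mu + mu^2 / r`.
#'
#' @param y Nonnegative integer count(s).
#' @param lambda Positive Poisson mean.
#' @param r Positive NB2 dispersion (number of successes).
#' @param p Success probability in (0, 1).
#' @return Log pmf value(s).
#' @examples
#' poisson_logpmf(0, 2) # -2
#' nb2_logpmf(0, r = 5, p = 0.5) # 5 * log(0.5)
#' @export
poisson_logpmf <- function(y, lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("`lambda` must be positive.", call. = FALSE)
  }
  if (any(y < 0) || any(y != round(y))) {
    stop("`y` must be nonnegative integer.", call. = FALSE)
  }
  dpois(y, lambda, log = TRUE)
}

#' @rdname poisson_logpmf
#' @export
nb2_logpmf <- function(y, r, p) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("`r` must be positive.", call. = FALSE)
  }
  if (any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly in (0, 1).", call. = FALSE)
  }
  if (any(y < 0) || any(y != round(y))) {
    stop("`y` must be nonnegative integer.", call. = FALSE)
  }
  dnbinom(y, size = r, prob = p, log = TRUE)
}

#' Small-sample corrected AIC
#'
#' `AICc = (2k - 2 loglik) + 2k(k+1) / (n - k - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size; must exceed `k + 1`.
#' @return The AICc value.
#' @examples
#' aicc(loglik = -3, k = 2, n = 10)
#' @export
aicc <- function(loglik, k, n) {
  stopifnot(is.numeric(loglik), is.numeric(k), is.numeric(n))
  if (n <= k + 1) {
    stop("AICc requires n > k + 1.", call. = FALSE)
  }
  (2 * k - 2 * loglik) + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' Softmax of `-AICc/2` relative to the best model:
#' `w_i = exp(-d_i/2) / sum_j exp(-d_j/2)` with `d_i = AICc_i - min(AICc)`.
#' Invariant to adding a constant to every AICc.
#'
#' @param aiccs Numeric vector of AICc values.
#' @return Vector of weights summing to 1, names preserved.
#' @examples
#' akaike_weights(c(poisson = 116.81, nb2 = 116.43))
#' @export
akaike_weights <- function(aiccs) {
  if (length(aiccs) == 0 || any(!is.finite(aiccs))) {
    stop("`aiccs` must be a nonempty finite numeric vector.", call. = FALSE)
  }
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Independent Poisson / NB2 regression for count traits
#'
#' Maximum-likelihood count regression ignoring phylogeny: Poisson via
#' [stats::glm()] and NB2 via [MASS::glm.nb()] (or a fixed-dispersion fit via
#' [MASS::negative.binomial()] when `r` is supplied), both with the log link.
#' AICc is computed with the dispersion counted as a parameter for NB2
#' (`k = p + 2`) and not for Poisson (`k = p + 1`). When the data are
#' underdispersed the NB2 dispersion estimate diverges; it is capped at
#' `r_max` with a warning.
#'
#' @param data A data frame with the response and covariates.
#' @param formula Model formula, e.g. `y ~ x`.
#' @param family `"poisson"` or `"nb2"`.
#' @param r Optional fixed NB2 dispersion; when `NULL` it is estimated.
#' @param r_max Cap for a diverging dispersion estimate.
#' @return An object of class `count_glm`: list with `beta`, `r`, `loglik`,
#'   `k`, `n`, `aicc`, `converged`, `iterations`, `fitted`, and the underlying
#'   `glm` object in `$fit`.
#' @examples
#' fit <- count_glm(toy_count_data(), y ~ 1, family = "poisson")
#' coef(fit) # log of the mean count
#' @export
count_glm <- function(data, formula, family = c("poisson", "nb2"), r = NULL,
                      r_max = 1e6) {
  family <- match.arg(family)
  mf <- model.frame(formula, data = data)
  Y <- model.response(mf)
  if (any(Y < 0) || any(Y != round(Y))) {
    stop("Response must contain nonnegative integer counts.", call. = FALSE)
  }
  if (all(Y == 0)) {
    stop("Response is identically zero; the count MLE is divergent.", call. = FALSE)
  }
  X <- model.matrix(formula, data = data)
  n <- length(Y)
  p1 <- ncol(X)

  ctrl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
  if (family == "poisson") {
    g <- glm(formula, data = data, family = poisson(), control = ctrl)
    k <- p1
    r_hat <- NULL
  } else if (!is.null(r)) {
    g <- glm(formula,
      data = data, family = MASS::negative.binomial(theta = r), control = ctrl
    )
    k <- p1 + 1L
    r_hat <- r
  } else {
    g <- tryCatch(
      withCallingHandlers(
        MASS::glm.nb(formula, data = data, control = ctrl),
        warning = function(w) invokeRestart("muffleWarning")
      ),
      error = function(e) NULL # theta diverging on underdispersed data
    )
    r_hat <- if (is.null(g)) Inf else g$theta
    if (!is.finite(r_hat) || r_hat > r_max) {
      warning(sprintf(
        "NB2 dispersion estimate diverged (data look underdispersed); capped at r = %g.",
        r_max
      ), call. = FALSE)
      r_hat <- r_max
      g <- glm(formula,
        data = data, family = MASS::negative.binomial(theta = r_hat),
        control = ctrl
      )
    }
    k <- p1 + 1L
  }

  ll <- count_loglik(Y, g$fitted.values, family, r_hat)
  structure(
    list(
      family = family,
      beta = coef(g),
      r = r_hat,
      loglik = ll,
      k = k, n = n, p = p1 - 1L,
      aicc = aicc(ll, k, n),
      converged = isTRUE(g$converged) || is.null(g$converged),
      iterations = g$iter %||% NA_integer_,
      fitted = unname(g$fitted.values),
      Y = unname(Y), X = X,
      formula = formula,
      fit = g
    ),
    class = "count_glm"
  )
}

# exact log-likelihood at the fitted means (Poisson; NB2 with dispersion r)
count_loglik <- function(Y, mu, family, r = NULL) {
  if (family == "poisson") {
    sum(dpois(Y, lambda = mu, log = TRUE))
  } else {
    sum(dnbinom(Y, size = r, mu = mu, log = TRUE))
  }
}

#' @export
coef.count_glm <- function(object, ...) object$beta

#' @export
fitted.count_glm <- function(object, ...) object$fitted

#' @export
logLik.count_glm <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
print.count_glm <- function(x, ...) {
  cat(sprintf(
    "<count_glm> %s (log link%s), n = %d\n", x$family,
    if (is.null(x$r)) "" else sprintf(", r = %.4g", x$r), x$n
  ))
  print(round(x$beta, 6))
  cat(sprintf("logLik = %.4f, AICc = %.4f\n", x$loglik, x$aicc))
  invisible(x)
}

#' @method tidy count_glm
#' @export
tidy.count_glm <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' @method glance count_glm
#' @export
glance.count_glm <- function(x, ...) {
  tibble::tibble(
    family = x$family, r = x$r %||% NA_real_, n = x$n, k = x$k,
    logLik = x$loglik, AICc = x$aicc, converged = x$converged
  )
}

#' Compare Poisson and NB2 fits by AICc
#'
#' Fits both independent count models to the same data and reports summary
#' statistics of the response together with AICc and Akaike weights, one row
#' per family.
#'
#' @inheritParams count_glm
#' @return A tibble with columns `family`, `n`, `mean_y`, `var_y`, `k`,
#'   `logLik`, `AICc`, `weight`.
#' @examples
#' compare_count_models(toy_count_data(), y ~ x)
#' @export
compare_count_models <- function(data, formula, r = NULL, r_max = 1e6) {
  fits <- list(
    poisson = count_glm(data, formula, family = "poisson"),
    nb2 = count_glm(data, formula, family = "nb2", r = r, r_max = r_max)
  )
  Y <- fits$poisson$Y
  out <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      family = f$family, n = f$n, mean_y = mean(Y), var_y = var(Y),
      k = f$k, logLik = f$loglik, AICc = f$aicc
    )
  })
  out$weight <- akaike_weights(out$AICc)
  out
}
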