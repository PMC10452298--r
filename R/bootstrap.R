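#' Parametric bootstrap for count-regression fits
#'
#' Simulates `B` new response vectors from the fitted model — at the fitted
#' means, through the Gaussian-copula sampler with the tree covariance C for
#' phylogenetic fits, or independently (C = identity) for GLM fits — refits
#' the same estimator on each, and summarizes the replicate coefficients:
#' bootstrap mean, SD and percentile confidence intervals. A parametric
#' scheme is used rather than case resampling because tips are not
#' exchangeable under phylogenetic dependence: resampling rows would destroy
#' the covariance structure encoded in C.
#'
#' Replicates whose refit fails or does not converge are dropped from the
#' summaries and counted in `n_failed`, never imputed.
#'
#' @param fit A `count_glm` or `phylo_gee` fit.
#' @param B Number of bootstrap replicates (>= 1).
#' @param level Confidence level for the percentile intervals.
#' @param seed Optional integer; the whole bootstrap is reproducible from it.
#' @param ... Unused.
#' @return An object of class `count_boot`: list with `estimates` (B x
#'   coefficients matrix, failed rows `NA`), `mean`, `sd`, `ci` (2 x
#'   coefficients), `n_failed`, `B`, `level`. [tidy()] returns one row per
#'   coefficient.
#' @examples
#' fit <- count_glm(toy_count_data(), y ~ 1, family = "poisson")
#' tidy(parametric_bootstrap(fit, B = 50, seed = 1))
#' @export
parametric_bootstrap <- function(fit, B = 1000L, level = 0.95, seed = NULL, ...) {
  UseMethod("parametric_bootstrap")
}

boot_engine <- function(terms, B, level, simulate_y, refit) {
  stopifnot(B >= 1, level > 0, level < 1)
  est <- matrix(NA_real_, nrow = B, ncol = length(terms),
    dimnames = list(NULL, terms)
  )
  for (b in seq_len(B)) {
    ystar <- simulate_y()
    cand <- tryCatch(refit(ystar), error = function(e) NULL)
    if (!is.null(cand)) est[b, ] <- cand
  }
  ok <- stats::complete.cases(est)
  if (!any(ok)) {
    stop("All bootstrap replicates failed to refit.", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  structure(
    list(
      estimates = est,
      mean = colMeans(est[ok, , drop = FALSE]),
      sd = apply(est[ok, , drop = FALSE], 2, sd),
      ci = apply(est[ok, , drop = FALSE], 2, quantile,
        probs = c(alpha, 1 - alpha)
      ),
      n_failed = sum(!ok), B = B, level = level
    ),
    class = "count_boot"
  )
}

#' @rdname parametric_bootstrap
#' @export
parametric_bootstrap.count_glm <- function(fit, B = 1000L, level = 0.95,
                                           seed = NULL, ...) {
  mu <- fit$fitted
  X <- fit$X
  simulate_y <- if (fit$family == "poisson") {
    function() rpois(length(mu), lambda = mu)
  } else {
    function() rnbinom(length(mu), size = fit$r, mu = mu)
  }
  refit <- function(ystar) {
    if (all(ystar == 0)) {
      return(NULL)
    }
    fam <- if (fit$family == "poisson") {
      poisson()
    } else {
      MASS::negative.binomial(theta = fit$r)
    }
    g <- suppressWarnings(stats::glm.fit(X, ystar, family = fam))
    if (!g$converged) {
      return(NULL)
    }
    coef(g)
  }
  run <- function() boot_engine(names(fit$beta), B, level, simulate_y, refit)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @rdname parametric_bootstrap
#' @export
parametric_bootstrap.phylo_gee <- function(fit, B = 1000L, level = 0.95,
                                           seed = NULL, ...) {
  mu <- fit$fitted
  simulate_y <- function() {
    unname(rcount_copula(mu, fit$C, fit$family))
  }
  refit <- function(ystar) {
    g <- fit_gee(ystar, fit$X, fit$C, fit$family,
      working_var = fit$working_var, control = fit$control
    )
    if (!g$converged) {
      return(NULL)
    }
    g$beta
  }
  run <- function() boot_engine(names(fit$beta), B, level, simulate_y, refit)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.count_boot <- function(x, ...) {
  cat(sprintf(
    "<count_boot> %d replicates (%d failed), %.0f%% percentile intervals\n",
    x$B, x$n_failed, 100 * x$level
  ))
  print(tidy(x))
  invisible(x)
}

#' @method tidy count_boot
#' @export
tidy.count_boot <- function(x, ...) {
  tibble::tibble(
    term = names(x$mean),
    estimate = unname(x$mean),
    std.error = unname(x$sd),
    conf.low = unname(x$ci[1, ]),
    conf.high = unname(x$ci[2, ])
  )
}

#' @method glance count_boot
#' @export
glance.count_boot <- function(x, ...) {
  tibble::tibble(B = x$B, n_failed = x$n_failed, level = x$level)
}
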