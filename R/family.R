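#' Mean/variance/link specification for the count GEE
#'
#' Bundles the link, mean, variance and mean-derivative functions used by the
#' estimating equations, for the two count families:
#' \describe{
#'   \item{Poisson, log link}{`mu = V = dmu/deta = exp(eta)`.}
#'   \item{NB2, log link}{`mu = exp(eta)`, `V = mu + mu^2/r`, `dmu/deta = mu`.}
#'   \item{NB2, canonical link}{`theta = log(mu/(mu+r))`, so
#'     `mu = r e^eta/(1-e^eta)` with domain `eta < 0`, and
#'     `dmu/deta = V = r e^eta/(1-e^eta)^2 = mu + mu^2/r`.}
#' }
#' The NB2 dispersion `r` is a fixed constant of the family here: the GEE
#' estimates the regression coefficients only, with `r` either user-supplied
#' or taken from an independent NB2 maximum-likelihood fit.
#'
#' @param family `"poisson"` or `"nb2"`.
#' @param link `"log"` or `"canonical"`. For Poisson the canonical link *is*
#'   the log link; for NB2 they differ.
#' @param r Positive dispersion parameter (NB2 only); variance is
#'   `mu + mu^2/r`.
#' @return An object of class `gee_family`: a list with elements `family`,
#'   `link`, `r`, and functions `linkinv(eta)`, `mu_eta(eta)` (the derivative
#'   d mu / d eta), `variance(mu)`, `linkfun(mu)` and `in_domain(eta)`.
#' @examples
#' fam <- gee_family("nb2", link = "canonical", r = 10.68)
#' fam$linkinv(-1) # mean at eta = -1
#' @export
gee_family <- function(family = c("poisson", "nb2"),
                       link = c("log", "canonical"),
                       r = NULL) {
  family <- match.arg(family)
  link <- match.arg(link)
  if (family == "poisson") {
    link <- "log" # canonical link of the Poisson is the log
    spec <- list(
      family = family, link = link, r = NULL,
      linkfun = function(mu) log(mu),
      linkinv = function(eta) exp(eta),
      mu_eta = function(eta) exp(eta),
      variance = function(mu) mu,
      in_domain = function(eta) rep(TRUE, length(eta))
    )
  } else {
    if (is.null(r) || !is.numeric(r) || length(r) != 1L || r <= 0) {
      stop("NB2 families need a single positive dispersion `r`.", call. = FALSE)
    }
    spec <- if (link == "log") {
      list(
        family = family, link = link, r = r,
        linkfun = function(mu) log(mu),
        linkinv = function(eta) exp(eta),
        mu_eta = function(eta) exp(eta),
        variance = function(mu) mu + mu^2 / r,
        in_domain = function(eta) rep(TRUE, length(eta))
      )
    } else {
      list(
        family = family, link = link, r = r,
        linkfun = function(mu) log(mu / (mu + r)),
        linkinv = function(eta) r * exp(eta) / (1 - exp(eta)),
        mu_eta = function(eta) r * exp(eta) / (1 - exp(eta))^2,
        variance = function(mu) mu + mu^2 / r,
        in_domain = function(eta) eta < 0
      )
    }
  }
  structure(spec, class = "gee_family")
}

#' @export
print.gee_family <- function(x, ...) {
  cat(sprintf(
    "<gee_family> %s, %s link%s\n", x$family, x$link,
    if (is.null(x$r)) "" else sprintf(", r = %g", x$r)
  ))
  invisible(x)
}

check_domain <- function(fam, eta, labels = NULL) {
  ok <- fam$in_domain(eta)
  if (!all(ok)) {
    bad <- which(!ok)
    who <- if (is.null(labels)) paste0("#", bad) else labels[bad]
    stop(sprintf(
      "Linear predictor outside the %s/%s domain (eta must be < 0) for: %s.",
      fam$family, fam$link, paste(who, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}
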