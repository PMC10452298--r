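# Shared fixtures and independent oracles for the test suite.

# The five-taxon shared-branch-length matrix, written out by hand in the
# tip order x, y, z, u, v.
five_taxon_matrix <- function() {
  m <- matrix(
    c(
      560, 0, 0, 0, 0,
      0, 560, 459, 217, 20,
      0, 459, 560, 217, 20,
      0, 217, 217, 560, 20,
      0, 20, 20, 20, 560
    ),
    nrow = 5, byrow = TRUE,
    dimnames = list(c("x", "y", "z", "u", "v"), c("x", "y", "z", "u", "v"))
  )
  m
}

# Independent star-tree dataset with Poisson or NB2 counts at modest means.
make_star_data <- function(n = 20, beta = c(1, 0.5), family = "poisson",
                           r = 5) {
  tree <- generate_tree("star", n)
  x <- rnorm(n)
  mu <- exp(beta[1] + beta[2] * x)
  y <- if (family == "poisson") rpois(n, mu) else rnbinom(n, size = r, mu = mu)
  list(
    tree = tree,
    data = tibble::tibble(species = tree$tip.label, y = y, x = x)
  )
}

# Brute-force root of the GEE estimating function for p = 1: profile the
# intercept out by bisection of the first score component along a grid, then
# bisect the profiled second component. Independent of the package's Newton
# solver; shares only the score function whose root is being located.
oracle_gee_root <- function(Y, X, C, fam,
                            b0_rng = c(-6, 8), b1_rng = c(-6, 8),
                            grid = 81, iters = 60) {
  s_fun <- function(b) gee_score(b, Y, X, C, fam)
  bisect <- function(f, lo, hi) {
    flo <- f(lo)
    for (k in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (flo * f(mid) <= 0) hi <- mid else {
        lo <- mid
        flo <- f(lo)
      }
    }
    (lo + hi) / 2
  }
  first_bracket <- function(v, g) {
    sgn <- v[-1] * v[-length(v)]
    i <- which(is.finite(sgn) & sgn <= 0)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  b0_of_b1 <- function(b1) {
    f <- function(b0) s_fun(c(b0, b1))[1]
    g <- seq(b0_rng[1], b0_rng[2], length.out = grid)
    v <- vapply(g, f, numeric(1))
    i <- first_bracket(v, g)
    if (is.na(i)) {
      return(NA_real_)
    }
    bisect(f, g[i], g[i + 1])
  }
  prof <- function(b1) {
    b0 <- b0_of_b1(b1)
    if (is.na(b0)) {
      return(NA_real_)
    }
    s_fun(c(b0, b1))[2]
  }
  g1 <- seq(b1_rng[1], b1_rng[2], length.out = grid)
  v1 <- vapply(g1, prof, numeric(1))
  sgn <- v1[-1] * v1[-length(v1)]
  brackets <- which(is.finite(sgn) & sgn <= 0)
  roots <- list()
  for (i in brackets) {
    b1 <- bisect(prof, g1[i], g1[i + 1])
    b0 <- b0_of_b1(b1)
    if (is.na(b0)) next
    cand <- c(b0, b1)
    # keep genuine roots only (profile jumps can fake a sign change)
    if (max(abs(s_fun(cand))) < 1e-3 * (1 + max(abs(Y)))) {
      roots[[length(roots) + 1]] <- cand
    }
  }
  if (length(roots) == 0) {
    return(NULL)
  }
  roots
}

# distance from a solver root to the nearest oracle root
oracle_distance <- function(beta, roots) {
  min(vapply(roots, function(r) max(abs(beta - r)), numeric(1)))
}

# Synthetic stand-in for the published lizard life-history table (17 taxa,
# eggs-per-year response, egg-mass covariate). The original appendix table is
# not redistributable here; this synthetic version only exercises the same
# code paths and does NOT reproduce the published statistics.
synthetic_lizard_data <- function(seed = 402) {
  withr::with_seed(seed, {
    n <- 17
    em <- round(runif(n, 0.2, 0.65), 2)
    mu <- exp(3.6 - 1.5 * em)
    tibble::tibble(
      species = paste0("pop", seq_len(n)),
      EPY = rnbinom(n, size = 12, mu = mu),
      EM = em
    )
  })
}
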