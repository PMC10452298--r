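#' Parse a Newick string into a phylogenetic tree
#'
#' Thin, strict wrapper around [ape::read.tree()]. Branch lengths are required
#' on every edge (the downstream covariance matrix is undefined without them),
#' tip labels must be unique, and malformed input raises an informative error
#' instead of returning a half-parsed tree. Internal node labels are tolerated
#' and ignored.
#'
#' @param text A single Newick string (trailing whitespace tolerated).
#' @return An [ape] `phylo` object, rooted, with `edge.length` set.
#' @examples
#' tr <- parse_newick("(a:1,b:1);")
#' tree_height(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single Newick string.", call. = FALSE)
  }
  txt <- trimws(text)
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    stop(sprintf(
      "Malformed Newick: %d '(' vs %d ')' (unbalanced parentheses).",
      n_open, n_close
    ), call. = FALSE)
  }
  if (!grepl(";\\s*$", txt)) {
    stop("Malformed Newick: missing terminating ';'.", call. = FALSE)
  }
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = txt)),
    error = function(e) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("Malformed Newick: ape could not parse the string.", call. = FALSE)
  }
  validate_tree(tree)
  tree
}

#' Read / write Newick files
#'
#' @param path File path.
#' @return `read_newick()` returns a `phylo`; `write_newick()` returns `path`
#'   invisibly.
#' @export
read_newick <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_tree <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop("Tree has no branch lengths; they are required.", call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    stop("Tree has missing branch lengths on some edges.", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("Tree has negative branch lengths.", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop(sprintf("Duplicate tip labels: %s.", paste(dup, collapse = ", ")),
      call. = FALSE
    )
  }
  if (length(tree$edge.length) != nrow(tree$edge)) {
    stop("Tree has branch lengths missing for some edges.", call. = FALSE)
  }
  invisible(tree)
}

#' Shared-branch-length covariance matrix of a tree
#'
#' Converts a rooted tree with branch lengths into the n x n matrix C whose
#' entry c_ij is the total branch length shared by the root-to-tip paths of
#' tips i and j (the depth of their most recent common ancestor); the diagonal
#' c_ii is the root-to-tip depth of tip i. Under Brownian-motion trait
#' evolution C is the trait covariance up to the rate constant, and it is the
#' matrix embedded in the working covariance of the phylogenetic GEE.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A symmetric positive semi-definite numeric matrix with tip labels
#'   as `dimnames`.
#' @examples
#' C <- tree_covariance(five_taxon_tree())
#' C["y", "z"] # shared path length of tips y and z
#' @export
tree_covariance <- function(tree) {
  validate_tree(tree)
  C <- ape::vcv(tree)
  # vcv orders rows by tip.label order already
  C[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Tree height (maximum root-to-tip depth)
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A single nonnegative number.
#' @export
tree_height <- function(tree) {
  validate_tree(tree)
  max(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
}

#' Rescale a tree to a target height
#'
#' Multiplies every branch length by `target_height / tree_height(tree)`, so
#' the covariance matrix scales by the same factor. Simulation studies use
#' unit-height trees so that covariate and count scales are comparable across
#' tree shapes and sizes.
#'
#' @param tree A `phylo` object.
#' @param target_height Positive number; the new maximum root-to-tip depth.
#' @return The rescaled `phylo`.
#' @export
scale_tree <- function(tree, target_height = 1) {
  stopifnot(is.numeric(target_height), length(target_height) == 1L, target_height > 0)
  h <- tree_height(tree)
  if (h <= 0) {
    stop("Tree has zero height; cannot rescale.", call. = FALSE)
  }
  tree$edge.length <- tree$edge.length * (target_height / h)
  tree
}

#' Generate ultrametric trees of the four study shapes
#'
#' Generates a unit-height ultrametric tree of one of four shapes used in the
#' simulation study:
#' \describe{
#'   \item{`coalescent`}{Kingman-style random coalescent ([ape::rcoal()]),
#'     rescaled to unit height.}
#'   \item{`balanced`}{Fully balanced binary tree (`n` must be a power of 2)
#'     with split depths equally spaced across levels.}
#'   \item{`left`}{Pectinate (caterpillar) tree: each split separates a single
#'     tip; split depths equally spaced on `[0, 1)`.}
#'   \item{`star`}{All tips attached directly to the root; C is the identity
#'     after unit scaling.}
#' }
#'
#' @param kind One of `"coalescent"`, `"balanced"`, `"left"`, `"star"`.
#' @param n Number of tips (>= 2).
#' @param seed Optional integer; when supplied the coalescent draw is made
#'   reproducible via [withr::with_seed()]. Ignored by the deterministic
#'   shapes.
#' @return A unit-height `phylo` with tips `t1..tn`.
#' @examples
#' tr <- generate_tree("balanced", 8)
#' tree_height(tr)
#' @export
generate_tree <- function(kind = c("coalescent", "balanced", "left", "star"),
                          n, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(n), length(n) == 1L, n == round(n))
  if (n < 2) stop("Need at least 2 tips.", call. = FALSE)
  n <- as.integer(n)
  labs <- paste0("t", seq_len(n))
  tree <- switch(kind,
    coalescent = {
      draw <- function() ape::rcoal(n, tip.label = labs)
      if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    },
    balanced = {
      k <- log2(n)
      if (abs(k - round(k)) > 1e-9) {
        stop("Balanced trees require `n` to be a power of 2.", call. = FALSE)
      }
      parse_newick(paste0(balanced_newick(n, depth = 0, k = round(k)), ";"))
    },
    left = parse_newick(paste0(pectinate_newick(n), ";")),
    star = {
      nwk <- paste0("(", paste0(labs, ":1", collapse = ","), ");")
      parse_newick(nwk)
    }
  )
  if (kind %in% c("balanced", "left")) tree$tip.label <- labs[seq_len(n)]
  scale_tree(tree, 1)
}

# recursive newick for a balanced tree of n = 2^k tips; split depths at
# 0, 1/k, ..., (k-1)/k, tips at depth 1
balanced_newick <- function(n, depth, k, counter = new.env()) {
  if (is.null(counter$i)) counter$i <- 0L
  step <- 1 / k
  if (n == 1L) {
    counter$i <- counter$i + 1L
    return(sprintf("t%d:%.12f", counter$i, 1 - depth))
  }
  left <- balanced_newick(n / 2, depth + step, k, counter)
  right <- balanced_newick(n / 2, depth + step, k, counter)
  sprintf("(%s,%s):%.12f", left, right, if (depth == 0) 0 else step)
}

# caterpillar: splits at depths 0, 1/(n-1), ..., (n-2)/(n-1)
pectinate_newick <- function(n) {
  step <- 1 / (n - 1)
  # innermost cherry at depth (n-2)/(n-1): pendant length = step
  s <- sprintf("(t%d:%.12f,t%d:%.12f)", n - 1, step, n, step)
  depth_next <- (n - 2) / (n - 1)
  for (i in seq(n - 2, 1)) {
    # node for split i sits at depth (i-1)/(n-1)
    pend <- 1 - (i - 1) * step
    s <- sprintf("(t%d:%.12f,%s:%.12f)", i, pend, s, step)
  }
  s
}

#' The five-taxon example tree
#'
#' A small rooted ultrametric tree of five taxa (x, y, z, u, v) of height 560
#' whose shared-branch-length matrix is used throughout the documentation and
#' tests: diagonal 560, c(y,z) = 459, c(y,u) = c(z,u) = 217, c(v, y/z/u) = 20,
#' and x sharing no history with the rest.
#'
#' @return A `phylo` with 5 tips.
#' @examples
#' tree_covariance(five_taxon_tree())
#' @export
five_taxon_tree <- function() {
  parse_newick("(x:560,(v:540,(u:343,(y:101,z:101):242):197):20);")
}

#' Toy count dataset for the five-taxon tree
#'
#' Five species with a count response `y` and one quantitative covariate `x`,
#' aligned to [five_taxon_tree()] tip labels.
#'
#' @return A tibble with columns `species`, `y`, `x`.
#' @export
toy_count_data <- function() {
  tibble::tibble(
    species = c("x", "y", "z", "u", "v"),
    y = c(2L, 8L, 12L, 5L, 16L),
    x = c(23.4, 26.7, 24.5, 30.6, 32.5)
  )
}

#' Export a covariance matrix as labelled CSV
#'
#' @param C A labelled square matrix, as returned by [tree_covariance()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_covariance_csv <- function(C, path) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  utils::write.csv(as.data.frame(C), path, row.names = TRUE)
  invisible(path)
}
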