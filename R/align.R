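#' Align a trait table with a tree and build the regression inputs
#'
#' Intersects the species labels of a trait table with the tip labels of a
#' tree, drops (with a warning) species present in only one of the two, and
#' returns the response vector, design matrix and covariance matrix C jointly
#' reordered to a single canonical label order — preventing silent
#' misalignment between rows of the data and rows/columns of C. Rows with
#' missing values in the model variables are dropped listwise, by name.
#'
#' @param data Data frame with one row per species.
#' @param tree A `phylo` whose tip labels key the rows of `data`.
#' @param formula Model formula (response on the left); alternatively supply
#'   `response` and `covariates` column names.
#' @param response,covariates Column names used when `formula` is `NULL`.
#' @param label Name of the species-label column; defaults to the first
#'   character column of `data`.
#' @return A list with `labels`, `Y`, `X` (intercept column first), `C`,
#'   `data` (the aligned tibble) and `dropped` (labels excluded and why).
#' @examples
#' al <- align_data(toy_count_data(), five_taxon_tree(), y ~ x)
#' al$labels
#' @export
align_data <- function(data, tree, formula = NULL, response = NULL,
                       covariates = NULL, label = NULL) {
  stopifnot(is.data.frame(data))
  validate_tree(tree)
  if (is.null(formula)) {
    if (is.null(response)) {
      stop("Supply either `formula` or `response`.", call. = FALSE)
    }
    rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
    formula <- stats::as.formula(paste(response, "~", rhs))
  }
  if (is.null(label)) {
    is_chr <- vapply(data, is.character, logical(1)) |
      vapply(data, is.factor, logical(1))
    if (!any(is_chr)) {
      stop("No character column found to use as species labels; supply `label`.",
        call. = FALSE
      )
    }
    label <- names(data)[which(is_chr)[1]]
  }
  labs_data <- as.character(data[[label]])
  if (anyDuplicated(labs_data)) {
    stop("Duplicate species labels in `data`.", call. = FALSE)
  }
  shared <- intersect(tree$tip.label, labs_data)
  dropped <- list(
    from_tree = setdiff(tree$tip.label, shared),
    from_data = setdiff(labs_data, shared)
  )
  if (length(shared) < 2) {
    stop("Fewer than 2 species shared between tree and data.", call. = FALSE)
  }
  if (length(dropped$from_tree) || length(dropped$from_data)) {
    warning(sprintf(
      "Dropped %d tree tip(s) [%s] and %d data row(s) [%s] not shared.",
      length(dropped$from_tree), paste(dropped$from_tree, collapse = ", "),
      length(dropped$from_data), paste(dropped$from_data, collapse = ", ")
    ), call. = FALSE)
  }

  dat <- tibble::as_tibble(data)[match(shared, labs_data), , drop = FALSE]
  vars <- all.vars(formula)
  complete <- stats::complete.cases(dat[, intersect(vars, names(dat)), drop = FALSE])
  if (!all(complete)) {
    warning(sprintf(
      "Dropped %d species with missing model variables: %s.",
      sum(!complete), paste(shared[!complete], collapse = ", ")
    ), call. = FALSE)
    dat <- dat[complete, , drop = FALSE]
    shared <- shared[complete]
    dropped$incomplete <- setdiff(shared, shared[complete])
  }
  if (nrow(dat) < 2) {
    stop("Fewer than 2 complete-case species remain.", call. = FALSE)
  }

  mf <- model.frame(formula, data = dat)
  Y <- model.response(mf)
  if (any(Y != round(Y))) {
    bad <- shared[Y != round(Y)]
    stop(sprintf(
      "Response is not integer-valued for: %s.", paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  if (any(Y < 0)) {
    stop("Response contains negative counts.", call. = FALSE)
  }
  X <- model.matrix(formula, data = dat)
  rownames(X) <- shared
  keep <- ape::keep.tip(tree, shared)
  C <- tree_covariance(keep)[shared, shared, drop = FALSE]

  list(
    labels = shared, Y = as.integer(round(Y)), X = X, C = C,
    data = dat, dropped = dropped, formula = formula, label = label
  )
}
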