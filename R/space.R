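# Factor sample spaces, regions and observation sets.
#
# A factor space is the product of p unordered categorical variables; a
# region is a product of non-empty category subsets; observations are
# (optionally weighted) rows of category indices.  The storage order of
# categories carries no meaning: every downstream computation depends on
# labels only through marginal counts.

#' Define a factor sample space
#'
#' A factor space is the cartesian product of `p` unordered categorical
#' variables. Category order is storage order only and carries no semantics.
#'
#' @param variables Character vector of variable names (length `p >= 1`).
#' @param categories List of character vectors, one per variable, giving the
#'   category labels (each of length `m_i >= 1`, unique within a variable).
#' @return An object of class `"factor_space"` with elements `variables` and
#'   `categories`.
#' @examples
#' factor_space(c("dx1", "dx2"), list(c("a", "b"), c("x", "y", "z")))
#' @export
factor_space <- function(variables, categories) {
  variables <- as.character(variables)
  if (length(variables) < 1L) stop("need at least one variable")
  if (!is.list(categories) || length(categories) != length(variables))
    stop("'categories' must be a list with one entry per variable")
  categories <- lapply(categories, as.character)
  for (i in seq_along(categories)) {
    if (length(categories[[i]]) < 1L)
      stop("variable '", variables[i], "' has no categories")
    if (anyDuplicated(categories[[i]]))
      stop("duplicate category labels for variable '", variables[i], "'")
  }
  names(categories) <- variables
  structure(list(variables = variables, categories = categories),
            class = "factor_space")
}

#' @export
print.factor_space <- function(x, ...) {
  m <- space_sizes(x)
  cat("Factor space:", length(x$variables), "variable(s),",
      format(prod(m), big.mark = ","), "combination cells\n")
  for (i in seq_along(x$variables))
    cat("  ", x$variables[i], ": ", m[i], " categories\n", sep = "")
  invisible(x)
}

#' Per-variable category counts of a factor space
#'
#' @param space A [factor_space()].
#' @return Integer vector `m` of length `p`.
#' @export
space_sizes <- function(space) {
  lengths(space$categories)
}

#' Encode an observation table over a factor space
#'
#' Builds a factor space from the labels observed in `data` (optionally
#' extended by `categories`) and encodes the rows as category indices. A
#' column named `count` (or the one named by `count_col`) is interpreted as a
#' per-row multiplicity/weight; all other columns are treated as opaque
#' category labels.
#'
#' @param data Non-empty data frame, one row per observation (or per weighted
#'   row), one column per variable.
#' @param categories Optional named or positional list of per-variable label
#'   vectors. When given, every observed label must be listed and the space
#'   uses exactly these labels in this order.
#' @param count_col Name of the weight column; default `"count"`. Ignored if
#'   no such column exists.
#' @return An object of class `"observation_set"`: a list with `space`
#'   ([factor_space()]), `x` (integer matrix of category indices, `n` by `p`)
#'   and `w` (numeric non-negative weights).
#' @examples
#' d <- data.frame(a = c("u", "u", "v"), b = c("x", "y", "x"))
#' obs <- observations(d)
#' region_sample_count(whole_region(obs$space), obs)
#' @export
observations <- function(data, categories = NULL, count_col = "count") {
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("'data' is empty")
  w <- rep(1, nrow(data))
  if (count_col %in% names(data)) {
    w <- data[[count_col]]
    if (!is.numeric(w) || anyNA(w) || any(w < 0))
      stop("'", count_col, "' column must be non-negative numeric")
    w <- as.numeric(w)
    data <- data[setdiff(names(data), count_col)]
  }
  if (ncol(data) < 1L) stop("no variable columns in 'data'")
  vars <- names(data)
  cols <- lapply(data, as.character)
  if (anyNA(data, recursive = TRUE) || any(vapply(cols, anyNA, logical(1))))
    stop("missing values are not supported")
  if (!is.null(categories)) {
    if (is.null(names(categories))) names(categories) <- vars
    if (!all(vars %in% names(categories)))
      stop("'categories' must cover every variable column")
    cats <- lapply(vars, function(v) as.character(categories[[v]]))
  } else {
    cats <- lapply(cols, function(v) sort(unique(v)))
  }
  space <- factor_space(vars, cats)
  x <- matrix(0L, nrow(data), length(vars))
  for (i in seq_along(vars)) {
    idx <- match(cols[[i]], cats[[i]])
    if (anyNA(idx))
      stop("label(s) ", paste(unique(cols[[i]][is.na(idx)]), collapse = ", "),
           " of variable '", vars[i], "' not among the declared categories")
    x[, i] <- idx
  }
  new_observations(space, x, w)
}

# internal constructor: already-encoded index matrix
new_observations <- function(space, x, w = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (is.null(w)) w <- rep(1, nrow(x))
  m <- space_sizes(space)
  if (ncol(x) != length(m)) stop("column count does not match the space")
  for (i in seq_len(ncol(x)))
    if (nrow(x) && (min(x[, i]) < 1L || max(x[, i]) > m[i]))
      stop("category index out of range for variable ", space$variables[i])
  structure(list(space = space, x = x, w = as.numeric(w)),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat("Observation set: ", nrow(x$x), " row(s), total weight ",
      format(sum(x$w)), "\n", sep = "")
  print(x$space)
  invisible(x)
}

#' Whole-space region
#'
#' @param space A [factor_space()].
#' @return A region: a list of integer index vectors, one full sequence per
#'   variable. Regions are plain lists of (non-empty) category-index vectors
#'   relative to a factor space.
#' @export
whole_region <- function(space) {
  lapply(space_sizes(space), seq_len)
}

check_region <- function(A, space) {
  m <- space_sizes(space)
  if (!is.list(A) || length(A) != length(m)) stop("malformed region")
  for (i in seq_along(A)) {
    a <- A[[i]]
    if (length(a) < 1L || anyDuplicated(a) || min(a) < 1L || max(a) > m[i])
      stop("invalid category subset for variable ", space$variables[i])
  }
  invisible(A)
}

#' Number of combination cells in a region
#'
#' @param A Region (list of per-variable category index vectors).
#' @return `C(A)`, the product of subset sizes (a double, since cell counts
#'   overflow integers quickly).
#' @export
region_cell_count <- function(A) {
  prod(lengths(A))
}

# logical row filter: which observation rows fall inside A
rows_in_region <- function(obs, A) {
  keep <- rep(TRUE, nrow(obs$x))
  m <- space_sizes(obs$space)
  for (i in seq_along(A)) {
    if (length(A[[i]]) == m[i]) next
    mask <- logical(m[i])
    mask[A[[i]]] <- TRUE
    keep <- keep & mask[obs$x[, i]]
  }
  keep
}

#' Total observation weight inside a region
#'
#' @param A Region.
#' @param obs An [observations()] set over the same space.
#' @return `N(A)`, the summed weight of rows whose every coordinate lies in
#'   the region's subsets.
#' @export
region_sample_count <- function(A, obs) {
  check_region(A, obs$space)
  sum(obs$w[rows_in_region(obs, A)])
}

# weighted tabulate over 1..nbins
wtabulate <- function(xi, w, nbins, unit_w = FALSE) {
  if (unit_w || all(w == 1)) return(as.numeric(tabulate(xi, nbins)))
  out <- numeric(nbins)
  if (length(xi)) {
    ag <- rowsum(w, xi, reorder = FALSE)
    out[as.integer(rownames(ag))] <- ag[, 1L]
  }
  out
}

#' Marginal population of one variable within a region
#'
#' For variable `i` and each of its categories retained in region `A`, the
#' total weight of observations in `A` whose `i`-th coordinate equals that
#' category. Entries sum to `N(A)`.
#'
#' @param A Region.
#' @param obs Observation set.
#' @param i Variable index (1-based).
#' @return Named numeric vector over the categories of `A[[i]]` (in the
#'   region's storage order).
#' @export
marginal_population <- function(A, obs, i) {
  check_region(A, obs$space)
  stopifnot(length(i) == 1L, i >= 1L, i <= length(A))
  keep <- rows_in_region(obs, A)
  m <- space_sizes(obs$space)
  tab <- wtabulate(obs$x[keep, i], obs$w[keep], m[i])
  out <- tab[A[[i]]]
  names(out) <- obs$space$categories[[i]][A[[i]]]
  out
}

# linear (1-based, double) cell index of encoded rows; cells ordered with
# variable 1 fastest
cell_index <- function(x, m) {
  idx <- as.numeric(x[, 1L]) - 1
  stride <- 1
  for (i in seq_along(m)[-1L]) {
    stride <- stride * m[i - 1L]
    idx <- idx + (as.numeric(x[, i]) - 1) * stride
  }
  idx + 1
}

# linear indices (double) of all cells of a product region
region_cell_indices <- function(A, m) {
  idx <- as.numeric(A[[1L]]) - 1
  stride <- 1
  for (i in seq_along(m)[-1L]) {
    stride <- stride * m[i - 1L]
    idx <- as.vector(outer(idx, (as.numeric(A[[i]]) - 1) * stride, "+"))
  }
  idx + 1
}

logsumexp <- function(v) {
  mx <- max(v)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(v - mx)))
}
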