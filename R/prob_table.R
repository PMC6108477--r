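# Probability tables over a factor space.
#
# A table stores cell probabilities in up to three additive components:
# `dense`  — a numeric vector over all C cells (variable 1 fastest),
# `cells`  — explicit cells (index matrix) with probabilities,
# `blocks` — product regions whose mass is spread uniformly over their
#            cells (the natural output of a partition tree: nested blocks
#            sum where they overlap).
# Unmentioned cells are zero.

#' Construct a probability table
#'
#' @param space A [factor_space()].
#' @param dense Optional numeric vector of length `prod(m)`, cell values in
#'   linear order (variable 1 fastest).
#' @param cells Optional integer matrix of category indices (k by p).
#' @param prob Probabilities for the rows of `cells`.
#' @param blocks Optional list of `list(region =, mass =)` entries; each
#'   block spreads `mass` uniformly over the cells of its region.
#'   Components are additive; omitted cells are zero.
#' @return An object of class `"prob_table"`.
#' @export
prob_table <- function(space, dense = NULL, cells = NULL, prob = NULL,
                       blocks = NULL) {
  if (!inherits(space, "factor_space")) stop("'space' must be a factor_space")
  if (!is.null(cells)) {
    cells <- as.matrix(cells)
    storage.mode(cells) <- "integer"
    if (is.null(prob) || length(prob) != nrow(cells))
      stop("'prob' must match the rows of 'cells'")
    if (any(prob < 0)) stop("negative probability")
  }
  if (!is.null(dense)) {
    if (length(dense) != prod(space_sizes(space)))
      stop("'dense' must cover every cell")
    if (any(dense < 0)) stop("negative probability")
  }
  if (!is.null(blocks)) {
    for (b in blocks) {
      check_region(b$region, space)
      if (b$mass < 0) stop("negative block mass")
    }
  }
  structure(list(space = space, dense = dense, cells = cells,
                 prob = as.numeric(prob), blocks = blocks),
            class = "prob_table")
}

#' Total mass of a probability table
#'
#' @param pt A [prob_table()].
#' @return Sum of all cell probabilities (1 for a distribution).
#' @export
total_mass <- function(pt) {
  tot <- 0
  if (!is.null(pt$dense)) tot <- tot + sum(pt$dense)
  if (!is.null(pt$cells)) tot <- tot + sum(pt$prob)
  if (!is.null(pt$blocks))
    tot <- tot + sum(vapply(pt$blocks, `[[`, numeric(1), "mass"))
  tot
}

# materialize to a dense vector over all cells
pt_dense <- function(pt, max_cells = 2^24) {
  m <- space_sizes(pt$space)
  C <- prod(m)
  if (C > max_cells)
    stop("space too large to materialize (", C, " cells)")
  v <- numeric(C)
  if (!is.null(pt$dense)) v <- v + pt$dense
  if (!is.null(pt$cells) && nrow(pt$cells)) {
    idx <- cell_index(pt$cells, m)
    # duplicate cells accumulate
    ag <- rowsum(pt$prob, idx, reorder = FALSE)
    v[as.numeric(rownames(ag))] <- v[as.numeric(rownames(ag))] + ag[, 1L]
  }
  if (!is.null(pt$blocks)) {
    for (b in pt$blocks) {
      idx <- region_cell_indices(b$region, m)
      v[idx] <- v[idx] + b$mass / length(idx)
    }
  }
  v
}

#' @export
print.prob_table <- function(x, ...) {
  m <- space_sizes(x$space)
  cat("Probability table over", format(prod(m), big.mark = ","),
      "cells; total mass", format(total_mass(x)), "\n")
  comp <- c(
    if (!is.null(x$dense)) "dense",
    if (!is.null(x$cells)) paste0(nrow(x$cells), " explicit cell(s)"),
    if (!is.null(x$blocks)) paste0(length(x$blocks), " uniform block(s)"))
  cat("Components:", paste(comp, collapse = ", "), "\n")
  invisible(x)
}

#' Materialize a probability table as a data frame
#'
#' One row per cell with nonzero probability (or per explicit cell), label
#' columns named after the variables plus a `probability` column.
#'
#' @param x A [prob_table()].
#' @param row.names,optional Ignored (data frame method signature).
#' @param drop_zero Drop zero-probability cells; default TRUE.
#' @param max_cells Guard for dense materialization; default `2^22`.
#' @param ... Unused.
#' @export
as.data.frame.prob_table <- function(x, row.names = NULL, optional = FALSE,
                                     ..., drop_zero = TRUE,
                                     max_cells = 2^22) {
  m <- space_sizes(x$space)
  if (is.null(x$dense) && is.null(x$blocks) && !is.null(x$cells)) {
    cells <- x$cells
    prob <- x$prob
  } else {
    v <- pt_dense(x, max_cells = max_cells)
    keep <- if (drop_zero) which(v != 0) else seq_along(v)
    cells <- decode_cell_index(keep, m)
    prob <- v[keep]
  }
  out <- as.data.frame(lapply(seq_along(m), function(i)
    x$space$categories[[i]][cells[, i]]))
  names(out) <- x$space$variables
  out$probability <- prob
  out
}

# inverse of cell_index: linear (1-based) -> index matrix
decode_cell_index <- function(idx, m) {
  idx <- as.numeric(idx) - 1
  out <- matrix(0L, length(idx), length(m))
  for (i in seq_along(m)) {
    out[, i] <- as.integer(idx %% m[i]) + 1L
    idx <- idx %/% m[i]
  }
  out
}

#' Root sum square error between two probability tables
#'
#' `sqrt( sum_cells (a - b)^2 )` over every combination cell of the shared
#' space. Sparse explicit-cell tables are compared over the union of their
#' supports; tables with dense or block components are materialized.
#'
#' @param est,truth [prob_table()] objects over the same factor space.
#' @param max_cells Materialization guard; default `2^24`.
#' @return Non-negative scalar; 0 iff the tables agree on every cell.
#' @export
rsse <- function(est, truth, max_cells = 2^24) {
  ma <- space_sizes(est$space)
  mb <- space_sizes(truth$space)
  if (!identical(ma, mb) ||
      !identical(est$space$categories, truth$space$categories))
    stop("tables are defined over different factor spaces")
  sparse_a <- is.null(est$dense) && is.null(est$blocks)
  sparse_b <- is.null(truth$dense) && is.null(truth$blocks)
  if (sparse_a && sparse_b) {
    ka <- cell_index(est$cells, ma)
    kb <- cell_index(truth$cells, ma)
    keys <- unique(c(ka, kb))
    va <- numeric(length(keys))
    vb <- numeric(length(keys))
    ia <- match(ka, keys)
    ib <- match(kb, keys)
    for (j in seq_along(ka)) va[ia[j]] <- va[ia[j]] + est$prob[j]
    for (j in seq_along(kb)) vb[ib[j]] <- vb[ib[j]] + truth$prob[j]
    return(sqrt(sum((va - vb)^2)))
  }
  a <- pt_dense(est, max_cells = max_cells)
  b <- pt_dense(truth, max_cells = max_cells)
  sqrt(sum((a - b)^2))
}
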