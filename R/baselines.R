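# Baseline estimators: cell-wise maximum likelihood, Aitchison-Aitken
# categorical kernel smoothing, and the random-partition tree variant.

#' Combination-wise maximum likelihood estimate
#'
#' The conventional estimator: the probability of a combination cell is the
#' (weighted) number of samples observed in it divided by the total weight.
#' Unobserved cells are implicitly zero, so the table stays sparse.
#'
#' @param obs An [observations()] set with positive total weight.
#' @return A sparse [prob_table()] of explicit cells.
#' @export
mle_estimate <- function(obs) {
  tot <- sum(obs$w)
  if (tot <= 0) stop("total observation weight must be positive")
  keys <- do.call(paste, c(lapply(seq_len(ncol(obs$x)), function(i)
    obs$x[, i]), sep = "\r"))
  first <- !duplicated(keys)
  grp <- match(keys, keys[first])
  ag <- rowsum(obs$w, grp) # rows ordered by group id = first-appearance
  prob_table(obs$space, cells = obs$x[first, , drop = FALSE],
             prob = ag[, 1L] / tot)
}

#' Aitchison-Aitken categorical kernel density estimate
#'
#' Product kernel for unordered categories: per variable the kernel puts
#' weight `1 - lambda` on the observed category and `lambda / (m_i - 1)` on
#' every other category (weight 1 when `m_i = 1`); the cell estimate is the
#' weighted average of kernel products over the observations. `lambda = 0`
#' reproduces [mle_estimate()]; `lambda` near 1 smooths almost uniformly off
#' the observed category.
#'
#' @param obs An [observations()] set.
#' @param lambda Kernel bandwidth in `[0, 1]`; default 0.9.
#' @param max_cells Guard on the dense output size; default `2^22`.
#' @return A dense [prob_table()].
#' @export
kde_estimate <- function(obs, lambda = 0.9, max_cells = 2^22) {
  stopifnot(lambda >= 0, lambda <= 1)
  tot <- sum(obs$w)
  if (tot <= 0) stop("total observation weight must be positive")
  m <- space_sizes(obs$space)
  p <- length(m)
  C <- prod(m)
  if (C > max_cells) stop("space too large for a dense kernel estimate")
  if (p > 20L) stop("too many variables for the subset expansion")
  # expand prod_i (a_i + b_i * match_i) over subsets S of matched variables:
  # sum_S prod_{i in S} b_i prod_{i notin S} a_i * n_S(cell_S)
  a <- ifelse(m > 1, lambda / pmax(m - 1, 1), 0)
  b <- ifelse(m > 1, (1 - lambda) - lambda / pmax(m - 1, 1), 1)
  dense <- array(0, dim = m)
  for (code in 0:(2^p - 1)) {
    S <- as.logical(bitwAnd(code, 2^(seq_len(p) - 1L)))
    coefv <- prod(b[S]) * prod(a[!S])
    if (coefv == 0) next
    if (!any(S)) {
      dense <- dense + coefv * tot
      next
    }
    mS <- m[S]
    idx <- cell_index(obs$x[, S, drop = FALSE], mS)
    tb <- array(wtabulate(idx, obs$w, prod(mS)), dim = mS)
    pos <- c(which(S), which(!S))
    full <- array(tb, dim = c(mS, m[!S]))
    if (length(pos) > 1L) full <- aperm(full, match(seq_len(p), pos))
    dense <- dense + coefv * full
  }
  prob_table(obs$space, dense = as.vector(dense) / tot)
}

#' Random-partition optional Polya tree
#'
#' The random-partitioning variant of [opt_fit()]: each candidate split
#' assigns the variable's categories to the two sides uniformly at random
#' (redrawn until both sides are non-empty) instead of cutting the
#' marginal-population ranking. Likelihoods, commitment and posterior
#' inference are unchanged.
#'
#' @param obs An [observations()] set (or data frame).
#' @param params [opt_params()].
#' @param seed Integer seed making the tree reproducible.
#' @return An `"opt_tree"` object.
#' @export
random_partition_tree <- function(obs, params = opt_params(), seed = NULL) {
  opt_fit(obs, params = params, partition = "random", seed = seed)
}
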