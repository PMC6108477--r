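# Marginal-population-guided candidate splits.
#
# Within a region, the categories of one variable are ranked by their local
# marginal population; only prefix/suffix cuts of that ranking are candidate
# bipartitions.  The cut position minimizes the within-group dispersion T,
# the sum over the two groups of squared deviations of marginal populations
# about the group mean.  This reduces the split search from sum_i 2^(m_i-1)
# bipartitions to at most p ranked cuts.

#' Rank categories by ascending marginal population
#'
#' Stable ascending order: ties keep the original storage order.
#'
#' @param M Numeric vector of marginal populations (e.g. from
#'   [marginal_population()]).
#' @return Integer permutation of `seq_along(M)`.
#' @export
rank_by_marginal <- function(M) {
  if (!length(M)) stop("'M' is empty")
  order(as.numeric(M), method = "radix")
}

# vectorized T over all cut positions s = 1..len-1 for ascending weights
split_dispersion_all <- function(M_sorted) {
  len <- length(M_sorted)
  S1 <- cumsum(M_sorted)
  S2 <- cumsum(M_sorted^2)
  k <- seq_len(len)
  pre <- S2 - S1^2 / k
  kk <- len - k
  suf <- (S2[len] - S2) - (S1[len] - S1)^2 / pmax(kk, 1)
  pmax(pre[-len] + suf[-len], 0) # clamp tiny negative rounding
}

#' Within-group dispersion of a ranked split
#'
#' For ascending marginal populations `M_sorted` cut after position `s`, the
#' sum over both groups of squared deviations of each weight about its group
#' mean. Zero iff both groups are internally constant.
#'
#' @param M_sorted Numeric vector of ascending marginal populations.
#' @param s Cut position, `1 <= s <= length(M_sorted) - 1`.
#' @return Non-negative scalar (squared-count units).
#' @examples
#' split_dispersion(c(1, 2, 9, 10), 2) # 1
#' @export
split_dispersion <- function(M_sorted, s) {
  len <- length(M_sorted)
  if (len < 2L) stop("need at least two categories to split")
  if (s < 1L || s > len - 1L) stop("'s' out of range")
  split_dispersion_all(as.numeric(M_sorted))[s]
}

#' Suboptimal split of a region for one variable
#'
#' Ranks the categories of variable `i` inside region `A` by marginal
#' population and cuts the ranking at the position minimizing the dispersion
#' metric (smallest position on ties). The left subregion keeps the
#' lowest-population categories.
#'
#' @param A Region.
#' @param obs Observation set.
#' @param i Variable index.
#' @return `NULL` when the variable has fewer than two categories in `A`,
#'   else a list of class `"split_option"` with elements `variable`, `s`
#'   (cut position), `left`/`right` (subregions), `T` (dispersion at the
#'   cut), `ranking` (permutation used), `n1`/`n2` (child sample counts).
#' @export
find_suboptimal_split <- function(A, obs, i) {
  check_region(A, obs$space)
  sub <- A[[i]]
  if (length(sub) < 2L) return(NULL)
  M <- marginal_population(A, obs, i)
  o <- rank_by_marginal(M)
  Ms <- as.numeric(M)[o]
  Tv <- split_dispersion_all(Ms)
  s <- which.min(Tv)
  left <- A
  right <- A
  left[[i]] <- sub[o[seq_len(s)]]
  right[[i]] <- sub[o[(s + 1L):length(sub)]]
  structure(list(variable = i, s = s, left = left, right = right,
                 T = Tv[s], ranking = o,
                 n1 = sum(Ms[seq_len(s)]), n2 = sum(Ms[-seq_len(s)])),
            class = "split_option")
}

#' All candidate splits of a region
#'
#' One suboptimal split per variable whose category subset in `A` has at
#' least two members, in variable order.
#'
#' @param A Region.
#' @param obs Observation set.
#' @return List of `"split_option"` objects (possibly empty).
#' @export
candidate_splits <- function(A, obs) {
  out <- lapply(seq_along(A), function(i) find_suboptimal_split(A, obs, i))
  out[!vapply(out, is.null, logical(1))]
}
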