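# Region likelihoods for the optional Polya tree, in log domain.
#
# Phi(A) = rho * Phi0(A)
#        + (1-rho)/p * sum_i B(N1+alpha, N2+alpha)/B(alpha,alpha)
#                        * Phi(A_i1) * Phi(A_i2)
# where Phi0(A) = C(A)^(-N(A)) is the stop (uniform) likelihood and the sum
# runs over the per-variable suboptimal splits.  Terminal regions (single
# cell or no sample) have Phi = Phi0.  The limited-lookahead variant
# truncates the recursion after `depth` levels, substituting Phi0 at the
# frontier.  Everything is computed with log-sum-exp: Phi0 alone underflows
# for a few hundred samples on a large space.

#' Prior parameters for the optional Polya tree
#'
#' @param rho Prior stopping weight in (0, 1): mass given to "no further
#'   split" at every region. Default 0.5.
#' @param alpha Pseudo count of the Beta allocation weights (> 0).
#'   Default 0.5.
#' @param beta Cell-level pseudo count of the uniform Dirichlet extension
#'   inside stopped regions (> 0); affects sampled distributions only, not
#'   the posterior mean. Default 0.5.
#' @param lookahead Lookahead depth `h >= 1` of the limited-lookahead
#'   construction. Default 3.
#' @param commit_q Levels committed per lookahead; only `1` is implemented
#'   (the standard choice).
#' @return A list of class `"opt_params"`.
#' @export
opt_params <- function(rho = 0.5, alpha = 0.5, beta = 0.5,
                       lookahead = 3L, commit_q = 1L) {
  stopifnot(rho > 0, rho < 1, alpha > 0, beta > 0,
            lookahead >= 1, commit_q <= lookahead)
  if (commit_q != 1L) stop("only commit_q = 1 is implemented")
  structure(list(rho = rho, alpha = alpha, beta = beta,
                 lookahead = as.integer(lookahead),
                 commit_q = 1L),
            class = "opt_params")
}

#' Log uniform likelihood of a region
#'
#' `Phi0(A) = C(A)^(-N)`: the likelihood of `N` samples falling uniformly on
#' the `C(A)` cells of `A`.
#'
#' @param A Region.
#' @param n Sample count `N(A) >= 0` (weighted).
#' @return `-n * log(C(A))`, in nats.
#' @export
log_phi0 <- function(A, n) {
  -n * log(region_cell_count(A))
}

#' Log Beta allocation weight of a split
#'
#' `log( B(n1 + alpha, n2 + alpha) / B(alpha, alpha) )`, the marginal
#' likelihood weight rewarding unbalanced child populations.
#'
#' @param n1,n2 Child sample counts (>= 0).
#' @param alpha Pseudo count (> 0).
#' @return Finite log value.
#' @export
log_beta_weight <- function(n1, n2, alpha) {
  lbeta(n1 + alpha, n2 + alpha) - lbeta(alpha, alpha)
}

#' Is a region terminal?
#'
#' Terminal regions cannot be split meaningfully: a single cell (every
#' variable reduced to one category) or no observed sample.
#'
#' @param A Region.
#' @param obs Observation set.
#' @return Logical flag.
#' @export
is_terminal <- function(A, obs) {
  region_cell_count(A) == 1 || region_sample_count(A, obs) == 0
}

# --- internal evaluation engine -------------------------------------------
#
# A context bundles the encoded data and prior so the recursion carries only
# (region, row indices, N, depth).  `chooser(sub, tab)` returns the
# positions (within `sub`) of the left child's categories: the
# marginal-ranked prefix cut for the proposed method, a random bipartition
# for the random-partition baseline.

chooser_marginal <- function(sub, tab) {
  o <- order(tab, method = "radix")
  Tv <- split_dispersion_all(tab[o])
  o[seq_len(which.min(Tv))]
}

chooser_random <- function(sub, tab) {
  len <- length(sub)
  if (len == 2L) return(1L)
  repeat {
    side <- stats::runif(len) < 0.5
    if (any(side) && !all(side)) return(which(side))
  }
}

make_phi_ctx <- function(obs, params, chooser = chooser_marginal) {
  p <- ncol(obs$x)
  list(x = obs$x, w = obs$w, m = space_sizes(obs$space), p = p,
       vars = obs$space$variables, unit_w = all(obs$w == 1),
       rho = params$rho, alpha = params$alpha,
       lrho = log(params$rho), lsplit = log((1 - params$rho) / p),
       chooser = chooser)
}

# log Phi with `depth` further levels of splitting allowed (Inf = exact).
phi_eval <- function(region, rows, N, depth, ctx) {
  C <- prod(lengths(region))
  lp0 <- -N * log(C)
  if (C == 1 || N == 0 || depth == 0) return(lp0)
  terms <- numeric(0)
  for (i in seq_len(ctx$p)) {
    sub <- region[[i]]
    len <- length(sub)
    if (len < 2L) next
    xi <- ctx$x[rows, i]
    tab <- wtabulate(xi, ctx$w[rows], ctx$m[i], ctx$unit_w)[sub]
    lpos <- ctx$chooser(sub, tab)
    n1 <- sum(tab[lpos])
    n2 <- N - n1
    leftc <- sub[lpos]
    nl <- length(leftc)
    if (depth == 1) {
      Cother <- C / len
      lp1 <- -n1 * log(nl * Cother)
      lp2 <- -n2 * log((len - nl) * Cother)
    } else {
      mem <- logical(ctx$m[i])
      mem[leftc] <- TRUE
      inl <- mem[xi]
      r1 <- region; r1[[i]] <- leftc
      r2 <- region; r2[[i]] <- sub[-lpos]
      lp1 <- phi_eval(r1, rows[inl], n1, depth - 1, ctx)
      lp2 <- phi_eval(r2, rows[!inl], n2, depth - 1, ctx)
    }
    lbw <- lbeta(n1 + ctx$alpha, n2 + ctx$alpha) -
      lbeta(ctx$alpha, ctx$alpha)
    terms <- c(terms, ctx$lsplit + lbw + lp1 + lp2)
  }
  if (!length(terms)) return(lp0)
  logsumexp(c(ctx$lrho + lp0, terms))
}

# as phi_eval, but returns the per-option decomposition needed to commit a
# split: called once per committed node.
phi_eval_detail <- function(region, rows, N, depth, ctx) {
  C <- prod(lengths(region))
  lp0 <- -N * log(C)
  out <- list(log_phi0 = lp0, terms = numeric(0), options = list())
  if (C == 1 || N == 0 || depth == 0) {
    out$log_phi <- lp0
    return(out)
  }
  for (i in seq_len(ctx$p)) {
    sub <- region[[i]]
    len <- length(sub)
    if (len < 2L) next
    xi <- ctx$x[rows, i]
    tab <- wtabulate(xi, ctx$w[rows], ctx$m[i], ctx$unit_w)[sub]
    lpos <- ctx$chooser(sub, tab)
    n1 <- sum(tab[lpos])
    n2 <- N - n1
    leftc <- sub[lpos]
    mem <- logical(ctx$m[i])
    mem[leftc] <- TRUE
    inl <- mem[xi]
    r1 <- region; r1[[i]] <- leftc
    r2 <- region; r2[[i]] <- sub[-lpos]
    rl <- rows[inl]
    rr <- rows[!inl]
    lp1 <- phi_eval(r1, rl, n1, depth - 1, ctx)
    lp2 <- phi_eval(r2, rr, n2, depth - 1, ctx)
    lbw <- lbeta(n1 + ctx$alpha, n2 + ctx$alpha) -
      lbeta(ctx$alpha, ctx$alpha)
    out$terms <- c(out$terms, ctx$lsplit + lbw + lp1 + lp2)
    out$options <- c(out$options, list(list(
      variable = i, left = r1, right = r2, rows_left = rl, rows_right = rr,
      n1 = n1, n2 = n2)))
  }
  out$log_phi <- if (length(out$terms))
    logsumexp(c(ctx$lrho + lp0, out$terms)) else lp0
  out
}

#' Exact log region likelihood
#'
#' Full recursion of the likelihood down to terminal regions. Intended for
#' small spaces: the recursion visits on the order of `C(A)` subregions, so
#' a cell-count guard rejects large inputs.
#'
#' @param A Region.
#' @param obs Observation set.
#' @param params [opt_params()].
#' @param max_cells Guard on `C(A)`; default 4096.
#' @return `log Phi(A)` in nats.
#' @export
log_phi_exact <- function(A, obs, params = opt_params(), max_cells = 4096) {
  check_region(A, obs$space)
  if (region_cell_count(A) > max_cells)
    stop("region too large for exact recursion (", region_cell_count(A),
         " cells > max_cells); use log_phi_lookahead()")
  ctx <- make_phi_ctx(obs, params)
  rows <- which(rows_in_region(obs, A))
  phi_eval(A, rows, sum(obs$w[rows]), Inf, ctx)
}

#' Truncated (limited-lookahead) log region likelihood
#'
#' Same recursion as [log_phi_exact()], but regions reached after `depth`
#' levels contribute their uniform likelihood `Phi0` instead of recursing.
#' Equals the exact value once `depth` exceeds the depth of the full
#' recursion.
#'
#' @param A Region.
#' @param obs Observation set.
#' @param params [opt_params()].
#' @param depth Remaining lookahead levels (>= 0); `depth = 0` returns
#'   [log_phi0()].
#' @return `log Phi(A)` in nats.
#' @export
log_phi_lookahead <- function(A, obs, params = opt_params(),
                              depth = params$lookahead) {
  check_region(A, obs$space)
  stopifnot(depth >= 0)
  ctx <- make_phi_ctx(obs, params)
  rows <- which(rows_in_region(obs, A))
  phi_eval(A, rows, sum(obs$w[rows]), depth, ctx)
}
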