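# Synthetic data generators with known truth tables, and the RSSE
# benchmark harness.
#
# Each generator returns list(obs = observation_set, truth = prob_table).
# Category labels are shuffled by default so that storage order carries no
# information about the generative structure, as with real unordered codes.

sim_space <- function(m, prefix = "c") {
  p <- length(m)
  factor_space(paste0("X", seq_len(p)),
               lapply(m, function(mi) paste0(prefix, seq_len(mi))))
}

# save/restore the RNG around a block run under a fixed internal seed, so
# a generator's truth table depends on its parameters only
with_fixed_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

#' Two-level (super-category) uniform simulation
#'
#' Each variable's `m_i` fine categories aggregate into two hidden super
#' categories of `m_i / 2` categories each, with super masses
#' `p_super[i]` and `1 - p_super[i]`; fine categories are uniform within a
#' super category. In the dependent mode the super-category indicator is
#' shared by all variables (mass `p_super[1]` on the aligned low block,
#' the rest on the aligned high block, zero elsewhere); in the independent
#' mode the variables are independent, e.g. with `p_super = c(.7, .8, .9)`
#' the all-low block cell probability is `0.504 / prod(m / 2)`.
#'
#' @param n Number of observations to draw from the truth.
#' @param m Per-variable category counts (all even); default `c(100,
#'   100, 100)`.
#' @param p_super Per-variable mass of the first super category; default
#'   `c(0.7, 0.8, 0.9)`. The dependent mode requires a common value.
#' @param dependent Logical; default `FALSE` (independent variables).
#' @param seed Optional integer seed.
#' @param shuffle Shuffle category labels (see
#'   [shuffle_category_labels()]); default `TRUE`.
#' @return `list(obs, truth)`: the observations and the designed
#'   block-structured truth table.
#' @export
sim_two_level <- function(n, m = c(100, 100, 100),
                          p_super = c(0.7, 0.8, 0.9), dependent = FALSE,
                          seed = NULL, shuffle = TRUE) {
  p <- length(m)
  stopifnot(n >= 1, all(m >= 2), all(m %% 2 == 0),
            length(p_super) == p, all(p_super > 0), all(p_super < 1))
  masses <- lapply(p_super, function(q) c(q, 1 - q))
  sim_super_uniform(n, m, masses, K = 2L, dependent = dependent,
                    seed = seed, shuffle = shuffle)
}

# general K-super-category uniform engine; masses: list of length-K
# per-variable super masses (a single vector is recycled)
sim_super_uniform <- function(n, m, masses, K = 2L, dependent = FALSE,
                              seed = NULL, shuffle = TRUE) {
  p <- length(m)
  if (!is.list(masses)) masses <- rep(list(masses), p)
  stopifnot(length(masses) == p, all(m %% K == 0),
            all(vapply(masses, length, integer(1)) == K))
  for (w in masses)
    if (abs(sum(w) - 1) > 1e-12 || any(w <= 0))
      stop("super-category masses must be positive and sum to 1")
  if (dependent && length(unique(masses)) != 1L)
    stop("the dependent mode needs identical super masses for all variables")
  space <- sim_space(m)
  blk <- m %/% K
  block_idx <- function(i, k) ((k - 1L) * blk[i] + 1L):(k * blk[i])
  if (dependent) {
    w <- masses[[1L]]
    blocks <- lapply(seq_len(K), function(k) list(
      region = lapply(seq_len(p), function(i) block_idx(i, k)),
      mass = w[k]))
  } else {
    combos <- as.matrix(expand.grid(rep(list(seq_len(K)), p)))
    blocks <- lapply(seq_len(nrow(combos)), function(r) list(
      region = lapply(seq_len(p), function(i) block_idx(i, combos[r, i])),
      mass = prod(vapply(seq_len(p), function(i)
        masses[[i]][combos[r, i]], numeric(1)))))
  }
  truth <- prob_table(space, blocks = blocks)
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(0L, n, p)
  if (dependent) {
    k <- sample.int(K, n, replace = TRUE, prob = masses[[1L]])
    for (i in seq_len(p))
      x[, i] <- (k - 1L) * blk[i] + sample.int(blk[i], n, replace = TRUE)
  } else {
    for (i in seq_len(p)) {
      pr <- rep(masses[[i]] / blk[i], each = blk[i])
      x[, i] <- sample.int(m[i], n, replace = TRUE, prob = pr)
    }
  }
  obs <- new_observations(space, x)
  if (shuffle) shuffle_category_labels(obs, truth) else
    list(obs = obs, truth = truth)
}

# hand-rolled multivariate normal log density on a matrix of points
mvn_density <- function(pts, mean, sigma) {
  R <- chol(sigma)
  z <- forwardsolve(t(R), t(pts) - mean)
  exp(-0.5 * colSums(z^2)) / ((2 * pi)^(length(mean) / 2) * prod(diag(R)))
}

#' Discretized multivariate normal simulation
#'
#' A joint normal distribution is discretized over `m_1 x ... x m_p`
#' uniformly partitioned cells spanning `mean +/- range` standard
#' deviations per axis; cell probabilities are the (midpoint-rule) density
#' mass per cell, renormalized. Samples are drawn from the discretized
#' truth, so truth and data are exactly consistent.
#'
#' @param n Number of observations.
#' @param m Per-variable category counts; default `c(20, 20, 20)`.
#' @param mean Mean vector; default zeros.
#' @param sigma Covariance matrix; default equicorrelation `rho_corr` with
#'   unit variances.
#' @param rho_corr Pairwise correlation of the default `sigma`;
#'   default 0.2.
#' @param range Half-width of the grid in per-axis standard deviations;
#'   default 3.
#' @param seed,shuffle As in [sim_two_level()].
#' @return `list(obs, truth)` with a dense truth table.
#' @export
sim_mvnormal <- function(n, m = c(20, 20, 20), mean = NULL, sigma = NULL,
                         rho_corr = 0.2, range = 3, seed = NULL,
                         shuffle = TRUE) {
  p <- length(m)
  if (is.null(mean)) mean <- rep(0, p)
  if (is.null(sigma)) {
    sigma <- matrix(rho_corr, p, p)
    diag(sigma) <- 1
  }
  stopifnot(length(mean) == p, all(dim(sigma) == p))
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("'sigma' must be positive definite")
  C <- prod(m)
  if (C > 2^22) stop("space too large for a dense normal truth")
  sds <- sqrt(diag(sigma))
  mids <- lapply(seq_len(p), function(i) {
    br <- seq(mean[i] - range * sds[i], mean[i] + range * sds[i],
              length.out = m[i] + 1L)
    (br[-1L] + br[-(m[i] + 1L)]) / 2
  })
  pts <- as.matrix(expand.grid(mids)) # row order: variable 1 fastest
  dens <- mvn_density(pts, mean, sigma)
  truth <- prob_table(sim_space(m), dense = dens / sum(dens))
  if (!is.null(seed)) set.seed(seed)
  obs <- sample_from_truth(truth, n)
  if (shuffle) shuffle_category_labels(obs, truth) else
    list(obs = obs, truth = truth)
}

# draw n observations i.i.d. from a truth table (any representation)
sample_from_truth <- function(truth, n) {
  m <- space_sizes(truth$space)
  v <- pt_dense(truth)
  idx <- sample.int(length(v), n, replace = TRUE, prob = v)
  new_observations(truth$space, decode_cell_index(idx, m))
}

#' Auxiliary simulation families
#'
#' Parameterized generators for additional joint distributions: independent
#' discretized normals, additive exponential sums, a Clayton copula with a
#' uniform third axis, discretized log-normals, and uniform distributions
#' with `K` hidden super categories. Families whose truth is not available
#' in closed form (`additive_exponential`, `lognormal`) define it by
#' discretizing a large fixed-seed Monte-Carlo sample of the latent model
#' (`mc_size` draws), so the truth depends only on the stated parameters.
#'
#' @param family One of `"normal_nocorr"`, `"additive_exponential"`,
#'   `"clayton_uniform"`, `"lognormal"`, `"super_uniform"`.
#' @param n Number of observations.
#' @param m Per-variable category counts; default `c(20, 20, 20)`.
#' @param rate Exponential rate (additive_exponential); default 1.
#' @param theta Clayton dependence parameter (> 0); default 2.
#' @param rho_corr Latent correlation (lognormal); default 0.2.
#' @param K,masses Super-category count and mass vector (super_uniform);
#'   default `K = 5` with linearly decreasing masses.
#' @param dependent Shared super-category indicator (super_uniform);
#'   default FALSE.
#' @param mc_size Latent Monte-Carlo size defining empirical truths;
#'   default `2e5`.
#' @param seed,shuffle As in [sim_two_level()].
#' @return `list(obs, truth)`.
#' @export
sim_auxiliary <- function(family = c("normal_nocorr",
                                     "additive_exponential",
                                     "clayton_uniform", "lognormal",
                                     "super_uniform"),
                          n, m = c(20, 20, 20), rate = 1, theta = 2,
                          rho_corr = 0.2, K = 5L, masses = NULL,
                          dependent = FALSE, mc_size = 2e5, seed = NULL,
                          shuffle = TRUE) {
  family <- match.arg(family)
  p <- length(m)
  if (family == "normal_nocorr")
    return(sim_mvnormal(n, m, rho_corr = 0, seed = seed, shuffle = shuffle))
  if (family == "super_uniform") {
    if (is.null(masses)) {
      masses <- rev(seq_len(K)) / sum(seq_len(K))
    }
    return(sim_super_uniform(n, m, masses, K = K, dependent = dependent,
                             seed = seed, shuffle = shuffle))
  }
  if (family == "clayton_uniform") {
    stopifnot(theta > 0, p >= 2)
    # exact truth: Clayton copula mass on axes 1-2 by inclusion-exclusion,
    # remaining axes independent uniform
    cop <- function(u, v) (pmax(u^(-theta) + v^(-theta) - 1, 0))^(-1 / theta)
    g1 <- seq(0, 1, length.out = m[1] + 1L)
    g2 <- seq(0, 1, length.out = m[2] + 1L)
    Cm <- outer(g1, g2, cop)
    mass2 <- Cm[-1, -1] - Cm[-(m[1] + 1L), -1] -
      Cm[-1, -(m[2] + 1L)] + Cm[-(m[1] + 1L), -(m[2] + 1L)]
    dens <- as.vector(mass2)
    for (i in seq_len(p)[-(1:2)]) dens <- as.vector(outer(dens, rep(1 / m[i], m[i])))
    truth <- prob_table(sim_space(m), dense = dens / sum(dens))
  } else { # additive_exponential or lognormal: empirical latent truth
    latent <- function(N) {
      if (family == "additive_exponential") {
        z0 <- stats::rexp(N, rate)
        sapply(seq_len(p), function(i) z0 + stats::rexp(N, rate))
      } else {
        sig <- matrix(rho_corr, p, p)
        diag(sig) <- 1
        R <- chol(sig)
        exp(matrix(stats::rnorm(N * p), N, p) %*% R)
      }
    }
    upper <- if (family == "additive_exponential")
      stats::qgamma(0.995, 2, rate) else exp(3)
    disc <- function(y, mi) pmin(pmax(ceiling(y / upper * mi), 1L), mi)
    big <- with_fixed_seed(874511L, latent(mc_size))
    xs <- sapply(seq_len(p), function(i) disc(big[, i], m[i]))
    dens <- wtabulate(cell_index(xs, m), rep(1, nrow(xs)), prod(m))
    truth <- prob_table(sim_space(m), dense = dens / sum(dens))
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- sample_from_truth(truth, n)
  if (shuffle) shuffle_category_labels(obs, truth) else
    list(obs = obs, truth = truth)
}

#' Shuffle category labels consistently in data and truth
#'
#' Applies an independent random permutation to each variable's categories,
#' consistently in the observations and the truth table: the estimation
#' problem is unchanged (any sensible estimator's RSSE is invariant) but
#' the storage order no longer reflects the generative structure.
#'
#' @param obs An [observations()] set.
#' @param truth A [prob_table()] over the same space.
#' @param seed Optional integer seed.
#' @return `list(obs, truth)` with permuted category indices (labels keep
#'   their attachment to probabilities and samples).
#' @export
shuffle_category_labels <- function(obs, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- space_sizes(obs$space)
  perms <- lapply(m, sample.int)
  list(obs = permute_obs(obs, perms),
       truth = permute_table(truth, perms))
}

permute_obs <- function(obs, perms) {
  x <- obs$x
  for (i in seq_along(perms)) x[, i] <- perms[[i]][x[, i]]
  new_observations(obs$space, x, obs$w)
}

permute_table <- function(pt, perms) {
  m <- space_sizes(pt$space)
  dense <- pt$dense
  if (!is.null(dense)) {
    inv <- lapply(perms, order)
    arr <- array(dense, dim = m)
    arr <- do.call(`[`, c(list(arr), inv, list(drop = FALSE)))
    dense <- as.vector(arr)
  }
  cells <- pt$cells
  if (!is.null(cells))
    for (i in seq_along(perms)) cells[, i] <- perms[[i]][cells[, i]]
  blocks <- pt$blocks
  if (!is.null(blocks))
    blocks <- lapply(blocks, function(b) list(
      region = lapply(seq_along(perms), function(i)
        perms[[i]][b$region[[i]]]),
      mass = b$mass))
  prob_table(pt$space, dense = dense, cells = cells, prob = pt$prob,
             blocks = blocks)
}

#' Benchmark estimators on a simulation setting
#'
#' Repeatedly generates data from a named simulation setting, fits the
#' requested estimators, and summarizes the root sum square errors.
#'
#' @param setting `"two_level_dependent"`, `"two_level_independent"`,
#'   `"mvnormal_low"`, `"mvnormal_high"`, or one of the
#'   [sim_auxiliary()] family names.
#' @param n Sample size per replicate.
#' @param m Per-variable category counts.
#' @param replicates Number of repeated simulations; default 20.
#' @param estimators Subset of `c("opt", "mle", "kde", "randopt")`.
#' @param params [opt_params()] for the tree estimators.
#' @param lambda KDE bandwidth; default 0.9.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param ... Passed on to the generator (e.g. `theta`, `K`).
#' @return Data frame with one row per estimator: `setting`, `estimator`,
#'   `n`, `m`, `mean_rsse`, `sd_rsse`, `cv`; the per-replicate RSSE matrix
#'   is attached as attribute `"rsse"`.
#' @export
run_benchmark <- function(setting, n, m = c(20, 20, 20), replicates = 20,
                          estimators = c("opt", "mle", "kde", "randopt"),
                          params = opt_params(), lambda = 0.9, seed = 1,
                          ...) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  gen <- function(s) switch(
    setting,
    two_level_dependent = sim_two_level(n, m, p_super = rep(0.7, length(m)),
                                        dependent = TRUE, seed = s),
    two_level_independent = sim_two_level(
      n, m, p_super = rep_len(c(0.7, 0.8, 0.9), length(m)), seed = s),
    mvnormal_low = sim_mvnormal(n, m, rho_corr = 0.2, seed = s),
    mvnormal_high = sim_mvnormal(n, m, rho_corr = 0.8, seed = s),
    sim_auxiliary(setting, n, m, seed = s, ...))
  err <- matrix(NA_real_, replicates, length(estimators),
                dimnames = list(NULL, estimators))
  for (r in seq_len(replicates)) {
    d <- gen(seed + r)
    for (e in estimators) {
      est <- switch(e,
        opt = expected_cell_probabilities(opt_fit(d$obs, params = params)),
        mle = mle_estimate(d$obs),
        kde = kde_estimate(d$obs, lambda = lambda),
        randopt = expected_cell_probabilities(
          random_partition_tree(d$obs, params = params,
                                seed = seed + 7919L * r)))
      err[r, e] <- rsse(est, d$truth)
    }
  }
  out <- data.frame(setting = setting, estimator = estimators,
                    n = n, m = paste(m, collapse = "x"),
                    mean_rsse = colMeans(err),
                    sd_rsse = apply(err, 2, stats::sd),
                    row.names = NULL)
  out$cv <- out$sd_rsse / out$mean_rsse
  attr(out, "rsse") <- err
  out
}
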