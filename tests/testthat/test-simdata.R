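test_that("two-level truths have the designed block probabilities", {
  m <- c(100, 100, 100)
  # dependent, common super mass 0.7: low-block cells at 0.7/125000
  dep <- sim_two_level(5, m, p_super = rep(0.7, 3), dependent = TRUE,
                       seed = 1, shuffle = FALSE)
  blocks <- dep$truth$blocks
  expect_length(blocks, 2)
  expect_equal(blocks[[1]]$mass / prod(m / 2), 0.7 / 125000,
               tolerance = 1e-15)
  expect_equal(total_mass(dep$truth), 1, tolerance = 1e-12)

  # independent, p = (.7, .8, .9): all-low block cells at 0.504/125000
  ind <- sim_two_level(5, m, seed = 1, shuffle = FALSE)
  masses <- vapply(ind$truth$blocks, `[[`, numeric(1), "mass")
  expect_length(ind$truth$blocks, 8)
  expect_equal(max(masses), 0.504, tolerance = 1e-12)
  expect_equal(max(masses) / prod(m / 2), 0.504 / 125000, tolerance = 1e-15)
  expect_equal(total_mass(ind$truth), 1, tolerance = 1e-12)

  expect_error(sim_two_level(5, m = c(3, 4, 4)), "%%")
})

test_that("discretized normal truths factorize, reflect, and refine", {
  # zero correlation: the truth is the product of its marginals
  d0 <- sim_mvnormal(5, m = c(8, 8, 8), rho_corr = 0, seed = 1,
                     shuffle = FALSE)
  arr <- array(d0$truth$dense, dim = c(8, 8, 8))
  m1 <- apply(arr, 1, sum); m2 <- apply(arr, 2, sum); m3 <- apply(arr, 3, sum)
  prod3 <- outer(outer(m1, m2), m3)
  expect_equal(as.vector(prod3), d0$truth$dense, tolerance = 1e-9)

  # zero mean, symmetric grid: invariant under coordinate reflection
  dc <- sim_mvnormal(5, m = c(6, 6, 6), rho_corr = 0.5, seed = 1,
                     shuffle = FALSE)
  arrc <- array(dc$truth$dense, dim = c(6, 6, 6))
  expect_equal(arrc, arrc[6:1, 6:1, 6:1], tolerance = 1e-12)

  # midpoint discretization approaches a refined quadrature of the density
  m <- c(10, 10)
  d2 <- sim_mvnormal(5, m = m, mean = c(0, 0),
                     sigma = matrix(c(1, .4, .4, 1), 2), seed = 1,
                     shuffle = FALSE)
  # oracle: subdivide each cell 7x7 and integrate the same density
  fine <- sim_mvnormal(5, m = m * 7, mean = c(0, 0),
                       sigma = matrix(c(1, .4, .4, 1), 2), seed = 1,
                       shuffle = FALSE)
  coarse <- array(0, m)
  fa <- array(fine$truth$dense, m * 7)
  for (i in seq_len(m[1])) for (j in seq_len(m[2]))
    coarse[i, j] <- sum(fa[(i - 1) * 7 + 1:7, (j - 1) * 7 + 1:7])
  expect_lt(max(abs(array(d2$truth$dense, m) - coarse)), 2e-3)
})

test_that("auxiliary families yield valid reproducible truths", {
  for (fam in c("additive_exponential", "clayton_uniform", "lognormal")) {
    d <- sim_auxiliary(fam, n = 50, m = c(6, 6, 6), seed = 3,
                       mc_size = 5e4, shuffle = FALSE)
    expect_equal(total_mass(d$truth), 1, tolerance = 1e-9)
    expect_true(all(d$truth$dense >= 0))
    d2 <- sim_auxiliary(fam, n = 50, m = c(6, 6, 6), seed = 3,
                        mc_size = 5e4, shuffle = FALSE)
    expect_equal(d$truth$dense, d2$truth$dense) # truth independent of draw
  }
  # equal-mass super categories, independent: all nonzero cells equal
  d <- sim_auxiliary("super_uniform", n = 20, m = c(10, 10), K = 5,
                     masses = rep(0.2, 5), seed = 1, shuffle = FALSE)
  v <- optcat:::pt_dense(d$truth)
  nz <- v[v > 0]
  expect_equal(nz, rep(1 / length(v), length(v)), tolerance = 1e-12)

  # Clayton truth matches a large empirical draw of the copula
  dcl <- sim_auxiliary("clayton_uniform", n = 10, m = c(8, 8), theta = 2,
                       seed = 5, shuffle = FALSE)
  set.seed(99)
  u1 <- runif(2e5); v0 <- runif(2e5)
  th <- 2
  u2 <- ((v0^(-th / (1 + th)) - 1) * u1^(-th) + 1)^(-1 / th)
  emp <- table(factor(ceiling(u1 * 8), levels = 1:8),
               factor(ceiling(u2 * 8), levels = 1:8)) / 2e5
  expect_lt(max(abs(as.vector(array(dcl$truth$dense, c(8, 8))) -
                      as.vector(emp))), 0.005)
})

test_that("label shuffling permutes consistently and reversibly", {
  d <- sim_two_level(200, m = c(10, 10, 10), seed = 7, shuffle = FALSE)
  sh <- shuffle_category_labels(d$obs, d$truth, seed = 11)
  # MLE error is invariant under the joint relabeling
  expect_equal(rsse(mle_estimate(d$obs), d$truth),
               rsse(mle_estimate(sh$obs), sh$truth), tolerance = 1e-12)
  expect_equal(total_mass(sh$truth), 1, tolerance = 1e-12)
  # applying the inverse permutations restores the original
  set.seed(11)
  perms <- lapply(c(10L, 10L, 10L), sample.int)
  invs <- lapply(perms, order)
  back_obs <- optcat:::permute_obs(sh$obs, invs)
  back_truth <- optcat:::permute_table(sh$truth, invs)
  expect_identical(back_obs$x, d$obs$x)
  expect_equal(optcat:::pt_dense(back_truth), optcat:::pt_dense(d$truth),
               tolerance = 1e-12)
})

test_that("rsse agrees with dense brute force and closed forms", {
  d <- sim_two_level(50, m = c(6, 6, 6), seed = 13, shuffle = FALSE)
  est <- mle_estimate(d$obs)
  expect_equal(rsse(est, d$truth), oracle_rsse(est, d$truth),
               tolerance = 1e-12)
  expect_equal(rsse(d$truth, d$truth), 0)

  # all mass on one zero-truth cell: sqrt(1 + sum truth^2)
  dep <- sim_two_level(5, m = c(4, 4, 4), p_super = rep(0.7, 3),
                       dependent = TRUE, seed = 1, shuffle = FALSE)
  zero_cell <- matrix(c(1L, 1L, 3L), 1) # low block x low x high: truth 0
  point <- prob_table(dep$truth$space, cells = zero_cell, prob = 1)
  tv <- optcat:::pt_dense(dep$truth)
  expect_equal(rsse(point, dep$truth), sqrt(1 + sum(tv^2)),
               tolerance = 1e-12)

  # mismatched spaces are rejected
  other <- sim_two_level(5, m = c(4, 4), p_super = c(.7, .8), seed = 1)
  expect_error(rsse(other$truth, dep$truth), "different factor spaces")

  # both tables sum to 1: the error cannot exceed sqrt(2)
  for (rep in 1:5) {
    d <- sim_two_level(10, c(4, 4), p_super = c(.7, .8), seed = rep)
    expect_lte(rsse(mle_estimate(d$obs), d$truth), sqrt(2))
  }
})

test_that("benchmarks are seed-reproducible and MLE error is calibrated", {
  b1 <- run_benchmark("two_level_independent", n = 300, m = c(6, 6, 6),
                      replicates = 2, estimators = c("mle", "kde"), seed = 5)
  b2 <- run_benchmark("two_level_independent", n = 300, m = c(6, 6, 6),
                      replicates = 2, estimators = c("mle", "kde"), seed = 5)
  expect_equal(b1$mean_rsse, b2$mean_rsse)
  expect_equal(b1$cv, b1$sd_rsse / b1$mean_rsse)

  # analytic multinomial oracle: E[sum (phat - p)^2] = (1 - sum p^2)/n
  m <- c(10, 10); n <- 400; reps <- 50
  d0 <- sim_two_level(5, m, p_super = c(.7, .8), seed = 1, shuffle = FALSE)
  p2 <- sum(optcat:::pt_dense(d0$truth)^2)
  sq <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- sim_two_level(n, m, p_super = c(.7, .8), seed = 100 + r)
    sq[r] <- rsse(mle_estimate(d$obs), d$truth)^2
  }
  expected <- (1 - p2) / n
  se <- stats::sd(sq) / sqrt(reps)
  expect_lt(abs(mean(sq) - expected), 3 * se)
})

test_that("tree estimation error shrinks with sample size on block data", {
  ns <- c(800, 3200, 12800)
  err <- vapply(ns, function(n) {
    mean(vapply(1:20, function(r) {
      d <- sim_two_level(n, m = c(20, 20, 20), seed = 40 + 7 * r + n)
      rsse(expected_cell_probabilities(opt_fit(d$obs)), d$truth)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})
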