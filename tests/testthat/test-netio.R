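test_that("count matrices load identically from MTX and TSV", {
  m <- matrix(c(1, 0, 0, 3), 2, 2,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  tsv <- tempfile(fileext = ".tsv")
  write.table(m, tsv, sep = "\t", quote = FALSE, col.names = NA)
  o_tsv <- read_count_matrix(tsv)
  expect_equal(sum(o_tsv$w), 4)
  expect_equal(nrow(o_tsv$x), 2) # only nonzero entries

  mtx <- tempfile(fileext = ".mtx")
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mtx)
  o_mtx <- read_count_matrix(mtx)
  expect_equal(o_mtx$x, o_tsv$x)
  expect_equal(o_mtx$w, o_tsv$w)

  # random sparse matrix round-trips through writeMM
  set.seed(103)
  big <- matrix(rpois(30 * 20, 0.3), 30, 20)
  obs <- optcat:::new_observations(
    factor_space(c("row", "col"),
                 list(paste0("r", 1:30), paste0("c", 1:20))),
    which(big > 0, arr.ind = TRUE), big[big > 0])
  rt <- tempfile(fileext = ".mtx")
  write_count_matrix(obs, rt)
  back <- read_count_matrix(rt)
  ord <- order(obs$x[, 1], obs$x[, 2])
  ord2 <- order(back$x[, 1], back$x[, 2])
  expect_equal(unname(obs$x[ord, ]), unname(back$x[ord2, ]))
  expect_equal(obs$w[ord], back$w[ord2])

  neg <- tempfile(fileext = ".tsv")
  write.table(matrix(c(1, -2), 1), neg, sep = "\t", quote = FALSE,
              col.names = NA)
  expect_error(read_count_matrix(neg), "negative")
})

test_that("binomial thinning preserves totals in expectation", {
  set.seed(105)
  big <- matrix(rpois(20 * 10, 2), 20, 10)
  obs <- optcat:::new_observations(
    factor_space(c("row", "col"),
                 list(paste0("r", 1:20), paste0("c", 1:10))),
    which(big > 0, arr.ind = TRUE), big[big > 0])
  expect_equal(sum(subsample_counts(obs, 1)$w), sum(obs$w))
  s1 <- subsample_counts(obs, 0.3, seed = 7)
  s2 <- subsample_counts(obs, 0.3, seed = 7)
  expect_equal(s1$w, s2$w)
  set.seed(107)
  tots <- replicate(200, sum(subsample_counts(obs, 0.3)$w))
  n <- sum(obs$w)
  expect_lt(abs(mean(tots) - 0.3 * n), 3 * sqrt(n * 0.3 * 0.7 / 200) + 1e-9)
  expect_error(subsample_counts(obs, 0), "fraction")
})

test_that("co-occurrence edges enumerate labels of nonzero terminal regions", {
  # force a one-leaf tree: uniform 2x1 region with samples
  d <- data.frame(dx1 = c("a", "b"), dx2 = c("x", "x"))
  fit <- opt_fit(observations(d))
  edges <- cooccurrence_network(fit)
  # root stop: labels {a, b, x} -> 3 pairs of weight 1
  expect_equal(nrow(edges), 3)
  expect_equal(edges$weight, rep(1, 3))
  expect_true(all(edges$code_a < edges$code_b))

  # zero-sample terminal regions contribute nothing
  set.seed(109)
  d2 <- sim_two_level(100, m = c(10, 10), p_super = c(.7, .9), seed = 3)
  fit2 <- opt_fit(d2$obs)
  lv <- summary(fit2)$leaves
  edges2 <- cooccurrence_network(fit2, top_k = Inf)
  # recompute by brute force over nonzero leaves
  ref <- new.env(parent = emptyenv())
  walk <- function(node) {
    if (!is.null(node$children)) {
      walk(node$children[[1]]); walk(node$children[[2]]); return(invisible())
    }
    if (node$n == 0) return(invisible())
    labs <- sort(unique(unlist(lapply(1:2, function(i)
      fit2$space$categories[[i]][node$region[[i]]]))))
    if (length(labs) < 2) return(invisible())
    cmb <- combn(labs, 2)
    for (k in seq_len(ncol(cmb))) {
      key <- paste(cmb[1, k], cmb[2, k])
      assign(key, 1 + mget(key, ref, ifnotfound = 0)[[1]], envir = ref)
    }
  }
  walk(fit2$root)
  expect_equal(nrow(edges2), length(ls(ref)))
  expect_equal(sum(edges2$weight), sum(unlist(mget(ls(ref), ref))))
  # weights sorted descending, capped at top_k
  expect_true(all(diff(edges2$weight) <= 0))
  expect_lte(nrow(cooccurrence_network(fit2, top_k = 20)), 20)
})

test_that("trees and probability tables round-trip through files", {
  set.seed(113)
  obs <- rand_obs(80, c(5, 4, 3), weights = TRUE)
  fit <- opt_fit(obs)
  tf <- tempfile(fileext = ".json")
  write_opt_tree(fit, tf)
  back <- read_opt_tree(tf)
  expect_equal(back$n_nodes, fit$n_nodes)
  expect_equal(optcat:::pt_dense(expected_cell_probabilities(back)),
               optcat:::pt_dense(expected_cell_probabilities(fit)),
               tolerance = 1e-12)
  expect_equal(cooccurrence_network(back), cooccurrence_network(fit))

  pt <- mle_estimate(obs)
  pf <- tempfile(fileext = ".tsv")
  write_prob_table(pt, pf)
  back_pt <- read_prob_table(pf, obs$space)
  expect_equal(rsse(back_pt, pt), 0, tolerance = 1e-9)
})

test_that("the command line mirrors the library calls", {
  exe <- system.file("exec", "optcat", package = "optcat")
  if (!nzchar(exe)) exe <- file.path(find.package("optcat"), "exec", "optcat")
  expect_true(file.exists(exe))
  rscript <- file.path(R.home("bin"), "Rscript")
  run <- function(...) suppressWarnings(
    system2(rscript, c(exe, ...), stdout = TRUE, stderr = TRUE))

  td <- tempfile(); dir.create(td)
  dat <- file.path(td, "d.csv"); tru <- file.path(td, "t.tsv")
  est <- file.path(td, "e.tsv"); trj <- file.path(td, "tree.json")
  out1 <- run("simulate", "--setting", "two_level_independent",
              "--m", "6,6", "--n", "200", "--seed", "4",
              "--out-data", dat, "--out-truth", tru)
  expect_true(file.exists(dat) && file.exists(tru))
  run("estimate", "--data", dat, "--estimator", "mle", "--out", est)
  cli_tbl <- read_prob_table(est)
  lib_tbl <- mle_estimate(observations(read.csv(dat,
    colClasses = "character")))
  expect_equal(rsse(cli_tbl, lib_tbl), 0, tolerance = 1e-12)
  out2 <- run("evaluate", "--estimate", est, "--truth", tru)
  expect_match(paste(out2, collapse = " "), "RSSE: [0-9.]+")
  run("estimate", "--data", dat, "--estimator", "opt", "--tree", trj)
  expect_true(file.exists(trj))
  enet <- file.path(td, "net.tsv")
  run("network", "--tree", trj, "--top", "10", "--out", enet)
  expect_true(file.exists(enet))
  bad <- run("estimate", "--nonsense", "1")
  expect_match(paste(bad, collapse = " "), "unknown flag|required")
})
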