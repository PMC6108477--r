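# Committed limited-lookahead optional Polya tree and posterior inference.
#
# Construction (q = 1 commitment): at each region, score "stop" against the
# p marginal-guided splits using likelihoods truncated at lookahead depth h,
# commit the single best action, and recurse into committed children until a
# region is terminal or a stop is committed.  The committed tree then
# carries posterior stopping probabilities rho*Phi0/Phi, selection
# probabilities over the scored splits, and Beta allocation parameters,
# from which the posterior mean, mode and random draws are derived.

#' Fit a marginal-population-guided optional Polya tree
#'
#' Estimates the joint probability distribution of `p` unordered factor
#' variables by recursive binary partitioning of the sample space. At each
#' region the categories of every variable are ranked by local marginal
#' population and the best prefix cut per variable competes with stopping;
#' likelihoods are evaluated with `params$lookahead` levels of recursion
#' (LL-OPT) and the best action is committed.
#'
#' @param data A data frame of label-valued observations (optionally with a
#'   `count` column), or an [observations()] set.
#' @param categories Optional per-variable label lists (see
#'   [observations()]); ignored when `data` is already encoded.
#' @param params Prior and lookahead parameters, see [opt_params()].
#' @param partition `"marginal"` for the marginal-population-guided split
#'   (the proposed method) or `"random"` for the random-bipartition
#'   baseline.
#' @param seed Optional integer seed; only consumed by
#'   `partition = "random"` (the marginal build is deterministic).
#' @return An object of class `"opt_tree"`: a list with the fitted `root`
#'   node, the `space`, `params`, `partition` flavour and size summaries
#'   (`n_nodes`, `n_leaves`, `max_depth`, total weight `n`). Nodes carry
#'   `region`, `n`, `log_phi`, `log_phi0`, `stop_prob`, `sel` (selection
#'   probabilities over scored splits), a committed `split` and `children`.
#' @seealso [expected_cell_probabilities()], [mode_tree()],
#'   [posterior_sample()], [predict.opt_tree()], [simulate.opt_tree()]
#' @examples
#' d <- data.frame(x = c("a", "a", "b"), y = c("u", "v", "u"))
#' fit <- opt_fit(d)
#' predict(fit)
#' @export
opt_fit <- function(data, categories = NULL, params = opt_params(),
                    partition = c("marginal", "random"), seed = NULL) {
  partition <- match.arg(partition)
  obs <- if (inherits(data, "observation_set")) data
         else observations(data, categories)
  if (sum(obs$w) <= 0) stop("total observation weight must be positive")
  if (!is.null(seed)) set.seed(seed)
  chooser <- if (partition == "random") chooser_random else chooser_marginal
  ctx <- make_phi_ctx(obs, params, chooser)
  stats <- new.env(parent = emptyenv())
  stats$nodes <- 0L
  stats$leaves <- 0L
  stats$depth <- 0L
  root <- build_node(whole_region(obs$space), seq_len(nrow(obs$x)),
                     sum(obs$w), 0L, ctx, params, stats)
  structure(list(space = obs$space, params = params, partition = partition,
                 root = root, n = sum(obs$w), n_rows = nrow(obs$x),
                 n_nodes = stats$nodes, n_leaves = stats$leaves,
                 max_depth = stats$depth, call = match.call()),
            class = "opt_tree")
}

build_node <- function(region, rows, N, depth, ctx, params, stats) {
  stats$nodes <- stats$nodes + 1L
  stats$depth <- max(stats$depth, depth)
  C <- prod(lengths(region))
  lp0 <- -N * log(C)
  if (C == 1 || N == 0) {
    stats$leaves <- stats$leaves + 1L
    return(list(region = region, n = N, depth = depth,
                log_phi = lp0, log_phi0 = lp0, stop_prob = 1,
                sel = NULL, split = NULL, children = NULL,
                terminal = TRUE))
  }
  det <- phi_eval_detail(region, rows, N, params$lookahead, ctx)
  stopw <- ctx$lrho + lp0
  stop_prob <- min(1, exp(stopw - det$log_phi))
  sel <- exp(det$terms - logsumexp(det$terms))
  names(sel) <- ctx$vars[vapply(det$options, `[[`, integer(1), "variable")]
  node <- list(region = region, n = N, depth = depth,
               log_phi = det$log_phi, log_phi0 = det$log_phi0,
               stop_prob = stop_prob, sel = sel, split = NULL,
               children = NULL, terminal = FALSE)
  k <- which.max(det$terms)
  if (stopw >= det$terms[k]) { # committed stop (ties stop, deterministic)
    stats$leaves <- stats$leaves + 1L
    return(node)
  }
  op <- det$options[[k]]
  node$split <- list(variable = op$variable,
                     left = op$left[[op$variable]],
                     right = op$right[[op$variable]],
                     n1 = op$n1, n2 = op$n2,
                     etheta = (op$n1 + ctx$alpha) / (N + 2 * ctx$alpha))
  node$children <- list(
    build_node(op$left, op$rows_left, op$n1, depth + 1L, ctx, params, stats),
    build_node(op$right, op$rows_right, op$n2, depth + 1L, ctx, params,
               stats))
  node
}

#' Posterior stopping probability of a node
#'
#' `rho(A | D) = rho * Phi0(A) / Phi(A)`, stored on the node at build time.
#'
#' @param node A node of a fitted [opt_fit()] tree (e.g. `fit$root`).
#' @return Probability in `[0, 1]`.
#' @export
stopping_probability <- function(node) {
  node$stop_prob
}

#' Posterior split-selection probabilities of a node
#'
#' Probabilities over the scored per-variable splits, proportional to the
#' Beta-weighted child likelihoods, normalized over the available options.
#'
#' @param node A non-terminal node of a fitted [opt_fit()] tree.
#' @return Named numeric vector summing to 1 (names are variable indices).
#' @export
selection_probabilities <- function(node) {
  if (is.null(node$sel)) stop("node has no split option (terminal region)")
  node$sel
}

#' Posterior-mean cell probabilities
#'
#' Deterministic posterior expectation on the committed tree: each internal
#' node contributes its stopping probability as uniform mass over its
#' region, the remainder flows to the committed children in proportion to
#' the Beta allocation means `(N_child + alpha) / (N + 2 alpha)`; leaves are
#' uniform. The symmetric Dirichlet cell extension has mean `1/C(A)`
#' regardless of `beta`, so stopped regions are exactly uniform in
#' expectation.
#'
#' @param tree A fitted [opt_fit()] tree.
#' @return A block-structured [prob_table()] with total mass 1.
#' @export
expected_cell_probabilities <- function(tree) {
  blocks <- vector("list", tree$n_nodes)
  k <- 0L
  walk <- function(node, mass) {
    if (is.null(node$children)) {
      k <<- k + 1L
      blocks[[k]] <<- list(region = node$region, mass = mass)
      return(invisible())
    }
    if (node$stop_prob > 0) {
      k <<- k + 1L
      blocks[[k]] <<- list(region = node$region,
                           mass = mass * node$stop_prob)
    }
    go <- mass * (1 - node$stop_prob)
    walk(node$children[[1L]], go * node$split$etheta)
    walk(node$children[[2L]], go * (1 - node$split$etheta))
  }
  walk(tree$root, 1)
  prob_table(tree$space, blocks = blocks[seq_len(k)])
}

#' Posterior-mode partition and distribution
#'
#' Descends the committed tree keeping the stop action wherever its
#' posterior weight is at least that of the best split; the retained
#' terminal regions tile the space and receive their posterior-mean mass
#' spread uniformly over their cells.
#'
#' @param tree A fitted [opt_fit()] tree.
#' @return A list with `regions` (the terminal partition) and `table`
#'   (a block [prob_table()] with one disjoint block per terminal region).
#' @export
mode_tree <- function(tree) {
  regions <- list()
  blocks <- list()
  walk <- function(node, mass) {
    split_w <- if (is.null(node$children)) 0
               else (1 - node$stop_prob) * max(node$sel)
    if (is.null(node$children) || node$stop_prob >= split_w) {
      regions[[length(regions) + 1L]] <<- node$region
      blocks[[length(blocks) + 1L]] <<- list(region = node$region,
                                             mass = mass)
      return(invisible())
    }
    go <- mass # mode commits the split: full mass flows down
    walk(node$children[[1L]], go * node$split$etheta)
    walk(node$children[[2L]], go * (1 - node$split$etheta))
  }
  walk(tree$root, 1)
  tbl <- prob_table(tree$space, blocks = blocks)
  # renormalize: committed-stop mass deeper in pruned branches is cut off
  tot <- total_mass(tbl)
  for (i in seq_along(tbl$blocks)) tbl$blocks[[i]]$mass <-
    tbl$blocks[[i]]$mass / tot
  list(regions = regions, table = tbl)
}

#' Draw a random distribution from the posterior
#'
#' Follows the committed tree stochastically: each region stops with its
#' stopping probability (cell masses then drawn from the symmetric
#' Dirichlet `N/C + beta`), otherwise the committed split is taken with
#' allocation `theta ~ Beta(N1 + alpha, N2 + alpha)`.
#'
#' @param tree A fitted [opt_fit()] tree.
#' @param seed Optional integer seed for reproducible draws.
#' @param max_cells Guard on the number of explicit cells a stopped region
#'   may materialize; default `1e5`.
#' @return A [prob_table()] with explicit cells summing to 1.
#' @export
posterior_sample <- function(tree, seed = NULL, max_cells = 1e5) {
  if (!is.null(seed)) set.seed(seed)
  m <- space_sizes(tree$space)
  alpha <- tree$params$alpha
  beta <- tree$params$beta
  cells <- list()
  probs <- list()
  stop_here <- function(node, mass) {
    C <- region_cell_count(node$region)
    if (C > max_cells)
      stop("stopped region with ", C, " cells exceeds max_cells")
    g <- stats::rgamma(C, shape = node$n / C + beta)
    if (all(g == 0)) g <- rep(1, C) # degenerate underflow guard
    cells[[length(cells) + 1L]] <<- decode_cell_index(
      region_cell_indices(node$region, m), m)
    probs[[length(probs) + 1L]] <<- mass * g / sum(g)
  }
  walk <- function(node, mass) {
    if (is.null(node$children) || stats::runif(1) < node$stop_prob)
      return(stop_here(node, mass))
    g1 <- stats::rgamma(1, node$split$n1 + alpha)
    g2 <- stats::rgamma(1, node$split$n2 + alpha)
    th <- if (g1 + g2 > 0) g1 / (g1 + g2) else 0.5
    walk(node$children[[1L]], mass * th)
    walk(node$children[[2L]], mass * (1 - th))
  }
  walk(tree$root, 1)
  prob_table(tree$space, cells = do.call(rbind, cells),
             prob = unlist(probs))
}

# --- S3 model methods ------------------------------------------------------

#' @export
print.opt_tree <- function(x, ...) {
  cat("Optional Polya tree (", x$partition, " partitioning, lookahead h = ",
      x$params$lookahead, ")\n", sep = "")
  m <- space_sizes(x$space)
  cat("  space: ", length(m), " variable(s), ",
      format(prod(m), big.mark = ","), " cells; n = ", format(x$n),
      "\n", sep = "")
  cat("  tree: ", x$n_nodes, " nodes, ", x$n_leaves, " leaves, depth ",
      x$max_depth, "\n", sep = "")
  cat("  root stop probability: ", format(x$root$stop_prob, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.opt_tree <- function(object, ...) {
  leaves <- list()
  walk <- function(node) {
    if (is.null(node$children)) {
      leaves[[length(leaves) + 1L]] <<- c(
        n = node$n, cells = region_cell_count(node$region),
        depth = node$depth, stop_prob = node$stop_prob)
      return(invisible())
    }
    walk(node$children[[1L]])
    walk(node$children[[2L]])
  }
  walk(object$root)
  leaves <- as.data.frame(do.call(rbind, leaves))
  structure(list(tree = object, leaves = leaves), class = "summary.opt_tree")
}

#' @export
print.summary.opt_tree <- function(x, ...) {
  print(x$tree)
  lv <- x$leaves
  cat("Terminal regions:", nrow(lv), "\n")
  cat("  zero-sample:", sum(lv$n == 0), "; single-cell:",
      sum(lv$cells == 1), "\n")
  cat("  leaf sample counts: ")
  print(summary(lv$n))
  cat("  leaf cell counts: ")
  print(summary(lv$cells))
  invisible(x)
}

#' Coefficients of a fitted tree: the terminal-region masses
#'
#' @param object A fitted [opt_fit()] tree.
#' @param ... Unused.
#' @return Data frame with one row per leaf: per-variable retained category
#'   counts, sample count `n`, `cells`, and the posterior-mean mass of the
#'   leaf block.
#' @export
coef.opt_tree <- function(object, ...) {
  rows <- list()
  walk <- function(node, mass) {
    if (is.null(node$children)) {
      sizes <- lengths(node$region)
      rows[[length(rows) + 1L]] <<- data.frame(
        t(stats::setNames(sizes, paste0("m_", object$space$variables))),
        n = node$n, cells = region_cell_count(node$region),
        depth = node$depth, mass = mass, check.names = FALSE)
      return(invisible())
    }
    go <- mass * (1 - node$stop_prob)
    walk(node$children[[1L]], go * node$split$etheta)
    walk(node$children[[2L]], go * (1 - node$split$etheta))
  }
  walk(object$root, 1)
  do.call(rbind, rows)
}

#' Predict cell probabilities from a fitted tree
#'
#' Without `newdata`, returns the full estimated distribution as a
#' [prob_table()] (`type = "mean"` is the deterministic posterior
#' expectation; `"mode"` the posterior-mode partition; `"sample"` one
#' random posterior draw). With `newdata`, returns the posterior-mean
#' probability of each supplied combination cell.
#'
#' @param object A fitted [opt_fit()] tree.
#' @param newdata Optional data frame of label-valued combinations (one
#'   column per variable).
#' @param type Inference mode; default `"mean"`.
#' @param seed Seed for `type = "sample"`.
#' @param ... Unused.
#' @return A [prob_table()], or a numeric vector when `newdata` is given.
#' @export
predict.opt_tree <- function(object, newdata = NULL,
                             type = c("mean", "mode", "sample"),
                             seed = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(switch(type,
                  mean = expected_cell_probabilities(object),
                  mode = mode_tree(object)$table,
                  sample = posterior_sample(object, seed = seed)))
  }
  if (type != "mean")
    stop("cell lookup with 'newdata' supports type = \"mean\" only")
  newdata <- as.data.frame(newdata)
  vars <- object$space$variables
  if (!all(vars %in% names(newdata)))
    stop("'newdata' must contain the variable columns ",
         paste(vars, collapse = ", "))
  xs <- matrix(0L, nrow(newdata), length(vars))
  for (i in seq_along(vars)) {
    idx <- match(as.character(newdata[[vars[i]]]),
                 object$space$categories[[i]])
    if (anyNA(idx)) stop("unknown label(s) in column '", vars[i], "'")
    xs[, i] <- idx
  }
  vapply(seq_len(nrow(xs)), function(r)
    cell_prob_walk(object$root, xs[r, ]), numeric(1))
}

cell_prob_walk <- function(node, cell) {
  pr <- 0
  mass <- 1
  repeat {
    if (is.null(node$children))
      return(pr + mass / region_cell_count(node$region))
    pr <- pr + mass * node$stop_prob / region_cell_count(node$region)
    mass <- mass * (1 - node$stop_prob)
    v <- node$split$variable
    if (cell[v] %in% node$split$left) {
      mass <- mass * node$split$etheta
      node <- node$children[[1L]]
    } else {
      mass <- mass * (1 - node$split$etheta)
      node <- node$children[[2L]]
    }
  }
}

#' Simulate observations from the fitted distribution
#'
#' Draws `nsim` observations from the posterior-mean distribution by
#' descending the committed tree (stop: uniform cell in the region;
#' continue: child chosen by its expected allocation).
#'
#' @param object A fitted [opt_fit()] tree.
#' @param nsim Number of observations; default 1.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame of `nsim` label-valued rows.
#' @export
simulate.opt_tree <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- space_sizes(object$space)
  one <- function() {
    node <- object$root
    repeat {
      if (is.null(node$children) || stats::runif(1) < node$stop_prob) {
        return(vapply(node$region, function(a)
          a[sample.int(length(a), 1L)], integer(1)))
      }
      node <- if (stats::runif(1) < node$split$etheta)
        node$children[[1L]] else node$children[[2L]]
    }
  }
  xs <- t(vapply(seq_len(nsim), function(i) one(), integer(length(m))))
  out <- as.data.frame(lapply(seq_along(m), function(i)
    object$space$categories[[i]][xs[, i]]))
  names(out) <- object$space$variables
  out
}

#' Plot the terminal regions of a fitted tree
#'
#' Scatter of leaf sample count against leaf cell count (log axes), the
#' basic diagnostic of how the partition allocates resolution: many-cell
#' zero-sample leaves sit on the x-axis, dense single cells at the top
#' left.
#'
#' @param x A fitted [opt_fit()] tree.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.opt_tree <- function(x, ...) {
  lv <- summary(x)$leaves
  graphics::plot(lv$cells, lv$n + 0.5, log = "xy",
                 xlab = "cells in terminal region",
                 ylab = "samples in terminal region (+0.5)",
                 main = "Terminal regions", ...)
  invisible(x)
}
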