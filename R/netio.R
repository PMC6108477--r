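# File I/O: count matrices, probability tables, tree serialization,
# count thinning, and the terminal-region co-occurrence network.

#' Read a count matrix as a two-variable observation set
#'
#' A read-count (or any contingency) matrix is treated as observations of
#' two factor variables, `row` and `col`, with the matrix entries as
#' weights: total weight equals the matrix sum.
#'
#' @param path MatrixMarket coordinate file (`.mtx`) or TSV matrix with row
#'   labels in the first column and column labels in the header.
#' @param format `"auto"` (by extension), `"mtx"`, or `"tsv"`.
#' @return An [observations()] set over the two-variable space. MatrixMarket
#'   files carry no labels, so rows/columns are labelled `r1..`/`c1..`.
#' @export
read_count_matrix <- function(path, format = c("auto", "mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (format == "mtx") {
    mm <- Matrix::readMM(path)
    dn <- list(paste0("r", seq_len(nrow(mm))), paste0("c", seq_len(ncol(mm))))
    df <- as.data.frame(Matrix::summary(mm))
  } else {
    tb <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
    mat <- as.matrix(tb)
    if (!is.numeric(mat)) stop("non-numeric entries in count matrix")
    dn <- list(rownames(mat), colnames(mat))
    nz <- which(mat != 0, arr.ind = TRUE)
    df <- data.frame(i = nz[, 1L], j = nz[, 2L], x = mat[nz])
  }
  if (any(df$x < 0)) stop("negative counts in matrix")
  df <- df[df$x > 0, , drop = FALSE]
  if (!nrow(df)) stop("count matrix is empty")
  space <- factor_space(c("row", "col"), dn)
  new_observations(space, cbind(df$i, df$j), df$x)
}

#' Write a weighted two-variable observation set as a MatrixMarket file
#'
#' @param obs A two-variable [observations()] set.
#' @param path Output `.mtx` path.
#' @export
write_count_matrix <- function(obs, path) {
  if (ncol(obs$x) != 2L) stop("count matrices need exactly two variables")
  m <- space_sizes(obs$space)
  sm <- Matrix::sparseMatrix(i = obs$x[, 1L], j = obs$x[, 2L], x = obs$w,
                             dims = m)
  Matrix::writeMM(sm, path)
  invisible(path)
}

#' Binomial thinning of observation counts
#'
#' Each unit of weight is kept independently with probability `fraction`;
#' rows thinned to zero are dropped. Requires integer weights.
#'
#' @param obs An [observations()] set with integer weights.
#' @param fraction Keep probability in `(0, 1]`.
#' @param seed Optional integer seed.
#' @return A thinned [observations()] set over the same space.
#' @export
subsample_counts <- function(obs, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  if (any(obs$w != round(obs$w)))
    stop("binomial thinning requires integer weights")
  if (!is.null(seed)) set.seed(seed)
  w2 <- stats::rbinom(length(obs$w), size = as.integer(round(obs$w)),
                      prob = fraction)
  keep <- w2 > 0
  if (!any(keep)) stop("subsampling removed every observation")
  new_observations(obs$space, obs$x[keep, , drop = FALSE], w2[keep])
}

#' Co-occurrence network of terminal regions
#'
#' Categorical values that share a terminal region of the committed tree
#' are taken as co-occurring: for every terminal region with at least one
#' sample, each unordered pair of distinct labels present in the region
#' (within and across variables) gains weight 1 (or the region's sample
#' count with `weight = "samples"`). Zero-sample terminal regions are
#' excluded.
#'
#' @param tree A fitted [opt_fit()] tree.
#' @param top_k Number of edges to return, by descending weight (ties by
#'   label order); default 20.
#' @param weight `"regions"` (count terminal regions, the default) or
#'   `"samples"` (sum region sample counts).
#' @return Data frame with columns `code_a`, `code_b`, `weight`.
#' @export
cooccurrence_network <- function(tree, top_k = 20,
                                 weight = c("regions", "samples")) {
  weight <- match.arg(weight)
  env <- new.env(parent = emptyenv())
  cats <- tree$space$categories
  walk <- function(node) {
    if (!is.null(node$children)) {
      walk(node$children[[1L]])
      walk(node$children[[2L]])
      return(invisible())
    }
    if (node$n <= 0) return(invisible())
    labs <- sort(unique(unlist(lapply(seq_along(node$region), function(i)
      cats[[i]][node$region[[i]]]), use.names = FALSE)))
    if (length(labs) < 2L) return(invisible())
    inc <- if (weight == "regions") 1 else node$n
    pairs <- utils::combn(labs, 2L)
    keys <- paste(pairs[1L, ], pairs[2L, ], sep = "\r")
    for (k in keys)
      assign(k, inc + (if (exists(k, envir = env)) get(k, envir = env)
                       else 0), envir = env)
  }
  walk(tree$root)
  keys <- ls(env)
  if (!length(keys))
    return(data.frame(code_a = character(), code_b = character(),
                      weight = numeric()))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(code_a = vapply(parts, `[`, "", 1L),
                    code_b = vapply(parts, `[`, "", 2L),
                    weight = vapply(keys, get, 0, envir = env,
                                    USE.NAMES = FALSE))
  out <- out[order(-out$weight, out$code_a, out$code_b), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

# --- serialization --------------------------------------------------------

serialize_node <- function(node, cats) {
  out <- list(
    region = lapply(seq_along(node$region), function(i)
      cats[[i]][node$region[[i]]]),
    n = node$n, depth = node$depth,
    log_phi = node$log_phi, log_phi0 = node$log_phi0,
    stop_prob = node$stop_prob, terminal = node$terminal)
  if (!is.null(node$sel)) out$selection_probs <- as.list(node$sel)
  if (!is.null(node$split)) {
    v <- node$split$variable
    out$split <- list(variable = v,
                      left_labels = cats[[v]][node$split$left],
                      n1 = node$split$n1, n2 = node$split$n2)
    out$children <- list(serialize_node(node$children[[1L]], cats),
                         serialize_node(node$children[[2L]], cats))
  }
  out
}

#' Serialize a fitted tree to JSON
#'
#' Regions and splits are written as label lists, never as indices, so the
#' file round-trips across sessions regardless of category storage order.
#'
#' @param tree A fitted [opt_fit()] tree.
#' @param path Output path.
#' @export
write_opt_tree <- function(tree, path) {
  obj <- list(format = "optcat_tree", version = 1L,
              variables = tree$space$variables,
              categories = tree$space$categories,
              params = unclass(tree$params),
              partition = tree$partition,
              n = tree$n, n_rows = tree$n_rows, n_nodes = tree$n_nodes,
              n_leaves = tree$n_leaves, max_depth = tree$max_depth,
              root = serialize_node(tree$root, tree$space$categories))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

deserialize_node <- function(nd, space, alpha) {
  cats <- space$categories
  region <- lapply(seq_along(cats), function(i)
    match(unlist(nd$region[[i]]), cats[[i]]))
  node <- list(region = region, n = nd$n, depth = nd$depth,
               log_phi = nd$log_phi, log_phi0 = nd$log_phi0,
               stop_prob = nd$stop_prob,
               sel = if (!is.null(nd$selection_probs))
                 unlist(nd$selection_probs) else NULL,
               split = NULL, children = NULL, terminal = nd$terminal)
  if (!is.null(nd$split)) {
    v <- nd$split$variable
    left <- match(unlist(nd$split$left_labels), cats[[v]])
    node$split <- list(variable = v, left = left,
                       right = setdiff(region[[v]], left),
                       n1 = nd$split$n1, n2 = nd$split$n2,
                       etheta = (nd$split$n1 + alpha) /
                         (nd$n + 2 * alpha))
    node$children <- list(
      deserialize_node(nd$children[[1L]], space, alpha),
      deserialize_node(nd$children[[2L]], space, alpha))
  }
  node
}

#' Read a serialized tree
#'
#' @param path A JSON file written by [write_opt_tree()].
#' @return An `"opt_tree"` object equivalent to the one written.
#' @export
read_opt_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "optcat_tree")) stop("not an optcat tree file")
  space <- factor_space(unlist(obj$variables),
                        lapply(obj$categories, unlist))
  params <- do.call(opt_params, obj$params[c("rho", "alpha", "beta",
                                             "lookahead", "commit_q")])
  structure(list(space = space, params = params,
                 partition = obj$partition,
                 root = deserialize_node(obj$root, space, params$alpha),
                 n = obj$n, n_rows = obj$n_rows, n_nodes = obj$n_nodes,
                 n_leaves = obj$n_leaves, max_depth = obj$max_depth,
                 call = NULL),
            class = "opt_tree")
}

#' Write a probability table as TSV
#'
#' One row per nonzero cell: the label columns followed by `probability`.
#'
#' @param pt A [prob_table()].
#' @param path Output path.
#' @param max_cells Materialization guard (see
#'   [as.data.frame.prob_table()]).
#' @export
write_prob_table <- function(pt, path, max_cells = 2^22) {
  df <- as.data.frame(pt, max_cells = max_cells)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probability table from TSV
#'
#' @param path A file written by [write_prob_table()].
#' @param space Optional [factor_space()]; when omitted, a space is built
#'   from the labels present in the file (absent cells are zero).
#' @return A sparse [prob_table()] of explicit cells.
#' @export
read_prob_table <- function(path, space = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (!"probability" %in% names(df)) stop("no 'probability' column")
  prob <- as.numeric(df$probability)
  df <- df[setdiff(names(df), "probability")]
  if (is.null(space))
    space <- factor_space(names(df), lapply(df, function(v)
      sort(unique(v))))
  cells <- matrix(0L, nrow(df), ncol(df))
  for (i in seq_along(df)) {
    idx <- match(df[[i]], space$categories[[i]])
    if (anyNA(idx)) stop("label not in the supplied space: column ",
                         names(df)[i])
    cells[, i] <- idx
  }
  prob_table(space, cells = cells, prob = prob)
}
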