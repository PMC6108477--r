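# shared micro fixtures and brute-force oracles

# the 1-variable, 2-category space with counts (1, 1) and (2, 0):
# closed forms with rho = alpha = 0.5 follow from exact Gamma identities
obs_11 <- function() observations(data.frame(x = c("a", "b")))
obs_20 <- function() observations(data.frame(x = c("a", "a")),
                                  categories = list(x = c("a", "b")))

# random small observation set over p variables with sizes m
rand_obs <- function(n, m, weights = FALSE) {
  p <- length(m)
  df <- as.data.frame(lapply(seq_len(p), function(i)
    paste0("v", i, "_", sample.int(m[i], n, replace = TRUE))))
  names(df) <- paste0("X", seq_len(p))
  cats <- lapply(seq_len(p), function(i) paste0("v", i, "_", seq_len(m[i])))
  names(cats) <- names(df)
  if (weights) df$count <- sample(1:3, n, replace = TRUE)
  observations(df, categories = cats)
}

# random subregion of a space (each variable keeps a nonempty subset)
rand_region <- function(space) {
  lapply(space_sizes(space), function(mi)
    sort(sample.int(mi, sample.int(mi, 1L))))
}

# brute-force region membership count
oracle_region_count <- function(A, obs) {
  tot <- 0
  for (r in seq_len(nrow(obs$x))) {
    inside <- all(vapply(seq_along(A), function(i)
      obs$x[r, i] %in% A[[i]], logical(1)))
    if (inside) tot <- tot + obs$w[r]
  }
  tot
}

# brute-force within-group sum of squared deviations
oracle_dispersion <- function(M_sorted, s) {
  g1 <- M_sorted[seq_len(s)]
  g2 <- M_sorted[-seq_len(s)]
  sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
}

# dense brute-force RSSE over every cell of the space
oracle_rsse <- function(est, truth) {
  sqrt(sum((optcat:::pt_dense(est) - optcat:::pt_dense(truth))^2))
}
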