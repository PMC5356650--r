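# Independent brute-force implementation of the running-sum pre-DRS,
# written as explicit loops over i and j. Used as the oracle against the
# vectorized engine; must stay independent of the package internals.

brute_running_sums <- function(g, d) {
  n <- length(g)
  tf <- 0
  tb <- 0
  for (j in seq_len(n)) {
    tf <- tf + abs(g[j] * d[j])
    tb <- tb + abs(g[j] * (1 - d[j]))
  }
  f <- numeric(n)
  b <- numeric(n)
  for (i in seq_len(n)) {
    sf <- 0
    sb <- 0
    for (j in seq_len(i)) {
      sf <- sf + abs(g[j] * d[j])
      sb <- sb + abs(g[j] * (1 - d[j]))
    }
    f[i] <- sf / tf
    b[i] <- sb / tb
  }
  list(f = f, b = b)
}

brute_pdrs <- function(g, d) {
  rs <- brute_running_sums(g, d)
  best_max <- -Inf
  best_min <- Inf
  for (i in seq_along(rs$f)) {
    dd <- rs$f[i] - rs$b[i]
    if (dd > best_max) best_max <- dd
    if (dd < best_min) best_min <- dd
  }
  pos <- max(best_max, 0)
  neg <- min(best_min, 0)
  if (pos > abs(neg)) pos else neg
}

# random valid (g sorted descending, d in [0,1] with both groups nonempty)
random_instance <- function(n) {
  g <- sort(stats::rnorm(n), decreasing = TRUE)
  repeat {
    d <- ifelse(stats::runif(n) < 0.5, stats::runif(n), 0)
    if (any(d > 0) && sum(abs(g * (1 - d))) > 0 && sum(abs(g * d)) > 0)
      break
  }
  list(g = g, d = d)
}

# small two-group signature profile used across engine tests
toy_profile <- function(n_genes = 60, n_up = 10, n_dn = 10, seed = 42) {
  ids <- sprintf("t%03d", seq_len(n_genes))
  score <- numeric(n_genes)
  set.seed(seed)
  score[seq_len(n_up)] <- runif(n_up, 5, 20)
  score[n_up + seq_len(n_dn)] <- -runif(n_dn, 5, 20)
  drug_profile(ids, score, drug_name = "toy_drug")
}
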