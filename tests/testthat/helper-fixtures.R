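# Shared fixtures and independent oracles used across the test files.

# small expression matrix: k time groups x r replicates, given per-group gene means
make_expr <- function(means, timepoints = seq_len(ncol(means)) - 1,
                      replicates = 3, noise_sd = 0, seed = 1) {
  G <- nrow(means); Tn <- ncol(means)
  withr::with_seed(seed, {
    vals <- means[, rep(seq_len(Tn), each = replicates), drop = FALSE] +
      matrix(rnorm(G * Tn * replicates, 0, noise_sd), G)
  })
  samples <- paste0("t", rep(seq_len(Tn), each = replicates), "_r",
                    rep(seq_len(replicates), Tn))
  colnames(vals) <- samples
  rownames(vals) <- rownames(means) %||% sprintf("g%d", seq_len(G))
  design <- data.frame(sample = samples,
                       time_hours = rep(timepoints, each = replicates),
                       replicate = rep(seq_len(replicates), Tn))
  expression_matrix(vals, design)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force hypergeometric upper tail by enumeration of dhyper terms
# computed from factorials -- independent of phyper
hyper_tail_oracle <- function(n_f, n, N_f, N) {
  kmax <- min(n, N_f)
  if (n_f > kmax) return(0)
  terms <- vapply(n_f:kmax, function(k) {
    exp(lchoose(N_f, k) + lchoose(N - N_f, n - k) - lchoose(N, n))
  }, numeric(1))
  sum(terms)
}

# brute-force union-find for weakly connected components of a directed edge list
components_oracle <- function(src, tgt) {
  nodes <- sort(unique(c(src, tgt)))
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_along(src)) {
    a <- find(match(src[e], nodes)); b <- find(match(tgt[e], nodes))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  split(nodes, roots)
}

# scalar one-way RVM F-test oracle for a single gene, transliterating the
# shrunken-variance formula on plain vectors
rvm_scalar_oracle <- function(values, groups, a, b) {
  groups <- factor(groups)
  k <- nlevels(groups); N <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  counts <- tapply(values, groups, length)
  ms_between <- sum(counts * (means - gm)^2) / (k - 1)
  ss_within <- sum((values - means[as.integer(groups)])^2)
  d2 <- N - k
  s2 <- ss_within / d2
  shrunk <- (d2 * s2 + 2 / b) / (d2 + 2 * a)
  f <- ms_between / shrunk
  list(f = f, p = pf(f, k - 1, d2 + 2 * a, lower.tail = FALSE))
}

# simulate gene-wise residual variances from the random variance model:
# precision ~ Gamma(shape a, scale b), s2 = sigma^2 * chisq_d / d
rvm_variances <- function(n_genes, a, b, d, seed) {
  withr::with_seed(seed, {
    prec <- rgamma(n_genes, shape = a, scale = b)
    (1 / prec) * rchisq(n_genes, d) / d
  })
}
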