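#' One-sided Fisher's exact p-value for category over-representation
#'
#' With `N` genes on the platform of which `N_f` are differential, and a
#' category of `n` genes containing `n_f` differential ones, returns the
#' hypergeometric upper tail \eqn{P(X \ge n_f)} — the probability of seeing
#' at least the observed overlap by chance.
#'
#' @param n_f Differential genes in the category.
#' @param n Category size (on the platform).
#' @param N_f Total differential genes.
#' @param N Total genes on the platform.
#' @return p-value in `[0, 1]`. All arguments vectorized.
#' @examples
#' fisher_exact_p(3, 3, 3, 10)  # 1 / choose(10, 3) = 1/120
#' @export
fisher_exact_p <- function(n_f, n, N_f, N) {
  check_counts(n_f, n, N_f, N)
  phyper(n_f - 1, N_f, N - N_f, n, lower.tail = FALSE)
}

check_counts <- function(n_f, n, N_f, N) {
  bad <- n_f < 0 | n < 0 | N_f < 0 | N < 1 | n_f > pmin(n, N_f) |
    n > N | N_f > N
  if (any(bad))
    stop("inconsistent 2x2 counts: need 0 <= n_f <= min(n, N_f), n <= N, N_f <= N")
  invisible(TRUE)
}

#' Pearson chi-squared p-value on the 2x2 membership table
#'
#' Chi-squared test (1 df, no continuity correction) of independence between
#' category membership and differential status. Tables with any zero
#' expected cell are flagged undefined (`NA`), and such records are excluded
#' from the comparative FDR rule.
#'
#' @inheritParams fisher_exact_p
#' @return p-value in `[0, 1]`, or `NA` where an expected cell is zero.
#' @export
chi2_p <- function(n_f, n, N_f, N) {
  check_counts(n_f, n, N_f, N)
  a <- n_f; b <- n - n_f; c <- N_f - n_f; d <- N - n - N_f + n_f
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  undef <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  stat <- ifelse(undef, NA_real_, N * (a * d - b * c)^2 / (r1 * r2 * c1 * c2))
  ifelse(undef, NA_real_, pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Enrichment ratio Re
#'
#' Observed over expected representation of differential genes in a
#' category: \eqn{Re = (n_f / n) / (N_f / N)}.
#'
#' @inheritParams fisher_exact_p
#' @return Non-negative ratio; 1 means proportional representation.
#' @examples
#' enrichment_ratio(6, 20, 100, 1000)  # 3
#' @export
enrichment_ratio <- function(n_f, n, N_f, N) {
  check_counts(n_f, n, N_f, N)
  if (any(n == 0) || any(N_f == 0)) stop("n and N_f must be positive")
  (n_f / n) / (N_f / N)
}

#' Comparative Fisher-vs-chi-squared false discovery rate
#'
#' A batch-level FDR built from the disagreement of the two tests: with
#' \eqn{N_k} the number of categories whose Fisher p-value is strictly less
#' than their chi-squared p-value, over T valid categories,
#' \deqn{FDR = 1 - N_k / T.} Pairs with an undefined chi-squared p-value are
#' excluded from both counts.
#'
#' @param p_fisher,p_chi2 Aligned numeric vectors of per-category p-values.
#' @return Single FDR value in `[0, 1]`.
#' @examples
#' fisher_chi2_fdr(c(0.01, 0.2), c(0.02, 0.1))  # N_k = 1 of 2 -> 0.5
#' @export
fisher_chi2_fdr <- function(p_fisher, p_chi2) {
  if (length(p_fisher) != length(p_chi2))
    stop("p-value vectors must have the same length")
  if (length(p_fisher) == 0) stop("need at least one category")
  ok <- !is.na(p_chi2) & !is.na(p_fisher)
  if (!any(ok)) return(NA_real_)
  1 - sum(p_fisher[ok] < p_chi2[ok]) / sum(ok)
}

#' Gene-set over-representation analysis
#'
#' For every category (intersected with the universe, minimum size
#' `min_category_size`), computes the 2x2 counts, Fisher's exact and
#' chi-squared p-values, the enrichment ratio Re, Benjamini-Hochberg
#' q-values over the Fisher p-values, and the batch-level comparative FDR of
#' [fisher_chi2_fdr()] (attached to every record). Categories with
#' `p_fisher < p_threshold` are flagged significant.
#'
#' @param differential_genes Character vector of differential gene ids
#'   (must be a subset of `universe`).
#' @param universe Character vector of all gene ids on the platform.
#' @param sets A [gene_set_collection()].
#' @param p_threshold Significance threshold on the Fisher p-value
#'   (conventions: 0.05 for GO-style screens, 0.001 for KEGG pathways).
#' @param min_category_size Smallest in-universe category size tested.
#' @return Data frame sorted by Fisher p (ties: descending Re, then
#'   category id): `category`, `description`, `n_f`, `n`, `N_f`, `N`,
#'   `p_fisher`, `p_chi2`, `q_bh`, `fdr`, `re`, `significant`.
#' @export
enrich <- function(differential_genes, universe, sets, p_threshold = 0.05,
                   min_category_size = 2) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty gene universe")
  differential_genes <- unique(as.character(differential_genes))
  outside <- setdiff(differential_genes, universe)
  if (length(outside))
    stop("differential gene(s) outside the universe: ",
         paste(head(outside, 5), collapse = ", "))
  N <- length(universe)
  N_f <- length(differential_genes)
  in_univ <- lapply(sets$sets, intersect, universe)
  n <- lengths(in_univ)
  keep <- n >= min_category_size
  in_univ <- in_univ[keep]
  n <- n[keep]
  if (!length(in_univ)) {
    res <- data.frame(category = character(), description = character(),
                      n_f = integer(), n = integer(), N_f = integer(),
                      N = integer(), p_fisher = numeric(), p_chi2 = numeric(),
                      q_bh = numeric(), fdr = numeric(), re = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    return(res)
  }
  n_f <- vapply(in_univ, function(g) length(intersect(g, differential_genes)),
                integer(1))
  p_f <- fisher_exact_p(n_f, n, N_f, N)
  p_c <- chi2_p(n_f, n, N_f, N)
  re <- if (N_f > 0) enrichment_ratio(n_f, n, N_f, N) else rep(NA_real_, length(n))
  res <- data.frame(category = names(in_univ),
                    description = unname(sets$descriptions[names(in_univ)]),
                    n_f = n_f, n = as.integer(n), N_f = N_f, N = N,
                    p_fisher = p_f, p_chi2 = p_c,
                    q_bh = adjust_fdr_bh(p_f),
                    fdr = fisher_chi2_fdr(p_f, p_c),
                    re = re,
                    significant = p_f < p_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(res$p_fisher, -res$re, res$category)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}
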