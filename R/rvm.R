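#' Random variance model hyperparameters
#'
#' In the random variance model the per-gene precision is shared across the
#' array: \eqn{1/\sigma^2 \sim \mathrm{Gamma}(a, b)} (scale parametrization),
#' so that the scaled residual variance \eqn{a b s^2} follows an
#' \eqn{F(d, 2a)} distribution when \eqn{s^2} has \eqn{d} residual degrees of
#' freedom. Borrowing this distribution across genes raises the effective
#' degrees of freedom of each gene's variance estimate — the point of the
#' model for short, lightly replicated time courses.
#'
#' @param a,b Positive hyperparameters.
#' @return An object of class `RVMParams`.
#' @export
rvm_params <- function(a, b) {
  if (!(a > 0 && b > 0)) stop("hyperparameters must be positive")
  structure(list(a = a, b = b), class = "RVMParams")
}

#' @export
print.RVMParams <- function(x, ...) {
  cat(sprintf("RVMParams: a = %.4g, b = %.4g (adds 2a = %.3g df)\n",
              x$a, x$b, 2 * x$a))
  invisible(x)
}

#' Estimate random variance model hyperparameters by maximum likelihood
#'
#' Fits (a, b) so that the observed gene-wise residual variances maximize the
#' likelihood under \eqn{a b s^2 \sim F(d, 2a)}. Optimization is over
#' log-parameters with Nelder-Mead from a moment-based start and is
#' deterministic.
#'
#' @param residual_variances Per-gene pooled residual variances (>= 0; zeros
#'   are excluded with a warning).
#' @param residual_df Residual degrees of freedom of each variance.
#' @return An [rvm_params()] object with attribute `logLik`.
#' @export
estimate_rvm_hyperparams <- function(residual_variances, residual_df) {
  x <- residual_variances
  if (length(x) == 0) stop("no residual variances supplied")
  if (any(x < 0)) stop("residual variances must be non-negative")
  if (any(x == 0)) {
    warning(sum(x == 0), " zero variance(s) excluded from RVM estimation")
    x <- x[x > 0]
  }
  if (length(x) == 0) stop("no positive residual variances remain")
  if (length(x) < 50)
    warning("fewer than 50 genes; RVM hyperparameter estimates are unstable")
  if (max(x) / min(x) < 1 + 1e-10)
    stop("residual variances are (numerically) identical: ",
         "variance spread is degenerate, RVM hyperparameters unidentifiable")
  stopifnot(residual_df > 0)
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(log(a * b) + stats::df(a * b * x, residual_df, 2 * a, log = TRUE))
  }
  # moment start: E[s^2] = 1 / (b (a - 1)) for a > 1
  a0 <- 2
  b0 <- 1 / (mean(x) * (a0 - 1))
  fit <- optim(c(log(a0), log(b0)), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  if (fit$convergence != 0)
    stop("RVM hyperparameter optimization did not converge (code ",
         fit$convergence, ") at a = ", exp(fit$par[1]),
         ", b = ", exp(fit$par[2]))
  out <- rvm_params(exp(fit$par[1]), exp(fit$par[2]))
  attr(out, "logLik") <- -fit$value
  out
}

# Per-gene one-way decomposition across time groups: between-group mean
# square, pooled within-group variance and its df. Vectorized over genes.
time_group_anova <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  groups <- factor(x$design$time_hours)
  k <- nlevels(groups)
  if (k < 2) stop("need >= 2 time groups")
  N <- ncol(x$values)
  if (N <= k) stop("need more samples than time groups")
  counts <- as.vector(table(groups))
  if (all(counts == 1)) stop("every group has a single replicate; no within-group variance")
  gm <- rowMeans(x$values)
  group_means <- vapply(levels(groups), function(g)
    rowMeans(x$values[, groups == g, drop = FALSE]), numeric(nrow(x$values)))
  group_means <- matrix(group_means, nrow = nrow(x$values))
  ss_between <- as.vector(group_means^2 %*% counts) - N * gm^2
  centered <- x$values - group_means[, as.integer(groups), drop = FALSE]
  ss_within <- rowSums(centered^2)
  list(ms_between = ss_between / (k - 1),
       s2 = ss_within / (N - k),
       df1 = k - 1, df2 = N - k, k = k)
}

#' Random variance model F-test across time groups
#'
#' One-way F-test of any expression change across the time points, with the
#' per-gene variance shrunk toward the RVM prior:
#' \deqn{\tilde{s}^2 = (d_2 s^2 + 2/b) / (d_2 + 2a)}
#' and the statistic referred to \eqn{F(k - 1, d_2 + 2a)}, where \eqn{k} is
#' the number of time groups and \eqn{d_2} the pooled within-group degrees of
#' freedom.
#'
#' @param x An [expression_matrix()] whose design defines the time groups.
#' @param params An [rvm_params()] object, or `NULL` to estimate the
#'   hyperparameters from this matrix's residual variances.
#' @return A data frame (one row per gene, input order): `gene_id`,
#'   `f_statistic`, `df1`, `df2`, `p_value`, `q_value`
#'   (Benjamini-Hochberg), `selected` (all `FALSE`; see [select_degs()]).
#'   The fitted `RVMParams` are attached as attribute `rvm_params`.
#' @export
rvm_f_test <- function(x, params = NULL) {
  an <- time_group_anova(x)
  if (is.null(params))
    params <- estimate_rvm_hyperparams(an$s2, an$df2)
  stopifnot(inherits(params, "RVMParams"))
  shrunk <- (an$df2 * an$s2 + 2 / params$b) / (an$df2 + 2 * params$a)
  f <- an$ms_between / shrunk
  df2 <- an$df2 + 2 * params$a
  p <- pf(f, an$df1, df2, lower.tail = FALSE)
  res <- data.frame(gene_id = gene_ids(x),
                    f_statistic = f,
                    df1 = an$df1, df2 = df2,
                    p_value = p,
                    q_value = adjust_fdr_bh(p),
                    selected = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "rvm_params") <- params
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
adjust_fdr_bh <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Select differentially expressed genes
#'
#' Flags genes with `p_value < p_threshold` and `q_value < q_threshold`
#' (both strict). Defaults follow the usual short time-course screen:
#' p < 0.01 with the FDR controlled at 5%.
#'
#' @param records Result of [rvm_f_test()].
#' @param p_threshold,q_threshold Strict upper bounds on p and q.
#' @return `records` with the `selected` column set.
#' @export
select_degs <- function(records, p_threshold = 0.01, q_threshold = 0.05) {
  stopifnot(all(c("p_value", "q_value") %in% names(records)))
  records$selected <- records$p_value < p_threshold &
    records$q_value < q_threshold
  records
}
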