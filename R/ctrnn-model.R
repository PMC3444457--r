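#' Construct a continuous-time recurrent neural network model
#'
#' The abstract dynamic model used for gene regulation:
#' \deqn{\tau_i \, dg_i/dt = -g_i + \sum_j W_{ij}\,\sigma(g_j + \theta_j) + I_i(t)}
#' where \eqn{g_i(t)} is the expression state of gene i, \eqn{\tau_i > 0} its
#' time constant in hours, \eqn{W_{ij}} the weight of gene j's influence on
#' gene i, \eqn{\theta_j} the offset of source gene j inside the sigmoid
#' \eqn{\sigma(x) = 1/(1+e^{-x})}, and \eqn{I_i(t)} an optional external
#' input (identically zero by default; the injury perturbation is carried by
#' the initial condition).
#'
#' @param gene_ids Character vector of n gene ids.
#' @param W n x n numeric matrix; `W[i, j]` is the influence of gene j on
#'   gene i.
#' @param tau Positive numeric vector of length n (hours).
#' @param theta Numeric vector of length n.
#' @param external_input `NULL` (no input) or a function `f(t)` returning a
#'   numeric vector of length n.
#' @param coupling Sigmoid placement. `"source"` (default) applies the
#'   sigmoid per source gene as in the display equation; `"summed"` applies
#'   it to the summed input instead:
#'   \eqn{\tau_i \, dg_i/dt = -g_i + \sigma(\theta_i + \sum_j W_{ij} g_j) + I_i(t)}
#'   (with the offset then indexed by the target gene).
#' @return An object of class `CTRNNModel`.
#' @export
ctrnn_model <- function(gene_ids, W, tau, theta, external_input = NULL,
                        coupling = c("source", "summed")) {
  coupling <- match.arg(coupling)
  n <- length(gene_ids)
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  W <- as.matrix(W)
  if (!all(dim(W) == n) || length(tau) != n || length(theta) != n)
    stop("model dimensions inconsistent with gene_ids")
  if (any(!is.finite(W)) || any(!is.finite(tau)) || any(!is.finite(theta)))
    stop("model parameters must be finite")
  if (any(tau <= 0)) stop("time constants must be positive")
  if (!is.null(external_input) && !is.function(external_input))
    stop("external_input must be NULL or a function of time")
  dimnames(W) <- list(gene_ids, gene_ids)
  structure(list(gene_ids = as.character(gene_ids), W = W,
                 tau = as.numeric(tau), theta = as.numeric(theta),
                 external_input = external_input, coupling = coupling),
            class = "CTRNNModel")
}

#' @export
print.CTRNNModel <- function(x, ...) {
  nz <- sum(x$W != 0)
  cat(sprintf("CTRNNModel: %d genes, %d nonzero weights\n",
              length(x$gene_ids), nz))
  invisible(x)
}

# Build the integration grid: fixed step from 0 to max(times); every
# observation time must fall on a grid node (within 1e-9).
integration_grid <- function(observation_times, step) {
  if (is.unsorted(observation_times, strictly = TRUE))
    stop("observation times must be strictly increasing")
  if (observation_times[1] < 0) stop("observation times must be >= 0")
  if (step <= 0) stop("step must be positive")
  if (length(observation_times) > 1 && step > min(diff(observation_times)) + 1e-12)
    stop("step must not exceed the minimum observation spacing")
  n_steps <- as.integer(round(max(observation_times) / step))
  idx <- round(observation_times / step)
  if (any(abs(observation_times - idx * step) > 1e-9))
    stop("step must divide every observation time")
  list(n_steps = n_steps, obs_idx = as.integer(idx))
}

#' Simulate CTRNN trajectories at given observation times
#'
#' Integrates the model with a classic fourth-order Runge-Kutta scheme on a
#' fixed grid from t = 0 and returns the states at the requested observation
#' times (which must all lie on the grid, i.e. be integer multiples of
#' `step`).
#'
#' @param model A [ctrnn_model()].
#' @param g0 Numeric initial state, one value per gene.
#' @param observation_times Strictly increasing, non-negative times (hours).
#' @param step Integration step (hours); must divide every observation time
#'   and be at most the minimum observation spacing.
#' @return Numeric matrix genes x times (rownames = gene ids, colnames =
#'   times).
#' @examples
#' # decoupled (W = 0) "summed" model: g(t) = 0.5 + 0.5 * exp(-t / 2)
#' m <- ctrnn_model("g1", matrix(0), tau = 2, theta = 0, coupling = "summed")
#' simulate_trajectories(m, g0 = 1, observation_times = c(0, 1, 3), step = 0.05)
#' @export
simulate_trajectories <- function(model, g0, observation_times, step = 0.05) {
  stopifnot(inherits(model, "CTRNNModel"))
  n <- length(model$gene_ids)
  if (length(g0) != n) stop("g0 must have one value per gene")
  grid <- integration_grid(observation_times, step)
  if (is.null(model$external_input)) {
    I <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    half_times <- seq(0, grid$n_steps * step, by = step / 2)
    I <- vapply(half_times, function(t) {
      v <- model$external_input(t)
      if (length(v) != n) stop("external_input must return one value per gene")
      as.numeric(v)
    }, numeric(n))
    I <- matrix(I, nrow = n)
  }
  traj <- ctrnn_integrate_cpp(model$W, model$tau, model$theta, as.numeric(g0),
                              grid$n_steps, step, I,
                              as.integer(model$coupling == "summed"))
  out <- traj[, grid$obs_idx + 1L, drop = FALSE]
  dimnames(out) <- list(model$gene_ids, observation_times)
  out
}
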