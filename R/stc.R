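#' Build discretized temporal-tendency templates
#'
#' Enumerates every piecewise-linear expression-tendency template over T time
#' points whose successive transitions are integers in
#' `[-max_unit_change, +max_unit_change]`, cumulated from 0 (so the first
#' entry of every template is 0 and the flat template is included).
#' Templates are ordered lexicographically by their transition sequence.
#'
#' @param n_timepoints Number of time points T (>= 2).
#' @param max_unit_change Cap on the per-step unit change (default 1, giving
#'   `3^(T-1)` templates).
#' @return An object of class `STCProfileSet`: list with `transitions`
#'   (templates x (T-1) integer matrix), `profiles` (templates x T), the
#'   index of the flat template, and empty slots for assignments and
#'   significance statistics.
#' @examples
#' ps <- build_profile_templates(3)   # 9 templates
#' ps$profiles
#' @export
build_profile_templates <- function(n_timepoints, max_unit_change = 1) {
  if (n_timepoints < 2) stop("need >= 2 time points")
  stopifnot(max_unit_change >= 1)
  steps <- seq(-max_unit_change, max_unit_change)
  s <- length(steps)
  Tm1 <- n_timepoints - 1
  K <- s^Tm1
  transitions <- matrix(0L, K, Tm1)
  for (j in seq_len(Tm1))
    transitions[, j] <- rep(steps, each = s^(Tm1 - j), times = s^(j - 1))
  cums <- transitions
  if (Tm1 > 1)
    for (j in 2:Tm1) cums[, j] <- cums[, j - 1] + transitions[, j]
  profiles <- cbind(0L, cums)
  flat <- which(rowSums(transitions != 0) == 0)
  structure(list(n_timepoints = n_timepoints,
                 max_unit_change = max_unit_change,
                 transitions = transitions,
                 profiles = profiles,
                 flat_index = flat,
                 assignments = NULL, gene_profiles = NULL, stats = NULL),
            class = "STCProfileSet")
}

#' @export
print.STCProfileSet <- function(x, ...) {
  cat(sprintf("STCProfileSet: %d templates over %d time points (cap %d)\n",
              nrow(x$profiles), x$n_timepoints, x$max_unit_change))
  if (!is.null(x$assignments))
    cat(sprintf("  %d genes assigned\n", nrow(x$assignments)))
  if (!is.null(x$stats))
    cat(sprintf("  significance over %d permutations\n",
                attr(x$stats, "n_permutations")))
  invisible(x)
}

# human-readable transition sequence, e.g. "+1,0,-1,0,+1"
transition_strings <- function(profiles) {
  apply(profiles$transitions, 1, function(v)
    paste(ifelse(v > 0, paste0("+", v), v), collapse = ","))
}

# core assignment: best-correlated template per profile row.
# ties -> lowest template index; zero-variance rows -> flat template.
# the flat template itself has no variance and is excluded from correlation.
assign_to_templates <- function(P, profiles) {
  K <- nrow(profiles$profiles)
  Tm <- profiles$profiles
  tc <- Tm - rowMeans(Tm)
  tnorm <- sqrt(rowSums(tc^2))
  usable <- tnorm > 0
  pc <- P - rowMeans(P)
  pnorm <- sqrt(rowSums(pc^2))
  corr <- matrix(-Inf, nrow(P), K)
  if (any(usable)) {
    cross <- pc %*% t(tc[usable, , drop = FALSE])
    denom <- outer(pnorm, tnorm[usable])
    cc <- cross / denom
    cc[!is.finite(cc)] <- -Inf
    corr[, usable] <- cc
  }
  template <- max.col(corr, ties.method = "first")
  best <- corr[cbind(seq_len(nrow(P)), template)]
  zero_var <- pnorm == 0
  template[zero_var] <- profiles$flat_index
  best[zero_var] <- NA_real_
  list(template = template, correlation = best)
}

#' Compute anchored time-course profiles from an expression matrix
#'
#' Per-gene mean expression at each time point minus the value at the
#' earliest time point, so every profile starts at 0 and encodes change
#' relative to baseline.
#'
#' @param x An [expression_matrix()].
#' @param genes Optional character vector restricting (and ordering) the
#'   genes.
#' @return Numeric matrix genes x timepoints; `attr(, "timepoints")` holds
#'   the sorted time values.
#' @export
time_course_profiles <- function(x, genes = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  tp <- sort(unique(x$design$time_hours))
  means <- vapply(tp, function(t)
    rowMeans(x$values[, x$design$time_hours == t, drop = FALSE]),
    numeric(nrow(x$values)))
  means <- matrix(means, nrow = nrow(x$values),
                  dimnames = list(rownames(x$values), tp))
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(means))
    if (length(miss)) stop("gene(s) not in matrix: ", paste(miss, collapse = ", "))
    means <- means[genes, , drop = FALSE]
  }
  out <- means - means[, 1]
  attr(out, "timepoints") <- tp
  out
}

#' Assign genes to temporal templates by maximal correlation
#'
#' Each gene's anchored profile (first entry 0) is assigned to the template
#' with which its Pearson correlation is maximal; exact ties go to the lowest
#' template index, and genes with zero temporal variance go to the flat
#' template.
#'
#' @param log_ratio_profiles Numeric genes x T matrix (rownames = gene ids),
#'   as produced by [time_course_profiles()].
#' @param profiles An [build_profile_templates()] result.
#' @return `profiles` with `assignments` (data frame `gene_id`, `template`,
#'   `correlation`) and the gene profiles stored for permutation testing.
#' @export
assign_genes_to_profiles <- function(log_ratio_profiles, profiles) {
  stopifnot(inherits(profiles, "STCProfileSet"))
  P <- as.matrix(log_ratio_profiles)
  if (ncol(P) != profiles$n_timepoints)
    stop("profile length ", ncol(P), " does not match template length ",
         profiles$n_timepoints)
  if (is.null(rownames(P))) rownames(P) <- sprintf("gene%d", seq_len(nrow(P)))
  a <- assign_to_templates(P, profiles)
  profiles$assignments <- data.frame(gene_id = rownames(P),
                                     template = a$template,
                                     correlation = a$correlation,
                                     stringsAsFactors = FALSE)
  profiles$gene_profiles <- P
  profiles
}

#' Permutation significance of template occupancy
#'
#' For each template, compares the observed number of assigned genes with
#' its occupancy under datasets in which each gene's time labels are
#' independently permuted (profiles re-anchored to 0 at the first entry
#' after permutation). The p-value is the add-one-smoothed fraction of
#' permutations whose count reaches the observed count.
#'
#' @param profiles An [assign_genes_to_profiles()] result.
#' @param n_permutations Number of permutations (>= 100).
#' @param seed Integer seed; results are fully reproducible.
#' @return `profiles` with a `stats` data frame: `template`, `transitions`,
#'   `observed`, `expected`, `p_value`.
#' @export
profile_significance <- function(profiles, n_permutations = 1000, seed = 1) {
  stopifnot(inherits(profiles, "STCProfileSet"))
  if (is.null(profiles$assignments))
    stop("assign genes first (assign_genes_to_profiles)")
  if (n_permutations < 100) stop("need >= 100 permutations")
  P <- profiles$gene_profiles
  G <- nrow(P); Tn <- ncol(P); K <- nrow(profiles$profiles)
  observed <- tabulate(profiles$assignments$template, K)
  if (G == 0) {
    profiles$stats <- data.frame(template = seq_len(K),
                                 transitions = transition_strings(profiles),
                                 observed = 0L, expected = 0,
                                 p_value = 1, stringsAsFactors = FALSE)
    attr(profiles$stats, "n_permutations") <- n_permutations
    return(profiles)
  }
  exceed <- integer(K)
  expected <- numeric(K)
  withr::with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      keys <- matrix(runif(G * Tn), G, Tn)
      Pp <- matrix(0, G, Tn)
      for (j in seq_len(Tn)) {
        pick <- max.col(keys, ties.method = "first")
        Pp[, j] <- P[cbind(seq_len(G), pick)]
        keys[cbind(seq_len(G), pick)] <- -Inf
      }
      Pp <- Pp - Pp[, 1]
      cnt <- tabulate(assign_to_templates(Pp, profiles)$template, K)
      exceed <- exceed + (cnt >= observed)
      expected <- expected + cnt
    }
  })
  stats <- data.frame(template = seq_len(K),
                      transitions = transition_strings(profiles),
                      observed = observed,
                      expected = expected / n_permutations,
                      p_value = (1 + exceed) / (n_permutations + 1),
                      stringsAsFactors = FALSE)
  attr(stats, "n_permutations") <- n_permutations
  profiles$stats <- stats
  profiles
}
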