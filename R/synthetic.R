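#' Generate a ground-truth CTRNN regulatory network
#'
#' Builds a sparse signed weight matrix with a configurable number of hub
#' regulators (genes with out-degree strictly above the median), the ground
#' truth against which network recovery is measured.
#'
#' Off-diagonal nonzero weights are drawn uniformly from
#' `±[0.5, 1] * weight_scale` with balanced signs in expectation. Hub genes
#' are allocated extra outgoing edges first; the remaining edges are placed
#' uniformly at random among non-hub source pairs.
#'
#' @param n_genes Number of network genes.
#' @param density Fraction of the `n_genes * (n_genes - 1)` possible directed
#'   off-diagonal edges that are nonzero.
#' @param n_hubs Number of designated hub regulators (`< n_genes`).
#' @param weight_scale Positive scale of the weight magnitudes.
#' @param seed Integer seed; results are fully reproducible.
#' @param tau_range,theta_range Ranges for per-gene time constants (hours)
#'   and sigmoid offsets.
#' @return An object of class `GroundTruthNetwork`: list with `gene_ids`,
#'   `n_genes`, `W_true` (target x source), `tau_true`, `theta_true`,
#'   `hub_ids`.
#' @export
generate_ground_truth_network <- function(n_genes, density = 0.04, n_hubs = 2,
                                          weight_scale = 2, seed = 1,
                                          tau_range = c(0.5, 3),
                                          theta_range = c(-1, 1)) {
  stopifnot(n_genes >= 2, density >= 0, density <= 1, n_hubs >= 0,
            n_hubs < n_genes, weight_scale > 0)
  m <- round(density * n_genes * (n_genes - 1))
  ids <- sprintf("G%03d", seq_len(n_genes))
  withr::with_seed(seed, {
    hub_idx <- if (n_hubs > 0) sort(sample.int(n_genes, n_hubs)) else integer()
    # hubs take an elevated share of outgoing edges so their out-degree
    # strictly exceeds the median
    per_hub <- if (n_hubs > 0) max(3L, ceiling(0.15 * m / n_hubs)) else 0L
    per_hub <- min(per_hub, n_genes - 1L)
    if (m < n_hubs * per_hub)
      stop("density too low to give every hub its outgoing edges")
    pairs <- matrix(integer(), 0, 2)
    for (h in hub_idx) {
      tgt <- sample(setdiff(seq_len(n_genes), h), per_hub)
      pairs <- rbind(pairs, cbind(tgt, h))
    }
    n_rest <- m - nrow(pairs)
    if (n_rest > 0) {
      src_pool <- setdiff(seq_len(n_genes), hub_idx)
      all_pairs <- expand.grid(target = seq_len(n_genes), source = src_pool)
      all_pairs <- all_pairs[all_pairs$target != all_pairs$source, ]
      take <- sample.int(nrow(all_pairs), min(n_rest, nrow(all_pairs)))
      pairs <- rbind(pairs, as.matrix(all_pairs[take, c("target", "source")]))
    }
    W <- matrix(0, n_genes, n_genes, dimnames = list(ids, ids))
    k <- nrow(pairs)
    mag <- runif(k, 0.5, 1) * weight_scale
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    W[pairs] <- mag * sgn
    tau <- runif(n_genes, tau_range[1], tau_range[2])
    theta <- runif(n_genes, theta_range[1], theta_range[2])
  })
  structure(list(gene_ids = ids, n_genes = n_genes, W_true = W,
                 tau_true = tau, theta_true = theta,
                 hub_ids = ids[hub_idx]),
            class = "GroundTruthNetwork")
}

#' @export
print.GroundTruthNetwork <- function(x, ...) {
  cat(sprintf("GroundTruthNetwork: %d genes, %d edges, hubs: %s\n",
              x$n_genes, sum(x$W_true != 0),
              paste(x$hub_ids, collapse = ", ")))
  invisible(x)
}

#' Simulate a time-course expression dataset from a ground-truth network
#'
#' Network genes follow numerically integrated CTRNN trajectories from
#' randomized initial states; null genes have constant mean profiles drawn
#' from the empirical range of the network genes (so differential-expression
#' selection must separate by temporal variation, not absolute level).
#' Independent Gaussian noise of standard deviation `noise_sd` is added to
#' every replicate measurement.
#'
#' @param truth A [generate_ground_truth_network()] result.
#' @param timepoints Sorted observation times in hours (>= 3 points). The
#'   default mirrors the short nerve-injury design: 0, 0.5, 1, 3, 6, 9 h.
#' @param replicates Replicates per time point (>= 1).
#' @param noise_sd Non-negative measurement noise standard deviation.
#' @param n_null_genes Number of flat-profile null genes appended.
#' @param seed Integer seed.
#' @param step Integration step passed to [simulate_trajectories()].
#' @return An object of class `SyntheticDataset`: list with `expression`
#'   (an [expression_matrix()]), `truth`, `de_gene_ids` (network-driven
#'   genes), `null_gene_ids`, and `trajectories` (the noise-free network-gene
#'   trajectories at `timepoints`).
#' @export
simulate_dataset <- function(truth, timepoints = c(0, 0.5, 1, 3, 6, 9),
                             replicates = 3, noise_sd = 0.1,
                             n_null_genes = 150, seed = 1, step = 0.05) {
  stopifnot(inherits(truth, "GroundTruthNetwork"))
  if (is.unsorted(timepoints, strictly = TRUE) || length(timepoints) < 3)
    stop("timepoints must be >= 3 strictly increasing values")
  if (replicates < 1) stop("replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  n <- truth$n_genes
  model <- ctrnn_model(truth$gene_ids, truth$W_true, truth$tau_true,
                       truth$theta_true)
  res <- withr::with_seed(seed, {
    # initial states inside the sigmoid's responsive range
    g0 <- runif(n, 0.2, 0.8)
    traj <- simulate_trajectories(model, g0, timepoints, step = step)
    null_ids <- if (n_null_genes > 0) sprintf("N%03d", seq_len(n_null_genes))
                else character()
    null_means <- runif(n_null_genes, min(traj), max(traj))
    means <- rbind(traj,
                   matrix(null_means, n_null_genes, length(timepoints),
                          dimnames = list(null_ids, colnames(traj))))
    T <- length(timepoints)
    samples <- as.vector(vapply(seq_len(T), function(t)
      sprintf("t%g_r%d", timepoints[t], seq_len(replicates)),
      character(replicates)))
    design <- data.frame(sample = samples,
                         time_hours = rep(timepoints, each = replicates),
                         replicate = rep(seq_len(replicates), times = T))
    vals <- means[, rep(seq_len(T), each = replicates), drop = FALSE]
    colnames(vals) <- samples
    vals <- vals + matrix(rnorm(length(vals), 0, noise_sd), nrow(vals))
    list(vals = vals, design = design, traj = traj, null_ids = null_ids)
  })
  structure(list(expression = expression_matrix(res$vals, res$design),
                 truth = truth,
                 de_gene_ids = truth$gene_ids,
                 null_gene_ids = res$null_ids,
                 trajectories = res$traj),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf("SyntheticDataset: %d network + %d null genes, %d samples\n",
              length(x$de_gene_ids), length(x$null_gene_ids),
              ncol(x$expression$values)))
  invisible(x)
}

#' Generate matched gene-set and interaction-catalog annotations
#'
#' Builds a gene-set collection in which `enriched_categories` categories are
#' composed of at least 80% network-driven genes (so over-representation
#' analysis has a known answer) and the remaining background categories
#' sample all genes uniformly. The interaction catalog contains each true
#' network edge with probability `1 - dropout`, typed `activation` for
#' positive weights and `inhibition` for negative ones; dropped edges must be
#' re-discovered by the model fit as `computed` edges.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param n_categories Total number of categories (>= 1).
#' @param enriched_categories Number of categories enriched for network genes.
#' @param dropout Fraction of true edges withheld from the catalog.
#' @param seed Integer seed.
#' @param category_size Size of each generated category.
#' @return List with elements `gene_sets` (a [gene_set_collection()]) and
#'   `catalog` (an [interaction_catalog()]), plus `enriched_ids` naming the
#'   planted categories.
#' @export
generate_annotations <- function(dataset, n_categories = 30,
                                 enriched_categories = 5, dropout = 0.3,
                                 seed = 1, category_size = 25) {
  stopifnot(inherits(dataset, "SyntheticDataset"))
  if (n_categories < 1) stop("n_categories must be >= 1")
  if (enriched_categories > n_categories)
    stop("enriched_categories must be <= n_categories")
  if (dropout < 0 || dropout > 1) stop("dropout must be in [0, 1]")
  de <- dataset$de_gene_ids
  all_genes <- gene_ids(dataset$expression)
  category_size <- min(category_size, length(all_genes))
  withr::with_seed(seed, {
    sets <- list()
    enriched_ids <- if (enriched_categories > 0)
      sprintf("PLANTED%02d", seq_len(enriched_categories)) else character()
    for (id in enriched_ids) {
      n_de <- min(ceiling(0.9 * category_size), length(de))
      members <- sample(de, n_de)
      n_bg <- category_size - n_de
      if (n_bg > 0)
        members <- c(members, sample(setdiff(all_genes, members), n_bg))
      sets[[id]] <- members
    }
    bg_ids <- sprintf("BG%02d", seq_len(n_categories - enriched_categories))
    for (id in bg_ids) sets[[id]] <- sample(all_genes, category_size)
    W <- dataset$truth$W_true
    nz <- which(W != 0, arr.ind = TRUE)
    keep <- runif(nrow(nz)) >= dropout
    nz <- nz[keep, , drop = FALSE]
    catalog <- interaction_catalog(
      source = dataset$truth$gene_ids[nz[, 2]],
      target = dataset$truth$gene_ids[nz[, 1]],
      type = ifelse(W[nz] > 0, "activation", "inhibition"))
  })
  desc <- setNames(ifelse(names(sets) %in% enriched_ids,
                          "network-gene enriched", "background"), names(sets))
  list(gene_sets = gene_set_collection(sets, desc), catalog = catalog,
       enriched_ids = enriched_ids)
}

#' Write a complete synthetic fixture directory
#'
#' Emits the expression/design TSVs, the GMT gene sets and the interaction
#' catalog for a synthetic dataset, in exactly the formats the readers in
#' this package consume.
#'
#' @param dir Output directory (created if needed).
#' @param dataset A [simulate_dataset()] result.
#' @param annotations A [generate_annotations()] result.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synthetic_fixture <- function(dir, dataset, annotations) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             design = file.path(dir, "design.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             interactions = file.path(dir, "interactions.tsv"))
  write_expression_tsv(dataset$expression, paths["expression"], paths["design"])
  write_gmt(annotations$gene_sets, paths["gene_sets"])
  write_interaction_table(annotations$catalog, paths["interactions"])
  invisible(paths)
}
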