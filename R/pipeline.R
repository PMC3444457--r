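#' Default pipeline configuration
#'
#' All stage parameters with their defaults: differential-expression
#' thresholds p < 0.01 with the FDR controlled at 5%, pathway-style
#' enrichment at Fisher p < 0.001, the short-time-course design (0, 0.5, 1,
#' 3, 6, 9 h with 3 replicates) for the synthetic generator, and the
#' genetic-algorithm settings of [ga_config()].
#'
#' Configuration is a plain nested list so it can round-trip through a YAML
#' manifest. Either `input` (paths to expression/design/gene-set/interaction
#' files) or `synth` (generator parameters) drives a run; `synth` is used
#' when `input` is `NULL`.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    input = NULL,
    synth = list(n_genes = 50, density = 0.04, n_hubs = 2, weight_scale = 2,
                 timepoints = c(0, 0.5, 1, 3, 6, 9), replicates = 3,
                 noise_sd = 0.05, n_null_genes = 150, n_categories = 30,
                 enriched_categories = 5, dropout = 0.3, category_size = 25),
    de = list(p_threshold = 0.01, q_threshold = 0.05),
    stc = list(max_unit_change = 1, n_permutations = 1000,
               top_k_profiles = NULL),
    enrichment = list(p_threshold = 0.001, min_category_size = 5),
    network = list(ga = list(population_size = 200, generations = 500,
                             crossover_rate = 0.7, mutation_rate = 0.1,
                             mutation_sd_frac = 0.1, tournament_size = 3,
                             elitism = 2, sparsity_lambda = 0.01,
                             polish_maxit = 0),
                   rel_threshold = 0.1, step = 0.1, max_genes = 60,
                   restrict_to_catalog = FALSE, seed_from_catalog = TRUE),
    seed = 1,
    output_dir = NULL
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        !is.null(user[[k]])) {
      if (!is.list(user[[k]]))
        stop("config key '", sub("^\\.", "", paste0(path, ".", k)),
             "' must be a list")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, ".", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Fills unset keys with [default_config()] values, rejects unknown keys,
#' and checks ranges (thresholds in `[0, 1]`, positive permutation counts,
#' a usable input specification).
#'
#' @param config Partial configuration list (may be empty).
#' @return The normalized configuration.
#' @export
validate_config <- function(config = list()) {
  defaults <- default_config()
  # `input` has no default sub-structure; validate it separately
  input <- config$input
  config$input <- NULL
  cfg <- merge_config(defaults, config)
  if (!is.null(input)) {
    req <- c("expression", "design", "gene_sets", "interactions")
    miss <- setdiff(req, names(input))
    if (length(miss))
      stop("config input needs path(s): ", paste(miss, collapse = ", "))
    unknown <- setdiff(names(input), req)
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0("input.", unknown, collapse = ", "))
    cfg$input <- input
  }
  for (thr in c(cfg$de$p_threshold, cfg$de$q_threshold,
                cfg$enrichment$p_threshold))
    if (!is.numeric(thr) || thr < 0 || thr > 1)
      stop("thresholds must lie in [0, 1]")
  if (cfg$stc$n_permutations < 100)
    stop("stc n_permutations must be >= 100")
  if (cfg$synth$dropout < 0 || cfg$synth$dropout > 1)
    stop("synth dropout must lie in [0, 1]")
  if (cfg$network$restrict_to_catalog && is.null(cfg$input) &&
      cfg$synth$dropout >= 1)
    stop("restrict_to_catalog with an empty catalog (dropout = 1)")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("seed must be a single integer")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full inference pipeline
#'
#' Executes the four stages in order — differential expression (RVM F-test
#' with BH FDR), temporal-tendency clustering with permutation significance,
#' gene-set over-representation, and CTRNN network fitting with edge
#' extraction, regulator ranking and sub-network decomposition — writing
#' every intermediate table plus a machine-readable manifest to the output
#' directory. A rerun from the manifest reproduces all outputs (stochastic
#' stages are seed-identical).
#'
#' Stage seeds are derived from the single global seed by fixed offsets
#' (synthesis +0, annotations +1, permutations +2, GA +3), so each stage has
#' an independent reproducible stream.
#'
#' @param config Configuration list, normalized by [validate_config()].
#' @param output_dir Output directory; overrides `config$output_dir`;
#'   defaults to a fresh temporary directory.
#' @return A run report (list, class `PipelineReport`): per-stage counts,
#'   significant templates and categories, edges by provenance, top
#'   regulators, and the paths of everything written.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  cfg <- validate_config(config)
  out <- output_dir %||% cfg$output_dir %||%
    tempfile(paste0("ctrnnet_run_", format(Sys.Date(), "%Y%m%d")))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg$output_dir <- out
  paths <- character()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- data -------------------------------------------------------------
  dataset <- NULL
  data_res <- run_stage("data", {
    if (is.null(cfg$input)) {
      s <- cfg$synth
      truth <- generate_ground_truth_network(
        s$n_genes, s$density, s$n_hubs, s$weight_scale, seed = cfg$seed)
      dataset <- simulate_dataset(truth, s$timepoints, s$replicates,
                                  s$noise_sd, s$n_null_genes,
                                  seed = cfg$seed)
      ann <- generate_annotations(dataset, s$n_categories,
                                  s$enriched_categories, s$dropout,
                                  seed = cfg$seed + 1L,
                                  category_size = s$category_size)
      fix <- write_synthetic_fixture(file.path(out, "synth"), dataset, ann)
      paths <- c(paths, fix)
      list(x = dataset$expression, sets = ann$gene_sets,
           catalog = ann$catalog, dataset = dataset,
           enriched_ids = ann$enriched_ids)
    } else {
      list(x = read_expression_tsv(cfg$input$expression, cfg$input$design),
           sets = read_gmt(cfg$input$gene_sets),
           catalog = read_interaction_table(cfg$input$interactions),
           dataset = NULL, enriched_ids = NULL)
    }
  })
  x <- data_res$x
  if (cfg$network$restrict_to_catalog && nrow(data_res$catalog) == 0)
    stop("pipeline stage 'config' failed: restrict_to_catalog with an empty catalog")

  # --- differential expression -----------------------------------------
  de <- run_stage("de", {
    rec <- rvm_f_test(x)
    select_degs(rec, cfg$de$p_threshold, cfg$de$q_threshold)
  })
  paths["de"] <- write_tsv(de, file.path(out, "de_results.tsv"))
  de_genes <- de$gene_id[de$selected]

  # --- temporal tendency clustering ------------------------------------
  stc_res <- run_stage("stc", {
    tmpl <- build_profile_templates(length(unique(x$design$time_hours)),
                                    cfg$stc$max_unit_change)
    prof <- time_course_profiles(x, genes = de_genes)
    tmpl <- assign_genes_to_profiles(prof, tmpl)
    profile_significance(tmpl, cfg$stc$n_permutations, seed = cfg$seed + 2L)
  })
  paths["stc_templates"] <- write_tsv(stc_res$stats,
                                      file.path(out, "stc_templates.tsv"))
  paths["stc_assignments"] <- write_tsv(stc_res$assignments,
                                        file.path(out, "stc_assignments.tsv"))
  sig_templates <- stc_res$stats[stc_res$stats$observed > 0 &
                                   stc_res$stats$p_value < 0.05, ]
  stc_gene_pool <- de_genes
  if (!is.null(cfg$stc$top_k_profiles) && nrow(sig_templates) > 0) {
    keep_t <- sig_templates$template[
      order(sig_templates$p_value)][seq_len(min(cfg$stc$top_k_profiles,
                                                nrow(sig_templates)))]
    stc_gene_pool <- stc_res$assignments$gene_id[
      stc_res$assignments$template %in% keep_t]
  }

  # --- enrichment -------------------------------------------------------
  enr <- run_stage("enrich", {
    enrich(de_genes, gene_ids(x), data_res$sets,
           p_threshold = cfg$enrichment$p_threshold,
           min_category_size = cfg$enrichment$min_category_size)
  })
  paths["enrichment"] <- write_tsv(enr, file.path(out, "enrichment.tsv"))
  sig_categories <- enr$category[enr$significant]

  # --- network ----------------------------------------------------------
  net <- run_stage("network", {
    pool <- intersect(stc_gene_pool, de_genes)
    if (length(sig_categories)) {
      in_sig <- unique(unlist(data_res$sets$sets[sig_categories]))
      pool2 <- intersect(pool, in_sig)
      if (length(pool2) >= 2) pool <- pool2
    }
    if (length(pool) > cfg$network$max_genes) {
      f <- de$f_statistic[match(pool, de$gene_id)]
      pool <- pool[order(-f)][seq_len(cfg$network$max_genes)]
    }
    pool <- pool[order(match(pool, gene_ids(x)))]
    if (length(pool) < 2) {
      list(genes = pool, fit = NULL, edges = network_edges(),
           regulators = rank_regulators(network_edges()), subnets = list())
    } else {
      prof <- time_course_profiles(x, genes = pool)
      tp <- attr(prof, "timepoints")
      obs <- rescale_unit(prof)  # min-max rescaling removes the 0 h anchor
      gcfg <- do.call(ga_config, c(cfg$network$ga, list(seed = cfg$seed + 3L)))
      fit <- fit_ctrnn_ga(obs, tp, gcfg, catalog = data_res$catalog,
                          restrict_to_catalog = cfg$network$restrict_to_catalog,
                          seed_from_catalog = cfg$network$seed_from_catalog,
                          step = cfg$network$step)
      edges <- extract_edges(fit$model, data_res$catalog,
                             cfg$network$rel_threshold)
      list(genes = pool, fit = fit, edges = edges,
           regulators = rank_regulators(edges),
           subnets = decompose_subnetworks(edges))
    }
  })
  paths["edges"] <- file.path(out, "edges.tsv")
  write_network(net$edges, paths["edges"], "edge-table")
  paths["sif"] <- file.path(out, "network.sif")
  write_network(net$edges, paths["sif"], "sif")
  if (nrow(net$edges)) {
    paths["graphml"] <- file.path(out, "network.graphml")
    write_network(net$edges, paths["graphml"], "graphml")
  }
  paths["regulators"] <- write_tsv(net$regulators,
                                   file.path(out, "regulators.tsv"))
  if (!is.null(net$fit))
    paths["fitness_trace"] <- write_tsv(
      data.frame(generation = seq_along(net$fit$fitness_trace) - 1L,
                 best_fitness = net$fit$fitness_trace),
      file.path(out, "fitness_trace.tsv"))

  # --- manifest & report ------------------------------------------------
  manifest <- cfg
  manifest$stage_seeds <- list(synthesis = cfg$seed,
                               annotations = cfg$seed + 1L,
                               stc_permutations = cfg$seed + 2L,
                               ga = cfg$seed + 3L)
  paths["manifest"] <- file.path(out, "manifest.yaml")
  yaml::write_yaml(manifest, paths["manifest"])

  report <- list(
    output_dir = out,
    paths = paths,
    config = cfg,
    counts = list(
      genes = nrow(x$values),
      samples = ncol(x$values),
      de_genes = length(de_genes),
      templates = nrow(stc_res$stats),
      significant_templates = nrow(sig_templates),
      categories_tested = nrow(enr),
      significant_categories = length(sig_categories),
      network_genes = length(net$genes),
      edges = nrow(net$edges),
      subnetworks = length(net$subnets)),
    edges_by_provenance = table(factor(net$edges$provenance,
                                       c("database", "computed"))),
    significant_templates = sig_templates,
    significant_categories = sig_categories,
    top_regulators = head(net$regulators, 10),
    rvm_params = attr(de, "rvm_params"),
    enriched_ids = data_res$enriched_ids,
    dataset = data_res$dataset,
    fit = net$fit,
    edges = net$edges,
    regulators = net$regulators)
  paths["report"] <- file.path(out, "report.json")
  jsonlite::write_json(
    list(counts = report$counts,
         edges_by_provenance = as.list(report$edges_by_provenance),
         significant_categories = sig_categories,
         top_regulators = head(net$regulators, 10)),
    paths["report"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$paths <- paths
  class(report) <- "PipelineReport"
  report
}

#' @export
print.PipelineReport <- function(x, ...) {
  c_ <- x$counts
  cat("ctrnnet pipeline run:", x$output_dir, "\n")
  cat(sprintf("  %d genes x %d samples; %d differential\n",
              c_$genes, c_$samples, c_$de_genes))
  cat(sprintf("  %d/%d temporal templates significant\n",
              c_$significant_templates, c_$templates))
  cat(sprintf("  %d/%d categories significant\n",
              c_$significant_categories, c_$categories_tested))
  cat(sprintf("  network: %d genes, %d edges (%d database, %d computed), %d sub-networks\n",
              c_$network_genes, c_$edges,
              x$edges_by_provenance[["database"]],
              x$edges_by_provenance[["computed"]], c_$subnetworks))
  if (nrow(x$top_regulators)) {
    cat("  top regulators:\n")
    print(head(x$top_regulators, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Re-run a pipeline from a written manifest
#'
#' Reads the YAML manifest of a previous run and re-executes the pipeline
#' with the identical configuration and seeds.
#'
#' @param manifest_path Path to a `manifest.yaml` written by
#'   [run_pipeline()].
#' @param output_dir Where to write the rerun's outputs (default: a fresh
#'   temporary directory).
#' @return The rerun's `PipelineReport`.
#' @export
run_pipeline_from_manifest <- function(manifest_path, output_dir = NULL) {
  cfg <- yaml::read_yaml(manifest_path)
  cfg$stage_seeds <- NULL
  cfg$output_dir <- NULL
  if (!is.null(cfg$stc) && !is.null(cfg$stc$top_k_profiles) &&
      length(cfg$stc$top_k_profiles) == 0)
    cfg$stc$top_k_profiles <- NULL
  run_pipeline(cfg, output_dir = output_dir)
}
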