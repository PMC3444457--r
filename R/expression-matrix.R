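#' Construct an expression matrix with a time-course design
#'
#' The pipeline's universal input: a genes x samples matrix of log2-scale
#' intensities together with a per-sample design giving the time point (in
#' hours) and replicate index of each array. Values are assumed to be already
#' log-transformed and normalized; raw-intensity preprocessing is out of
#' scope.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene identifiers,
#'   unique, case-sensitive), samples in columns (colnames = sample ids).
#' @param design Data frame with columns `sample`, `time_hours` (non-negative
#'   real) and `replicate` (positive integer), one row per sample column of
#'   `values`, in any order.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (the matrix, columns reordered to match `design`) and `design`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' d <- data.frame(sample = paste0("s", 1:4),
#'                 time_hours = c(0, 0, 1, 1), replicate = c(1, 2, 1, 2))
#' x <- expression_matrix(m, d)
#' dim(x)
#' @export
expression_matrix <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  req <- c("sample", "time_hours", "replicate")
  if (!all(req %in% names(design)))
    stop("design must have columns: ", paste(req, collapse = ", "))
  design <- as.data.frame(design)[, req]
  design$sample <- as.character(design$sample)
  missing_design <- setdiff(colnames(values), design$sample)
  if (length(missing_design))
    stop("sample column(s) missing from design: ",
         paste(missing_design, collapse = ", "))
  extra <- setdiff(design$sample, colnames(values))
  if (length(extra))
    stop("design lists sample(s) absent from the matrix: ",
         paste(extra, collapse = ", "))
  if (anyDuplicated(design$sample))
    stop("duplicated sample id(s) in design")
  if (any(!is.finite(design$time_hours)) || any(design$time_hours < 0))
    stop("time_hours must be finite and non-negative")
  if (any(design$replicate < 1) || any(design$replicate != round(design$replicate)))
    stop("replicate must be a positive integer")
  design$replicate <- as.integer(design$replicate)
  values <- values[, design$sample, drop = FALSE]
  structure(list(values = values, design = design), class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  tp <- sort(unique(x$design$time_hours))
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n", nrow(x$values),
              ncol(x$values)))
  cat("  time points (h): ", paste(tp, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Gene identifiers of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of gene ids, in matrix row order.
#' @export
gene_ids <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  rownames(x$values)
}

#' Read an expression matrix and its design from tab-separated files
#'
#' The expression file has one header row of sample ids and one row per gene
#' (first column = gene id). The design file maps each sample column to its
#' time point and replicate (columns `sample`, `time_hours`, `replicate`).
#' Tabs only, "." decimal, lines starting with "#" are ignored.
#'
#' @param path Path to the expression TSV.
#' @param design_path Path to the design TSV.
#' @return A validated [expression_matrix()]; gene row order is preserved
#'   from the file.
#' @export
read_expression_tsv <- function(path, design_path) {
  for (p in c(path, design_path))
    if (!file.exists(p)) stop("file not found: ", p)
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression file needs a gene id column and >=1 sample")
  ids <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s', data row %d",
                   names(vals)[j], bad))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  design <- read.delim(design_path, header = TRUE, sep = "\t",
                       comment.char = "#", stringsAsFactors = FALSE)
  expression_matrix(m, design)
}

#' Write an expression matrix and its design to tab-separated files
#'
#' Inverse of [read_expression_tsv()]; round-trips losslessly.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path for the expression TSV.
#' @param design_path Output path for the design TSV.
#' @return Invisibly, `x`.
#' @export
write_expression_tsv <- function(x, path, design_path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  tab <- data.frame(gene_id = rownames(x$values),
                    apply(x$values, 2, function(v) sprintf("%.17g", v)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("gene_id", colnames(x$values))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$design, design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(x)
}
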