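#' Construct a gene-set collection
#'
#' Holds GO/KEGG-style categories: a named list of gene-id sets plus a
#' one-line description per category. Gene ids are matched case-sensitively
#' throughout the package.
#'
#' @param sets Named list of character vectors (category id -> member genes).
#' @param descriptions Optional named character vector of descriptions,
#'   aligned with `sets`; defaults to empty strings.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("category ids must be unique and non-empty")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) stop("every category must be non-empty")
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  descriptions <- descriptions[names(sets)]
  descriptions[is.na(descriptions)] <- ""
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d categories, sizes %s\n",
              length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)), collapse = "-")
              else "-"))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Read gene sets in GMT format
#'
#' One category per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Genes are deduplicated within a category.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()]. An empty file yields an empty
#'   collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(structure(list(sets = setNames(list(), character()),
                          descriptions = setNames(character(), character())),
                     class = "GeneSetCollection"))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  ids <- vapply(parts, `[[`, "", 1)
  desc <- vapply(parts, `[[`, "", 2)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  gene_set_collection(sets, setNames(desc, ids))
}

#' Write gene sets in GMT format
#' @param x A `GeneSetCollection`.
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "GeneSetCollection"))
  lines <- vapply(names(x$sets), function(id) {
    paste(c(id, x$descriptions[[id]], x$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(x)
}

#' Construct a prior interaction catalog
#'
#' Typed directed gene-gene interactions from a curated pathway database,
#' used to label fitted network edges with `database` vs `computed`
#' provenance and to carry `binding/association` annotations.
#'
#' @param source,target Character vectors of gene ids.
#' @param type Character vector of interaction types; unknown strings are
#'   mapped to `"other"` with a warning. Closed vocabulary: `activation`,
#'   `inhibition`, `binding/association`, `other`.
#' @return An object of class `InteractionCatalog` (a data frame with columns
#'   `source`, `target`, `type`). Duplicated typed pairs are collapsed.
#' @export
interaction_catalog <- function(source = character(), target = character(),
                                type = character()) {
  stopifnot(length(source) == length(target), length(source) == length(type))
  type <- as.character(type)
  unknown <- !(type %in% INTERACTION_TYPES)
  if (any(unknown)) {
    warning("unknown interaction type(s) mapped to 'other': ",
            paste(unique(type[unknown]), collapse = ", "))
    type[unknown] <- "other"
  }
  cat_df <- data.frame(source = as.character(source),
                       target = as.character(target),
                       type = type, stringsAsFactors = FALSE)
  cat_df <- cat_df[!duplicated(cat_df), , drop = FALSE]
  rownames(cat_df) <- NULL
  class(cat_df) <- c("InteractionCatalog", "data.frame")
  cat_df
}

#' Read a prior interaction table
#'
#' Tab-separated with header columns `source`, `target`, `type`.
#'
#' @param path Path to the interaction TSV.
#' @return An [interaction_catalog()].
#' @export
read_interaction_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  req <- c("source", "target", "type")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("interaction table missing column(s): ", paste(miss, collapse = ", "))
  interaction_catalog(tab$source, tab$target, tab$type)
}

#' Write a prior interaction table
#' @param x An `InteractionCatalog`.
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
write_interaction_table <- function(x, path) {
  stopifnot(inherits(x, "InteractionCatalog"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(x)
}

# lookup: catalog type of a typed pair, NA_character_ when absent
catalog_type <- function(catalog, source, target) {
  if (is.null(catalog) || nrow(catalog) == 0) return(rep(NA_character_, length(source)))
  key <- paste(catalog$source, catalog$target, sep = "\r")
  # prefer binding/association annotation when a pair is multiply typed
  ord <- order(catalog$type != "binding/association")
  key <- key[ord]
  types <- catalog$type[ord]
  types[match(paste(source, target, sep = "\r"), key)]
}
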