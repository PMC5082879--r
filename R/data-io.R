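#' Read a gene-by-sample expression table with phenotype labels
#'
#' Expression files are tab-separated with a header row of sample identifiers
#' and the first column holding gene symbols. The label file is a two-column
#' TSV (sample identifier, phenotype); a header line is optional and detected
#' by matching the first field against the expression header. Rows containing
#' any missing or non-numeric value are dropped and counted (low-quality
#' rows); duplicate gene symbols are collapsed per `dup_policy`.
#'
#' @param path expression TSV.
#' @param label_path two-column sample/phenotype TSV.
#' @param dup_policy how to collapse duplicate gene symbols:
#'   `"median"` (per-sample median across duplicate rows, the default),
#'   `"max_var"` (keep the duplicate row with the largest variance), or
#'   `"drop"` (discard all rows of a duplicated symbol).
#' @param ref_level reference phenotype; defaults to first in sort order.
#' @param log2_transform apply `log2(x + 1)` after reading, for tables of raw
#'   (linear-scale) intensities. Values are otherwise assumed log-scale.
#' @return an [expr_dataset()], with attributes `n_dropped` (low-quality rows
#'   removed) and `n_duplicate_symbols` (symbols that needed collapsing).
#' @export
read_expression <- function(path, label_path, dup_policy = c("median", "max_var", "drop"),
                            ref_level = NULL, log2_transform = FALSE) {
  dup_policy <- match.arg(dup_policy)
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  bad <- !stats::complete.cases(vals)
  n_dropped <- sum(bad)
  vals <- vals[!bad, , drop = FALSE]
  genes <- genes[!bad]

  dup_syms <- unique(genes[duplicated(genes)])
  if (length(dup_syms)) {
    vals <- .collapse_duplicates(vals, genes, dup_policy)
  } else {
    rownames(vals) <- genes
  }
  if (log2_transform) vals <- log2(vals + 1)

  lab <- read.delim(label_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(lab) < 2) stop("label file must have two columns: sample, phenotype")
  # tolerate a header line that is not a sample identifier
  if (!lab[[1]][1] %in% colnames(vals) && nrow(lab) > 1 &&
      all(lab[[1]][-1] %in% colnames(vals))) {
    lab <- lab[-1, , drop = FALSE]
  }
  unknown <- setdiff(lab[[1]], colnames(vals))
  if (length(unknown))
    stop("label file names unknown sample(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(colnames(vals), lab[[1]])
  if (length(missing))
    stop("no phenotype label for sample(s): ", paste(missing, collapse = ", "))
  labels <- setNames(as.character(lab[[2]]), lab[[1]])

  ds <- expr_dataset(vals, labels, ref_level = ref_level)
  attr(ds, "n_dropped") <- n_dropped
  attr(ds, "n_duplicate_symbols") <- length(dup_syms)
  ds
}

.collapse_duplicates <- function(vals, genes, dup_policy) {
  switch(dup_policy,
    median = {
      out <- rowsum(vals, genes, reorder = FALSE) # placeholder shape
      for (g in rownames(out)) {
        rows <- vals[genes == g, , drop = FALSE]
        out[g, ] <- if (nrow(rows) == 1) rows else apply(rows, 2, median)
      }
      out
    },
    max_var = {
      keep <- vapply(split(seq_along(genes), genes), function(idx) {
        if (length(idx) == 1) return(idx)
        idx[which.max(apply(vals[idx, , drop = FALSE], 1, var))]
      }, integer(1))
      keep <- keep[unique(genes)] # restore input order
      out <- vals[keep, , drop = FALSE]
      rownames(out) <- unique(genes)
      out
    },
    drop = {
      keep <- !genes %in% genes[duplicated(genes)]
      out <- vals[keep, , drop = FALSE]
      rownames(out) <- genes[keep]
      out
    })
}

#' Write an expression dataset (and its labels) back to TSV
#'
#' Emits the same dialects [read_expression()] accepts, so the pair
#' round-trips.
#'
#' @param ds an [expr_dataset()].
#' @param path expression TSV to write.
#' @param label_path optional label TSV to write.
#' @return `ds`, invisibly.
#' @export
write_expression <- function(ds, path, label_path = NULL) {
  stopifnot(inherits(ds, "expr_dataset"))
  df <- data.frame(gene = rownames(ds$values), ds$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(label_path)) {
    write.table(
      data.frame(sample = colnames(ds$values),
                 phenotype = as.character(ds$labels)),
      label_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(ds)
}

#' Merge protein-protein interaction files into one undirected graph
#'
#' Accepts SIF files (`A <relation> B`, whitespace-separated, one edge per
#' line) and two-column TSV edge lists, possibly mixed across `paths`. The
#' union of all edges is taken; duplicate edges (in either orientation) and
#' self-loops are removed, emulating the merge of several curated interaction
#' databases into one non-redundant interactome.
#'
#' @param paths character vector of edge-list files.
#' @return an undirected, simplified [igraph::graph][igraph] whose vertex
#'   names are gene symbols.
#' @export
merge_ppi <- function(paths) {
  edges <- purrr::map(paths, .read_edge_file)
  el <- do.call(rbind, edges)
  if (is.null(el) || nrow(el) == 0) stop("no edges found in input files")
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

.read_edge_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[\t ]+")
  n <- lengths(parts)
  bad <- which(!(n == 2L | n == 3L))
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected 2 (TSV) or 3 (SIF) fields",
                 bad[1], path))
  t(vapply(parts, function(p) {
    if (length(p) == 2L) c(p[1], p[2]) else c(p[1], p[3])
  }, character(2)))
}

#' Write a PPI graph as a two-column TSV edge list
#'
#' @param graph an igraph object.
#' @param path output file.
#' @return `graph`, invisibly.
#' @export
write_ppi <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  write.table(el, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(graph)
}

#' Restrict two expression datasets and a PPI graph to a shared gene universe
#'
#' Mirrors the cross-platform harmonization step of a two-cohort comparison:
#' both datasets are cut down to the genes measured in both, and (optionally)
#' the interaction graph is induced on those measured genes.
#'
#' @param dsA,dsB two [expr_dataset()] objects.
#' @param graph optional PPI graph to induce on the common genes. Genes of
#'   the common universe absent from the graph stay absent; graph nodes not
#'   measured are removed.
#' @return a list with elements `dsA`, `dsB` (restricted datasets), `graph`
#'   (induced graph or `NULL`), and `genes` (the common universe).
#' @export
intersect_universe <- function(dsA, dsB, graph = NULL) {
  stopifnot(inherits(dsA, "expr_dataset"), inherits(dsB, "expr_dataset"))
  common <- intersect(rownames(dsA$values), rownames(dsB$values))
  if (!length(common)) stop("datasets share no genes")
  out <- list(dsA = subset_genes(dsA, common),
              dsB = subset_genes(dsB, common),
              graph = NULL, genes = common)
  if (!is.null(graph)) {
    keep <- intersect(igraph::V(graph)$name, common)
    out$graph <- igraph::induced_subgraph(graph, keep)
  }
  out
}

#' Read a GMT gene-set collection
#'
#' GMT is tab-separated: set name, description, then member genes. Empty
#' sets and duplicate members are removed; duplicate set names are an error.
#'
#' @param path GMT file.
#' @return a named list of character vectors, with a `description` attribute
#'   (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop(sprintf("malformed GMT line %d: fewer than 3 fields", short[1]))
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in GMT file")
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nm
  sets <- sets[lengths(sets) > 0]
  attr(sets, "description") <-
    setNames(vapply(parts, `[[`, character(1), 2), nm)[names(sets)]
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets named list of character vectors (an optional `description`
#'   attribute supplies the second column; defaults to the set name).
#' @param path output file.
#' @return `sets`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}
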