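#' Construct an expression dataset
#'
#' The central container of the package: a numeric gene-by-sample matrix of
#' log-scale intensities together with a two-level phenotype factor over the
#' samples. The first factor level is the reference phenotype (the
#' benign-course class); the second is the case phenotype.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample identifiers).
#' @param labels phenotype per sample: a character/factor vector of length
#'   `ncol(values)`, or a named vector matched to `colnames(values)`.
#'   Exactly two distinct values are required.
#' @param ref_level which phenotype is the reference class. Defaults to the
#'   first level in sort order.
#' @return an object of class `expr_dataset`: a list with elements `values`
#'   (the matrix) and `labels` (a two-level factor, reference level first).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expr_dataset(m, c("LMP", "LMP", "HGSOC", "HGSOC"), ref_level = "LMP")
#' ds
#' @export
expr_dataset <- function(values, labels, ref_level = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in `values`; collapse duplicates first")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in `values`")
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing))
      stop("no phenotype label for sample(s): ", paste(missing, collapse = ", "))
    labels <- labels[colnames(values)]
  }
  if (length(labels) != ncol(values))
    stop("`labels` must provide one phenotype per sample")
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2L)
    stop("exactly two phenotype levels required, got: ",
         paste(lev, collapse = ", "))
  if (!is.null(ref_level)) {
    if (!ref_level %in% lev) stop("ref_level '", ref_level, "' not a phenotype")
    lev <- c(ref_level, setdiff(lev, ref_level))
  }
  labels <- factor(as.character(labels), levels = lev)
  if (any(table(labels) < 2L))
    stop("each phenotype level needs at least 2 samples")
  structure(list(values = values, labels = labels), class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf(
    "<expr_dataset> %d genes x %d samples (%s: %d ref, %s: %d case)\n",
    nrow(x$values), ncol(x$values),
    levels(x$labels)[1], tb[1], levels(x$labels)[2], tb[2]))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' @rdname expr_dataset
#' @param x an `expr_dataset`.
#' @export
ref_level <- function(x) levels(x$labels)[1]

#' @rdname expr_dataset
#' @export
case_level <- function(x) levels(x$labels)[2]

#' Restrict a dataset to a subset of genes
#'
#' @param ds an `expr_dataset`.
#' @param genes character vector of gene symbols to keep (order preserved
#'   from the dataset, not from `genes`).
#' @return an `expr_dataset` over the requested genes.
#' @export
subset_genes <- function(ds, genes) {
  stopifnot(inherits(ds, "expr_dataset"))
  keep <- rownames(ds$values) %in% genes
  if (!any(keep)) stop("none of the requested genes are in the dataset")
  expr_dataset(ds$values[keep, , drop = FALSE], ds$labels,
               ref_level = ref_level(ds))
}

#' Convert an expression dataset to a long tibble
#'
#' One row per (gene, sample) pair, carrying the phenotype label — handy for
#' ggplot2 and dplyr work on small datasets.
#'
#' @param x an `expr_dataset`.
#' @param ... unused.
#' @return a tibble with columns `gene`, `sample`, `phenotype`, `value`.
#' @method tidy expr_dataset
#' @export
tidy.expr_dataset <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    phenotype = rep(as.character(x$labels), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

# split sample indices by phenotype; ref first
.group_idx <- function(labels) {
  lev <- levels(labels)
  list(ref = which(labels == lev[1]), case = which(labels == lev[2]))
}
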