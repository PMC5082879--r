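#' Hypergeometric over-representation of a gene list in gene sets
#'
#' For each set, tests whether the query list overlaps the set more than
#' expected when drawing `q` genes at random from the universe of `N`
#' measured genes: `p = P(X >= k)` with
#' `X ~ Hypergeometric(N, s, q)`, where `s` is the set size after
#' restriction to the universe and `k` the observed overlap. P-values are
#' Benjamini-Hochberg adjusted across sets.
#'
#' @param query character vector of genes of interest. Genes outside the
#'   universe are dropped with a warning.
#' @param sets a named list of gene sets (e.g. from [read_gmt()]).
#' @param universe the background gene set — typically the measured genes.
#' @return an `enrichment_result` tibble sorted by p: `set`, `k` (overlap),
#'   `q` (query size in universe), `s` (set size in universe), `N`
#'   (universe size), `p`, `p_adj`.
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe is empty")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  q <- length(query)
  N <- length(universe)
  rows <- purrr::map(names(sets), function(nm) {
    s_genes <- intersect(sets[[nm]], universe)
    s <- length(s_genes)
    k <- length(intersect(query, s_genes))
    # upper tail including k itself
    p <- phyper(k - 1, s, N - s, q, lower.tail = FALSE)
    tibble::tibble(set = nm, k = k, q = q, s = s, N = N, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out <- dplyr::arrange(out, .data$p, .data$set)
  structure(out, class = c("enrichment_result", class(tibble::tibble())))
}
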