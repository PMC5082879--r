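#' Identify hub genes: nodes with enough measured interaction partners
#'
#' A hub must have at least `min_degree` interaction partners that are
#' measured in the dataset — unmeasured partners contribute nothing to the
#' correlation statistic and do not count.
#'
#' @param graph PPI igraph.
#' @param zds an [expr_dataset()] (only the measured gene set is used).
#' @param min_degree minimum measured-partner count (default 5).
#' @return character vector of hub genes (sorted).
#' @export
identify_hubs <- function(graph, zds, min_degree = 5) {
  measured <- rownames(zds$values)
  nodes <- igraph::V(graph)$name
  n_meas <- vapply(nodes, function(v) {
    sum(igraph::neighbors(graph, v)$name %in% measured)
  }, integer(1))
  sort(nodes[n_meas >= min_degree])
}

#' Score a hub's differential partner co-expression
#'
#' For each measured interaction partner I of hub H, the difference of
#' within-group Pearson correlations
#' \eqn{\nabla r_{H,I} = r_{ref}(H,I) - r_{case}(H,I)} is computed, and the
#' hub statistic is the scaled average of absolute differences
#' \deqn{AvgPCC = \frac{1}{m-1} \sum_{i=1}^{m} |\nabla r_{H,I_i}|}
#' where m is the number of usable partners. The 1/(m-1) prefactor follows
#' the method's published form and cancels in the permutation test;
#' `prefactor = "m"` gives the plain mean. Partners with zero variance in
#' either group cannot yield a correlation and are excluded (and counted).
#'
#' @param hub hub gene (must be measured and in the graph).
#' @param graph PPI igraph.
#' @param ds an [expr_dataset()] (raw or z-scored; Pearson correlation is
#'   invariant to per-gene affine scaling).
#' @param prefactor `"m-1"` (default) or `"m"`.
#' @return a `hub_score` list: `hub`, `edges` (tibble with partner, r_ref,
#'   r_case, delta), `m`, `avg_pcc`, `n_excluded`.
#' @export
score_hub <- function(hub, graph, ds, prefactor = c("m-1", "m")) {
  prefactor <- match.arg(prefactor)
  stopifnot(inherits(ds, "expr_dataset"))
  if (!hub %in% igraph::V(graph)$name) stop("hub '", hub, "' not in graph")
  if (!hub %in% rownames(ds$values)) stop("hub '", hub, "' not measured")
  partners <- intersect(igraph::neighbors(graph, hub)$name,
                        rownames(ds$values))
  idx <- .group_idx(ds$labels)
  if (length(idx$ref) < 3 || length(idx$case) < 3)
    stop("need >= 3 samples per group for within-group correlations")
  res <- .hub_edge_deltas(ds$values, hub, partners, idx$ref, idx$case)
  st <- .avg_pcc(res$delta[res$usable], prefactor)
  structure(list(
    hub = hub,
    edges = tibble::tibble(partner = partners,
                           r_ref = res$r_ref, r_case = res$r_case,
                           delta = res$delta)[res$usable, ],
    m = sum(res$usable), avg_pcc = st,
    n_excluded = sum(!res$usable), prefactor = prefactor),
    class = "hub_score")
}

.hub_edge_deltas <- function(values, hub, partners, ref_idx, case_idx) {
  h_ref <- values[hub, ref_idx]
  h_case <- values[hub, case_idx]
  p_ref <- values[partners, ref_idx, drop = FALSE]
  p_case <- values[partners, case_idx, drop = FALSE]
  sd0 <- function(x) sd(x) == 0
  usable <- !(apply(p_ref, 1, sd0) | apply(p_case, 1, sd0)) &
    !sd0(h_ref) & !sd0(h_case)
  r_ref <- rep(NA_real_, length(partners))
  r_case <- rep(NA_real_, length(partners))
  if (any(usable)) {
    r_ref[usable] <- as.vector(cor(h_ref, t(p_ref[usable, , drop = FALSE])))
    r_case[usable] <- as.vector(cor(h_case, t(p_case[usable, , drop = FALSE])))
  }
  list(r_ref = r_ref, r_case = r_case, delta = r_ref - r_case,
       usable = usable)
}

.avg_pcc <- function(deltas, prefactor = "m-1") {
  m <- length(deltas)
  if (m == 0) return(NA_real_)
  denom <- if (prefactor == "m-1") max(m - 1, 1) else m
  sum(abs(deltas)) / denom
}

#' @export
print.hub_score <- function(x, ...) {
  cat(sprintf("<hub_score> %s: m = %d partners, AvgPCC = %.4f", x$hub, x$m,
              x$avg_pcc))
  if (!is.null(x$p_perm)) cat(sprintf(", p_perm = %.3g", x$p_perm))
  cat("\n")
  invisible(x)
}

#' Label-permutation significance of a hub score
#'
#' Shuffles the phenotype labels, recomputes AvgPCC for the hub each time,
#' and reports the add-one empirical p-value
#' (#null >= observed + 1) / (reps + 1).
#'
#' @param score a `hub_score` from [score_hub()].
#' @param graph PPI igraph.
#' @param ds the dataset used for scoring.
#' @param reps permutations (default 1000, >= 100).
#' @param rng_seed integer seed.
#' @return `score` with elements `p_perm` and `null` (the null AvgPCC
#'   values).
#' @export
hub_significance <- function(score, graph, ds, reps = 1000, rng_seed = 1L) {
  stopifnot(inherits(score, "hub_score"))
  if (reps < 100) stop("reps must be >= 100")
  partners <- score$edges$partner
  n <- ncol(ds$values)
  n_ref <- sum(ds$labels == ref_level(ds))
  null <- .with_seed(rng_seed, vapply(seq_len(reps), function(i) {
    perm <- sample.int(n)
    res <- .hub_edge_deltas(ds$values, score$hub, partners,
                            perm[seq_len(n_ref)], perm[-seq_len(n_ref)])
    .avg_pcc(res$delta[res$usable], score$prefactor)
  }, numeric(1)))
  score$p_perm <- (sum(null >= score$avg_pcc, na.rm = TRUE) + 1) / (reps + 1)
  score$null <- null
  score
}

#' Score and test every hub in one call
#'
#' @param graph PPI igraph.
#' @param ds an [expr_dataset()].
#' @param min_degree minimum measured-partner count (default 5).
#' @param reps label permutations per hub (default 1000).
#' @param rng_seed integer seed (a sub-seed is derived per hub).
#' @param prefactor see [score_hub()].
#' @return a `hub_results` tibble: `hub`, `m`, `avg_pcc`, `p_perm`, plus a
#'   `scores` attribute holding the full `hub_score` objects.
#' @export
score_all_hubs <- function(graph, ds, min_degree = 5, reps = 1000,
                           rng_seed = 1L, prefactor = c("m-1", "m")) {
  prefactor <- match.arg(prefactor)
  hubs <- identify_hubs(graph, ds, min_degree)
  scores <- lapply(seq_along(hubs), function(i) {
    s <- score_hub(hubs[i], graph, ds, prefactor)
    hub_significance(s, graph, ds, reps = reps,
                     rng_seed = .derive_seed(rng_seed, i))
  })
  out <- tibble::tibble(
    hub = hubs,
    m = vapply(scores, `[[`, integer(1), "m"),
    avg_pcc = vapply(scores, `[[`, numeric(1), "avg_pcc"),
    p_perm = vapply(scores, `[[`, numeric(1), "p_perm"))
  out <- dplyr::arrange(out, dplyr::desc(.data$avg_pcc))
  structure(out, scores = scores,
            class = c("hub_results", class(tibble::tibble())))
}

#' Compare two Pearson correlations with Fisher's z transformation
#'
#' Tests whether a correlation observed in the reference group exceeds the
#' one observed in the case group:
#' \deqn{Z = \frac{\mathrm{atanh}(r_{ref}) - \mathrm{atanh}(r_{case})}
#'            {\sqrt{1/(n_{ref}-3) + 1/(n_{case}-3)}}}
#' The default p-value is the one-sided upper tail (alternative: the
#' correlation decreases in the case phenotype); `tail = "two"` doubles the
#' smaller tail.
#'
#' @param r_ref,r_case sample correlations, strictly inside (-1, 1).
#' @param n_ref,n_case group sizes (>= 4 each).
#' @param tail `"one"` (default) or `"two"`.
#' @return a tibble with columns `r_ref`, `r_case`, `n_ref`, `n_case`,
#'   `z_stat`, `p`.
#' @export
fisher_z_compare <- function(r_ref, n_ref, r_case, n_case,
                             tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (any(abs(c(r_ref, r_case)) >= 1))
    stop("correlations must be strictly inside (-1, 1)")
  if (any(c(n_ref, n_case) < 4)) stop("need n >= 4 in each group")
  z <- (atanh(r_ref) - atanh(r_case)) /
    sqrt(1 / (n_ref - 3) + 1 / (n_case - 3))
  p <- if (tail == "one") pnorm(z, lower.tail = FALSE)
       else 2 * pnorm(abs(z), lower.tail = FALSE)
  tibble::tibble(r_ref = r_ref, r_case = r_case,
                 n_ref = n_ref, n_case = n_case, z_stat = z, p = p)
}

#' Rank broker proteins that bridge isolated significant hubs
#'
#' Builds the graph induced on the significant hubs; hubs that land in
#' singleton components are "orphans". Every non-hub protein is ranked by
#' how many orphans it is adjacent to in the full interaction graph, and
#' brokers are added greedily (ties broken by symbol) until no remaining
#' orphan can gain a connection.
#'
#' @param significant_hubs character vector of significant hub genes.
#' @param graph the full PPI igraph.
#' @return a list: `brokers` (tibble with broker, n_orphans_connected, in
#'   selection order), `orphans_initial`, `orphans_unbridged`, and
#'   `bridged_network` (igraph induced on hubs plus chosen brokers).
#' @export
find_brokers <- function(significant_hubs, graph) {
  hubs <- intersect(significant_hubs, igraph::V(graph)$name)
  sub <- igraph::induced_subgraph(graph, hubs)
  comp <- igraph::components(sub)
  orphan <- igraph::V(sub)$name[comp$csize[comp$membership] == 1]
  orphans_initial <- sort(orphan)
  nonhubs <- setdiff(igraph::V(graph)$name, hubs)

  chosen <- character(0)
  n_conn <- integer(0)
  while (length(orphan)) {
    counts <- vapply(nonhubs, function(v) {
      sum(igraph::neighbors(graph, v)$name %in% orphan)
    }, integer(1))
    if (!length(counts) || max(counts) == 0) break
    top <- sort(names(counts)[counts == max(counts)])[1]
    chosen <- c(chosen, top)
    n_conn <- c(n_conn, max(counts))
    orphan <- setdiff(orphan, igraph::neighbors(graph, top)$name)
    nonhubs <- setdiff(nonhubs, top)
  }
  list(brokers = tibble::tibble(broker = chosen, n_orphans_connected = n_conn),
       orphans_initial = orphans_initial,
       orphans_unbridged = sort(orphan),
       bridged_network = igraph::induced_subgraph(graph, c(hubs, chosen)))
}

#' Hubs significant in both datasets
#'
#' @param resA,resB `hub_results` tibbles from [score_all_hubs()].
#' @param p_max permutation p threshold (default 0.05).
#' @return sorted character vector of shared significant hubs.
#' @export
cross_dataset_hubs <- function(resA, resB, p_max = 0.05) {
  sort(intersect(resA$hub[resA$p_perm < p_max],
                 resB$hub[resB$p_perm < p_max]))
}
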