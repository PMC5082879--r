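#' Per-sample activity of a subnetwork
#'
#' The activity of a member set in sample j is the mean of the members'
#' z-scored expression values in that sample. The averaging convention is
#' configurable: `"mean"` (1/n, the default), or `"sqrt"` (1/sqrt(n), the
#' normalization that keeps activity variance comparable across sizes under
#' independence).
#'
#' @param zds a z-scored [expr_dataset()] (see [zscore_normalize()]).
#' @param members character vector of member genes (duplicates ignored).
#' @param scaling `"mean"` or `"sqrt"`.
#' @return named numeric vector of per-sample activity.
#' @export
subnetwork_activity <- function(zds, members, scaling = c("mean", "sqrt")) {
  scaling <- match.arg(scaling)
  members <- unique(members)
  if (!length(members)) stop("members is empty")
  missing <- setdiff(members, rownames(zds$values))
  if (length(missing))
    stop("unmeasured member gene(s): ", paste(missing, collapse = ", "))
  m <- zds$values[members, , drop = FALSE]
  tot <- colSums(m)
  if (scaling == "mean") tot / length(members) else tot / sqrt(length(members))
}

#' Equal-width discretization of a per-sample activity vector
#'
#' Splits the activity range into `m = floor(log2(S)) + 1` equal-width bins
#' (S = number of samples), padding both extremes by
#' `delta = 1e-6 * (max - min)` (or `1e-6` for a degenerate range) so every
#' value falls in exactly one bin.
#'
#' @param activity numeric vector.
#' @param n_bins optional override of the bin count.
#' @return integer vector of bin indices in `1..m`, with attribute `breaks`.
#' @export
discretize_activity <- function(activity, n_bins = NULL) {
  s <- length(activity)
  m <- if (is.null(n_bins)) floor(log2(s)) + 1L else as.integer(n_bins)
  rng <- range(activity)
  delta <- 1e-6 * (rng[2] - rng[1])
  if (delta == 0) delta <- 1e-6
  breaks <- seq(rng[1] - delta, rng[2] + delta, length.out = m + 1L)
  bins <- findInterval(activity, breaks, rightmost.closed = TRUE)
  attr(bins, "breaks") <- breaks
  bins
}

#' Discrimination score: mutual information of binned activity and phenotype
#'
#' The plugin mutual information, in bits, between the equal-width-binned
#' activity (see [discretize_activity()]) and the two-class phenotype label:
#' \deqn{DS = \sum_{k,y} \hat p(k,y) \log_2 \frac{\hat p(k,y)}{\hat p(k)\hat p(y)}}
#' with \eqn{0 \log 0 := 0}. A perfectly separating activity on balanced
#' classes scores 1 bit; constant activity scores 0.
#'
#' @param activity per-sample activity vector.
#' @param labels two-level phenotype factor of equal length.
#' @return the score in bits (>= 0).
#' @export
discrimination_score <- function(activity, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("labels are constant")
  if (length(activity) != length(labels)) stop("length mismatch")
  bins <- discretize_activity(activity)
  .mi_bits(bins, labels)
}

# plugin MI in bits from two discrete vectors
.mi_bits <- function(x, y) {
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  expd <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / expd[nz]))
}

#' Grow a discriminative subnetwork greedily from a seed gene
#'
#' Starting from the seed alone, each iteration scores every graph neighbor
#' of the current member set (restricted to measured genes within
#' shortest-path distance 2 of the seed) by the discrimination score of the
#' enlarged set's activity. The best candidate (ties broken by gene symbol)
#' is accepted only if it improves the current score by at least
#' `min_improvement` in relative terms; otherwise growth stops. A hard size
#' cap bounds the search.
#'
#' @param seed seed gene (must be in the graph and measured).
#' @param graph PPI igraph.
#' @param zds z-scored [expr_dataset()].
#' @param min_improvement minimum relative DS gain to accept a step
#'   (default 0.1).
#' @param max_size hard cap on member count (default 20).
#' @param max_dist maximum shortest-path distance of any member from the
#'   seed (default 2).
#' @param scaling activity scaling, see [subnetwork_activity()].
#' @return a `scored_subnetwork` list: `seed`, `members`, `activity`, `ds`,
#'   and `trace` (tibble of accepted steps with the DS after each).
#' @export
grow_subnetwork <- function(seed, graph, zds, min_improvement = 0.1,
                            max_size = 20, max_dist = 2,
                            scaling = c("mean", "sqrt")) {
  scaling <- match.arg(scaling)
  if (!seed %in% igraph::V(graph)$name) stop("seed '", seed, "' not in graph")
  if (!seed %in% rownames(zds$values)) stop("seed '", seed, "' not measured")
  measured <- rownames(zds$values)
  # admissible candidate pool: measured genes within max_dist of the seed
  dist_to_seed <- igraph::distances(graph, v = seed)[1, ]
  pool <- names(dist_to_seed)[dist_to_seed <= max_dist]
  pool <- intersect(pool, measured)

  members <- seed
  ds_cur <- discrimination_score(
    subnetwork_activity(zds, members, scaling), zds$labels)
  trace <- list(list(gene = seed, ds = ds_cur))

  while (length(members) < max_size) {
    nb <- unique(unlist(lapply(members, function(v)
      igraph::neighbors(graph, v)$name)))
    cand <- sort(setdiff(intersect(nb, pool), members))
    if (!length(cand)) break
    ds_new <- vapply(cand, function(g) {
      discrimination_score(
        subnetwork_activity(zds, c(members, g), scaling), zds$labels)
    }, numeric(1))
    best <- which.max(ds_new) # ties: first of the sorted candidates
    gain <- if (ds_cur > 0) (ds_new[best] - ds_cur) / ds_cur
            else if (ds_new[best] > 0) Inf else 0
    if (gain < min_improvement) break
    members <- c(members, cand[best])
    ds_cur <- ds_new[[best]]
    trace <- c(trace, list(list(gene = cand[best], ds = ds_cur)))
  }
  structure(list(
    seed = seed, members = members,
    activity = subnetwork_activity(zds, members, scaling),
    ds = ds_cur,
    trace = tibble::tibble(
      step = seq_along(trace) - 1L,
      gene = vapply(trace, `[[`, character(1), "gene"),
      ds = vapply(trace, `[[`, numeric(1), "ds")),
    scaling = scaling), class = "scored_subnetwork")
}

#' @export
print.scored_subnetwork <- function(x, ...) {
  cat(sprintf("<scored_subnetwork> seed %s, %d members, DS = %.4f bits\n",
              x$seed, length(x$members), x$ds))
  if (!is.null(x$p_values))
    cat(sprintf("  p(random, same seed) = %.3g; p(random, other seed) = %.3g; p(label perm) = %.3g\n",
                x$p_values[["p_random_same_seed"]],
                x$p_values[["p_random_other_seed"]],
                x$p_values[["p_label_perm"]]))
  invisible(x)
}

#' Permutation significance of a scored subnetwork
#'
#' Three empirical nulls for the observed discrimination score:
#' \enumerate{
#'   \item random gene sets of the same size containing the same seed;
#'   \item random gene sets of the same size with a different random seed
#'     gene;
#'   \item phenotype labels permuted while the member set is held fixed.
#' }
#' Random gene sets are drawn uniformly from the measured genes without a
#' connectivity requirement. Each p-value uses the add-one estimator
#' (#null >= observed + 1) / (reps + 1), so it is never zero.
#'
#' @param sn a `scored_subnetwork` from [grow_subnetwork()].
#' @param zds the z-scored dataset used to grow it.
#' @param reps permutations per null (default 10000, >= 100).
#' @param rng_seed integer seed.
#' @return `sn` with a `p_values` element: named vector
#'   `p_random_same_seed`, `p_random_other_seed`, `p_label_perm`.
#' @export
subnetwork_significance <- function(sn, zds, reps = 10000, rng_seed = 1L) {
  stopifnot(inherits(sn, "scored_subnetwork"))
  if (reps < 100) stop("reps must be >= 100")
  measured <- rownames(zds$values)
  k <- length(sn$members)
  labels <- zds$labels
  scaling <- sn$scaling

  sn$p_values <- .with_seed(rng_seed, {
    others <- setdiff(measured, sn$seed)
    null1 <- vapply(seq_len(reps), function(i) {
      mem <- c(sn$seed, if (k > 1) sample(others, k - 1))
      discrimination_score(subnetwork_activity(zds, mem, scaling), labels)
    }, numeric(1))
    null2 <- vapply(seq_len(reps), function(i) {
      s2 <- sample(others, 1)
      mem <- c(s2, if (k > 1) sample(setdiff(measured, s2), k - 1))
      discrimination_score(subnetwork_activity(zds, mem, scaling), labels)
    }, numeric(1))
    null3 <- vapply(seq_len(reps), function(i) {
      discrimination_score(sn$activity, sample(labels))
    }, numeric(1))
    c(p_random_same_seed = (sum(null1 >= sn$ds) + 1) / (reps + 1),
      p_random_other_seed = (sum(null2 >= sn$ds) + 1) / (reps + 1),
      p_label_perm = (sum(null3 >= sn$ds) + 1) / (reps + 1))
  })
  sn
}

#' Discover all significant discriminative subnetworks
#'
#' Grows a subnetwork from every seed, scores the three permutation nulls,
#' and keeps those with `DS >= ds_min` and the required permutation p-values
#' below `p_max`. Identical member sets discovered from different seeds are
#' collapsed to one record listing all their seeds.
#'
#' @param zds z-scored [expr_dataset()].
#' @param graph PPI igraph.
#' @param seeds seed genes; default every measured gene present in the graph.
#' @param ds_min minimum discrimination score (default 0.66).
#' @param p_max permutation p threshold (default 1e-4).
#' @param require_nulls which nulls must pass `p_max`: any subset of
#'   `c("same_seed", "other_seed", "label_perm")`; default all three.
#' @param reps permutations per null.
#' @param rng_seed integer seed.
#' @param ... passed to [grow_subnetwork()].
#' @return a `subnet_results` tibble: `seed` (list-column of seed genes),
#'   `members` (list-column), `n_members`, `ds`, the three p-value columns,
#'   plus a `subnetworks` attribute holding the full `scored_subnetwork`
#'   objects.
#' @export
discover_subnetworks <- function(zds, graph, seeds = NULL, ds_min = 0.66,
                                 p_max = 1e-4,
                                 require_nulls = c("same_seed", "other_seed", "label_perm"),
                                 reps = 10000, rng_seed = 1L, ...) {
  require_nulls <- match.arg(require_nulls, several.ok = TRUE)
  if (is.null(seeds))
    seeds <- intersect(rownames(zds$values), igraph::V(graph)$name)
  grown <- lapply(seq_along(seeds), function(i) {
    sn <- grow_subnetwork(seeds[i], graph, zds, ...)
    if (sn$ds < ds_min) return(NULL) # p-values cannot rescue a low DS
    subnetwork_significance(sn, zds, reps = reps,
                            rng_seed = .derive_seed(rng_seed, i))
  })
  grown <- grown[!vapply(grown, is.null, logical(1))]
  pass <- vapply(grown, function(sn) {
    p <- sn$p_values
    ok <- c(same_seed = p[["p_random_same_seed"]] < p_max,
            other_seed = p[["p_random_other_seed"]] < p_max,
            label_perm = p[["p_label_perm"]] < p_max)
    all(ok[require_nulls])
  }, logical(1))
  grown <- grown[pass]

  # deduplicate identical member sets, accumulating seeds
  key <- vapply(grown, function(sn) paste(sort(sn$members), collapse = ";"),
                character(1))
  uniq <- !duplicated(key)
  recs <- lapply(which(uniq), function(i) {
    sn <- grown[[i]]
    sn$all_seeds <- sort(unique(vapply(grown[key == key[i]], `[[`,
                                       character(1), "seed")))
    sn
  })
  out <- tibble::tibble(
    seed = lapply(recs, `[[`, "all_seeds"),
    members = lapply(recs, `[[`, "members"),
    n_members = vapply(recs, function(r) length(r$members), integer(1)),
    ds = vapply(recs, `[[`, numeric(1), "ds"),
    p_random_same_seed = vapply(recs, function(r)
      r$p_values[["p_random_same_seed"]], numeric(1)),
    p_random_other_seed = vapply(recs, function(r)
      r$p_values[["p_random_other_seed"]], numeric(1)),
    p_label_perm = vapply(recs, function(r)
      r$p_values[["p_label_perm"]], numeric(1)))
  structure(out, subnetworks = recs,
            class = c("subnet_results", class(tibble::tibble())))
}

#' Overlap of subnetwork discoveries between two datasets
#'
#' @param resultsA,resultsB `subnet_results` tibbles from
#'   [discover_subnetworks()] on two datasets.
#' @return a list: `shared_members` (genes in the member union of both) and
#'   `shared_seeds` (seed genes found in both).
#' @export
cross_dataset_overlap <- function(resultsA, resultsB) {
  memA <- unique(unlist(resultsA$members))
  memB <- unique(unlist(resultsB$members))
  seedA <- unique(unlist(resultsA$seed))
  seedB <- unique(unlist(resultsB$seed))
  list(shared_members = sort(intersect(memA, memB)),
       shared_seeds = sort(intersect(seedA, seedB)))
}
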