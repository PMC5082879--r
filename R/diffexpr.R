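#' Z-score normalize each gene across samples
#'
#' Centers and scales every gene row to mean 0 and standard deviation 1
#' across samples (sample standard deviation, denominator n-1, the default;
#' set `sd_denom = "n"` for the population convention). Constant rows carry
#' no normalizable signal and are dropped with a count.
#'
#' @param ds an [expr_dataset()].
#' @param sd_denom `"n-1"` (default) or `"n"`.
#' @return a z-scored [expr_dataset()] with attribute `n_dropped` giving the
#'   number of zero-variance genes removed.
#' @export
zscore_normalize <- function(ds, sd_denom = c("n-1", "n")) {
  stopifnot(inherits(ds, "expr_dataset"))
  sd_denom <- match.arg(sd_denom)
  v <- ds$values
  mu <- rowMeans(v)
  cv <- v - mu
  ss <- rowSums(cv^2)
  denom <- if (sd_denom == "n-1") ncol(v) - 1 else ncol(v)
  s <- sqrt(ss / denom)
  keep <- s > 0
  z <- cv[keep, , drop = FALSE] / s[keep]
  out <- expr_dataset(z, ds$labels, ref_level = ref_level(ds))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Rank genes by a differential-expression method
#'
#' Four rankings of case-vs-reference differential expression: fold change
#' of group means or medians (on the log scale, so a difference), and
#' two-sided t or Wilcoxon rank-sum test p-values. Fold-change methods are
#' ranked by `|statistic|` descending; test methods by p ascending. Ties are
#' broken by gene symbol so rankings are deterministic.
#'
#' @param ds an [expr_dataset()] of log-scale values.
#' @param method one of `"mean_fc"`, `"median_fc"`, `"ttest"`, `"wilcoxon"`.
#' @return a `ranked_genes` tibble with columns `gene`, `statistic` (log
#'   fold change case minus reference for FC methods; the test statistic
#'   otherwise), `p` (NA for FC methods), `direction` (`"up"`/`"down"` in
#'   the case phenotype, from the sign of the method's own location
#'   difference), and `rank`.
#' @export
rank_genes <- function(ds, method = c("mean_fc", "median_fc", "ttest", "wilcoxon")) {
  stopifnot(inherits(ds, "expr_dataset"))
  method <- match.arg(method)
  idx <- .group_idx(ds$labels)
  if (length(idx$ref) < 2 || length(idx$case) < 2)
    stop("need >= 2 samples per group")
  vref <- ds$values[, idx$ref, drop = FALSE]
  vcase <- ds$values[, idx$case, drop = FALSE]
  genes <- rownames(ds$values)

  if (method %in% c("mean_fc", "median_fc")) {
    fun <- if (method == "mean_fc") rowMeans else .row_medians
    stat <- unname(fun(vcase) - fun(vref))
    p <- rep(NA_real_, length(stat))
    ord_key <- -abs(stat)
  } else {
    res <- vapply(seq_along(genes), function(i) {
      if (method == "ttest") {
        ht <- t.test(vcase[i, ], vref[i, ])
      } else {
        ht <- suppressWarnings(wilcox.test(vcase[i, ], vref[i, ], exact = NULL))
      }
      c(unname(ht$statistic), ht$p.value)
    }, numeric(2))
    stat <- res[1, ]
    p <- res[2, ]
    ord_key <- p
  }
  delta <- unname(.row_medians(vcase) - .row_medians(vref))
  if (method == "mean_fc") delta <- stat
  out <- tibble::tibble(
    gene = genes, statistic = stat, p = p,
    direction = ifelse(delta >= 0, "up", "down"))
  out <- out[order(ord_key, out$gene), ]
  out$rank <- seq_len(nrow(out))
  structure(out, method = method,
            class = c("ranked_genes", class(tibble::tibble())))
}

.row_medians <- function(m) apply(m, 1, median)

#' Cross-dataset reproducibility of top-ranked genes
#'
#' The fraction of one ranking's top-k genes also present in the other's
#' top k — the headline measure for comparing DE ranking methods across
#' independent cohorts.
#'
#' @param listA,listB `ranked_genes` tibbles (from [rank_genes()]) over a
#'   shared gene universe.
#' @param k list depth.
#' @return the overlap fraction in `[0, 1]`.
#' @export
reproducibility_rate <- function(listA, listB, k) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(listA) || k > nrow(listB))
    stop("k exceeds ranking length")
  length(intersect(head(listA$gene, k), head(listB$gene, k))) / k
}

#' Null distribution of the reproducibility rate for random gene lists
#'
#' Draws `reps` pairs of random k-gene lists from an N-gene universe and
#' records their overlap fraction; the expected value is k/N. An observed
#' rate can be scored against this null with the add-one empirical p-value
#' (#null >= observed + 1) / (reps + 1).
#'
#' @param n_genes universe size N.
#' @param k list depth.
#' @param reps number of random draws (>= 100).
#' @param rng_seed integer seed.
#' @param observed optional observed rate to score.
#' @return a list: `null` (vector of `reps` rates), `mean`, and — when
#'   `observed` is given — `p`.
#' @export
random_baseline <- function(n_genes, k, reps = 1000, rng_seed = 1L,
                            observed = NULL) {
  stopifnot(reps >= 100, k >= 1, k <= n_genes)
  null <- .with_seed(rng_seed, vapply(seq_len(reps), function(i) {
    length(intersect(sample.int(n_genes, k), sample.int(n_genes, k))) / k
  }, numeric(1)))
  out <- list(null = null, mean = mean(null))
  if (!is.null(observed))
    out$p <- (sum(null >= observed) + 1) / (reps + 1)
  out
}

#' Select genes concordantly differentially expressed in two datasets
#'
#' A gene is concordant when it passes a Wilcoxon p-value threshold and a
#' median fold-change threshold in *both* datasets, with the same direction
#' of change. Each dataset brings its own thresholds and its own fold-change
#' convention: `fc_scale = "log2"` reads `fc_min` directly as a minimum
#' |log2 FC|; `fc_scale = "linear"` reads it as a linear-scale ratio and
#' applies `|log2 FC| > log2(fc_min)`.
#'
#' @param wilcoxA,wilcoxB `ranked_genes` from [rank_genes()] with
#'   `method = "wilcoxon"` on each dataset.
#' @param fcA,fcB `ranked_genes` with `method = "median_fc"` on each dataset.
#' @param p_max_a,p_max_b Wilcoxon p thresholds (exclusive).
#' @param fc_min_a,fc_min_b fold-change thresholds (exclusive).
#' @param fc_scale_a,fc_scale_b `"log2"` or `"linear"` per dataset.
#' @return a `concordance` tibble: `gene`, `p_a`, `fc_a`, `p_b`, `fc_b`,
#'   `direction`; attributes `n_up` and `n_down` count directions in the
#'   case phenotype.
#' @export
select_concordant <- function(wilcoxA, fcA, wilcoxB, fcB,
                              p_max_a, fc_min_a, fc_scale_a = c("log2", "linear"),
                              p_max_b, fc_min_b, fc_scale_b = c("log2", "linear")) {
  stopifnot(p_max_a > 0, p_max_b > 0, fc_min_a > 0, fc_min_b > 0)
  fc_scale_a <- match.arg(fc_scale_a)
  fc_scale_b <- match.arg(fc_scale_b)
  thr_a <- if (fc_scale_a == "log2") fc_min_a else log2(fc_min_a)
  thr_b <- if (fc_scale_b == "log2") fc_min_b else log2(fc_min_b)

  a <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(wilcoxA), "gene", p_a = "p"),
    dplyr::select(tibble::as_tibble(fcA), "gene", fc_a = "statistic"),
    by = "gene")
  b <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(wilcoxB), "gene", p_b = "p"),
    dplyr::select(tibble::as_tibble(fcB), "gene", fc_b = "statistic"),
    by = "gene")
  both <- dplyr::inner_join(a, b, by = "gene")
  keep <- dplyr::filter(
    both,
    .data$p_a < p_max_a, abs(.data$fc_a) > thr_a,
    .data$p_b < p_max_b, abs(.data$fc_b) > thr_b,
    sign(.data$fc_a) == sign(.data$fc_b), .data$fc_a != 0)
  keep <- dplyr::mutate(keep,
    direction = ifelse(.data$fc_a > 0, "up", "down"))
  keep <- dplyr::arrange(keep, .data$gene)
  structure(keep,
            n_up = sum(keep$direction == "up"),
            n_down = sum(keep$direction == "down"),
            class = c("concordance", class(tibble::tibble())))
}

#' Cluster samples on a gene signature and measure phenotype homogeneity
#'
#' Samples are clustered by average-linkage hierarchical clustering on the
#' (1 - Pearson correlation) distance computed over the signature genes, and
#' the tree is cut into `n_clusters` groups. Each cluster's homogeneity is
#' the fraction of its samples carrying the cluster's majority phenotype;
#' the overall score is the sample-weighted mean — 1.0 means the signature
#' separates the phenotypes perfectly.
#'
#' @param ds an [expr_dataset()].
#' @param signature character vector of genes (must all be measured).
#' @param n_clusters number of clusters to cut (default 2).
#' @return a list: `overall` (weighted homogeneity), `clusters` (tibble with
#'   per-cluster size, majority phenotype and homogeneity), `assignments`
#'   (named integer vector sample -> cluster).
#' @export
cluster_homogeneity <- function(ds, signature, n_clusters = 2) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (!length(signature)) stop("signature is empty")
  missing <- setdiff(signature, rownames(ds$values))
  if (length(missing))
    stop("signature gene(s) not measured: ", paste(missing, collapse = ", "))
  sub <- ds$values[signature, , drop = FALSE]
  if (nrow(sub) >= 2) {
    d <- as.dist(1 - cor(sub))
  } else {
    d <- stats::dist(t(sub)) # correlation distance undefined on 1 gene
  }
  cl <- cutree(hclust(d, method = "average"), k = n_clusters)
  per <- tibble::as_tibble(do.call(rbind, lapply(seq_len(n_clusters), function(k) {
    lab <- ds$labels[cl == k]
    tb <- table(lab)
    data.frame(cluster = k, n = length(lab),
               majority = names(tb)[which.max(tb)],
               homogeneity = max(tb) / length(lab))
  })))
  list(overall = sum(per$homogeneity * per$n) / sum(per$n),
       clusters = per, assignments = cl)
}
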