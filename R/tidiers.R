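#' Tidy a classification report into one row per split
#'
#' @param x a `classification_report`.
#' @param ... unused.
#' @return tibble with columns `repeat_id`, `auc`.
#' @method tidy classification_report
#' @export
tidy.classification_report <- function(x, ...) {
  tibble::tibble(repeat_id = seq_along(x$auc), auc = x$auc)
}

#' One-row summary of a classification report
#'
#' @param x a `classification_report`.
#' @param ... unused.
#' @return tibble with `signature_type`, `repeats`, `mean_auc`, `sd_auc`.
#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(signature_type = x$signature_type, repeats = x$repeats,
                 mean_auc = x$mean_auc, sd_auc = x$sd_auc)
}

#' Tidy subnetwork results into one row per member gene
#'
#' @param x a `subnet_results` tibble from [discover_subnetworks()].
#' @param ... unused.
#' @return tibble with `subnetwork` (index), `gene`, `ds`, `p_label_perm`.
#' @method tidy subnet_results
#' @export
tidy.subnet_results <- function(x, ...) {
  if (!nrow(x)) return(tibble::tibble(subnetwork = integer(0),
                                      gene = character(0), ds = numeric(0),
                                      p_label_perm = numeric(0)))
  tidyr::unnest(
    tibble::tibble(subnetwork = seq_len(nrow(x)), gene = x$members,
                   ds = x$ds, p_label_perm = x$p_label_perm),
    "gene")
}

#' One-row summary of subnetwork discovery
#'
#' @param x a `subnet_results` tibble.
#' @param ... unused.
#' @return tibble with `n_subnetworks`, `n_genes`, `median_size`, `max_ds`.
#' @method glance subnet_results
#' @export
glance.subnet_results <- function(x, ...) {
  tibble::tibble(
    n_subnetworks = nrow(x),
    n_genes = length(unique(unlist(x$members))),
    median_size = if (nrow(x)) median(x$n_members) else NA_real_,
    max_ds = if (nrow(x)) max(x$ds) else NA_real_)
}

#' Tidy a hub score into one row per partner edge
#'
#' @param x a `hub_score` from [score_hub()].
#' @param ... unused.
#' @return tibble with `hub`, `partner`, `r_ref`, `r_case`, `delta`.
#' @method tidy hub_score
#' @export
tidy.hub_score <- function(x, ...) {
  dplyr::mutate(x$edges, hub = x$hub, .before = 1)
}

#' One-row summary of a hub score
#'
#' @param x a `hub_score`.
#' @param ... unused.
#' @return tibble with `hub`, `m`, `avg_pcc`, and `p_perm` when computed.
#' @method glance hub_score
#' @export
glance.hub_score <- function(x, ...) {
  tibble::tibble(hub = x$hub, m = x$m, avg_pcc = x$avg_pcc,
                 p_perm = if (is.null(x$p_perm)) NA_real_ else x$p_perm)
}

#' Plot the pooled ROC curve of a classification report
#'
#' @param object a `classification_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot classification_report
#' @export
autoplot.classification_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s signature: mean AUC = %.3f",
                      object$signature_type, object$mean_auc)) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of a ranked gene list
#'
#' Fold-change methods show the statistic against rank; test methods show
#' the statistic against -log10(p).
#'
#' @param object a `ranked_genes` tibble from [rank_genes()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ranked_genes
#' @export
autoplot.ranked_genes <- function(object, ...) {
  method <- attr(object, "method")
  df <- tibble::as_tibble(object)
  if (all(is.na(df$p))) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$statistic,
                                          colour = .data$direction)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "Rank", y = "log fold change (case - ref)")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic,
                                          y = -log10(.data$p),
                                          colour = .data$direction)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "Test statistic", y = "-log10 p")
  }
  p + ggplot2::ggtitle(paste("Ranking method:", method)) +
    ggplot2::theme_minimal()
}

#' Plot hub differential-correlation results
#'
#' AvgPCC against -log10 permutation p, one point per hub.
#'
#' @param object a `hub_results` tibble from [score_all_hubs()].
#' @param p_max significance threshold drawn as a reference line.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot hub_results
#' @export
autoplot.hub_results <- function(object, p_max = 0.05, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg_pcc,
                                   y = -log10(.data$p_perm))) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "AvgPCC", y = "-log10 permutation p",
                  title = "Differential hub co-expression") +
    ggplot2::theme_minimal()
}

#' Plot discovered subnetworks: size against discrimination score
#'
#' @param object a `subnet_results` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot subnet_results
#' @export
autoplot.subnet_results <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_members, y = .data$ds)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Subnetwork size", y = "Discrimination score (bits)",
                  title = "Discriminative subnetworks") +
    ggplot2::theme_minimal()
}
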