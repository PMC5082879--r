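#' Build a per-sample feature matrix from a molecular signature
#'
#' Three signature types feed the classifier:
#' \describe{
#'   \item{`de_genes`}{the expression rows of the signature genes, one
#'     feature per gene;}
#'   \item{`subnetworks`}{one feature per subnetwork — the mean z-scored
#'     activity of its members (see [subnetwork_activity()]);}
#'   \item{`hubs`}{one feature per hub — the per-sample co-expression
#'     contribution \eqn{f_h(j) = \mathrm{mean}_p\, z_{h,j} z_{p,j}} over
#'     the hub's measured partners, whose within-group means recover the
#'     group-wise hub-partner correlations.}
#' }
#'
#' @param ds an [expr_dataset()]; for the `subnetworks` and `hubs` types
#'   it should be z-scored ([zscore_normalize()]).
#' @param signature for `de_genes`: a character vector of genes; for
#'   `subnetworks`: a list of member-gene vectors (named, or named after
#'   their first member); for `hubs`: a named list mapping hub gene to its
#'   partner genes.
#' @param type `"de_genes"`, `"subnetworks"` or `"hubs"`.
#' @return a `feature_matrix` list: `values` (features x samples matrix),
#'   `labels`, `type`. Signature entries with no measured genes are dropped
#'   with a warning; an error is raised if none survive.
#' @export
build_features <- function(ds, signature,
                           type = c("de_genes", "subnetworks", "hubs")) {
  type <- match.arg(type)
  stopifnot(inherits(ds, "expr_dataset"))
  measured <- rownames(ds$values)
  if (type == "de_genes") {
    keep <- intersect(signature, measured)
    if (length(keep) < length(signature))
      warning(length(signature) - length(keep),
              " signature gene(s) not measured, dropped")
    if (!length(keep)) stop("no signature gene is measured")
    fm <- ds$values[keep, , drop = FALSE]
  } else if (type == "subnetworks") {
    if (is.null(names(signature)))
      names(signature) <- vapply(signature, `[[`, character(1), 1)
    rows <- lapply(signature, function(mem) {
      mem <- intersect(mem, measured)
      if (!length(mem)) return(NULL)
      subnetwork_activity(ds, mem)
    })
    ok <- !vapply(rows, is.null, logical(1))
    if (any(!ok)) warning(sum(!ok), " subnetwork(s) with no measured gene dropped")
    if (!any(ok)) stop("no subnetwork has measured genes")
    fm <- do.call(rbind, rows[ok])
    rownames(fm) <- paste0("subnet_", names(signature)[ok])
  } else {
    rows <- lapply(names(signature), function(h) {
      partners <- intersect(signature[[h]], measured)
      if (!h %in% measured || !length(partners)) return(NULL)
      z_h <- ds$values[h, ]
      z_p <- ds$values[partners, , drop = FALSE]
      colMeans(z_p * rep(z_h, each = length(partners)))
    })
    names(rows) <- names(signature)
    ok <- !vapply(rows, is.null, logical(1))
    if (any(!ok)) warning(sum(!ok), " hub(s) unusable (hub or partners unmeasured), dropped")
    if (!any(ok)) stop("no usable hub in signature")
    fm <- do.call(rbind, rows[ok])
    rownames(fm) <- paste0("hub_", names(signature)[ok])
  }
  structure(list(values = fm, labels = ds$labels, type = type),
            class = "feature_matrix")
}

# area under the ROC curve by the rank (Mann-Whitney) formula:
# P(score_case > score_ref) + 0.5 P(tie)
.auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# fit a linear SVM on training columns, return decision scores oriented so
# that larger means "more case-like", for arbitrary columns
.svm_scores <- function(train_x, train_y, test_x, cost = 1) {
  fit <- e1071::svm(x = train_x, y = train_y, kernel = "linear",
                    cost = cost, scale = FALSE)
  pred <- predict(fit, test_x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # column name "A/B" means positive decision values favor class A
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  s <- dv[, 1]
  if (first == levels(train_y)[1]) s <- -s # orient toward the case level
  s
}

#' Evaluate an SVM classifier by repeated random splits
#'
#' Monte-Carlo cross-validation: each repeat draws `train_frac` of the
#' samples for training (redrawn if either side of the split lacks a
#' class), standardizes every
#' feature on the training split only, fits a linear-kernel SVM, and scores
#' the held-out samples; the AUC of the decision values (case phenotype
#' positive) is recorded per repeat.
#'
#' @param fm a `feature_matrix` from [build_features()].
#' @param repeats number of random splits (default 50).
#' @param train_frac training fraction (default 2/3).
#' @param cost SVM cost parameter (default 1).
#' @param rng_seed integer seed; fixed seed gives identical reports.
#' @return a `classification_report` list: `auc` (per-repeat vector),
#'   `mean_auc`, `sd_auc` (NA when `repeats == 1`), `roc` (pooled ROC
#'   points tibble), and the configuration echo.
#' @export
evaluate_classifier <- function(fm, repeats = 50, train_frac = 2 / 3,
                                cost = 1, rng_seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"), repeats >= 1)
  y <- fm$labels
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  x <- t(fm$values) # samples x features
  n <- nrow(x)
  n_train <- max(2, round(train_frac * n))
  pos <- levels(y)[2]

  res <- .with_seed(rng_seed, {
    lapply(seq_len(repeats), function(r) {
      # redraw until both classes appear on each side of the split, so the
      # SVM can be fit and the held-out AUC is defined
      for (try in 1:1000) {
        tr <- sample.int(n, n_train)
        te <- setdiff(seq_len(n), tr)
        if (nlevels(droplevels(y[tr])) == 2 &&
            nlevels(droplevels(y[te])) == 2) break
        if (try == 1000) stop("could not draw a two-class split")
      }
      std <- .standardize(x[tr, , drop = FALSE], x[te, , drop = FALSE])
      s <- .svm_scores(std$train, droplevels(y[tr]), std$test, cost)
      list(auc = .auc(s, y[te], pos), scores = s, truth = y[te])
    })
  })
  aucs <- vapply(res, `[[`, numeric(1), "auc")
  pooled <- tibble::tibble(
    score = unlist(lapply(res, `[[`, "scores")),
    truth = unlist(lapply(res, function(r) as.character(r$truth))))
  structure(list(
    auc = aucs, mean_auc = mean(aucs),
    sd_auc = if (repeats > 1) sd(aucs) else NA_real_,
    roc = .roc_points(pooled$score, pooled$truth, pos),
    signature_type = fm$type, repeats = repeats,
    train_frac = train_frac, cost = cost, rng_seed = rng_seed),
    class = "classification_report")
}

# standardize features on training statistics only; constant features are
# left centered but unscaled
.standardize <- function(train, test) {
  mu <- colMeans(train)
  s <- apply(train, 2, sd)
  s[s == 0 | is.na(s)] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, s, "/"),
       test = sweep(sweep(test, 2, mu), 2, s, "/"))
}

.roc_points <- function(scores, truth, positive) {
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(truth[ord] == positive)
  fp <- cumsum(truth[ord] != positive)
  tibble::tibble(fpr = c(0, fp / max(fp[length(fp)], 1)),
                 tpr = c(0, tp / max(tp[length(tp)], 1)))
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "<classification_report> %s signature: mean AUC = %.3f (sd %.3f) over %d split(s)\n",
    x$signature_type, x$mean_auc, x$sd_auc, x$repeats))
  invisible(x)
}

#' Train on one dataset, test on another
#'
#' Fits the linear SVM on every sample of the training feature matrix
#' (features standardized on the training data) and reports the AUC on the
#' full test feature matrix. Features are matched by name and restricted to
#' the intersection.
#'
#' @param fm_train,fm_test `feature_matrix` objects built with the same
#'   signature on two datasets.
#' @param cost SVM cost parameter.
#' @return a `classification_report` with a single AUC.
#' @export
cross_dataset_evaluate <- function(fm_train, fm_test, cost = 1) {
  stopifnot(inherits(fm_train, "feature_matrix"),
            inherits(fm_test, "feature_matrix"))
  common <- intersect(rownames(fm_train$values), rownames(fm_test$values))
  if (!length(common)) stop("no shared features between the two matrices")
  xtr <- t(fm_train$values[common, , drop = FALSE])
  xte <- t(fm_test$values[common, , drop = FALSE])
  y_tr <- fm_train$labels
  pos <- levels(fm_test$labels)[2]
  std <- .standardize(xtr, xte)
  s <- .svm_scores(std$train, y_tr, std$test, cost)
  auc <- .auc(s, fm_test$labels, pos)
  structure(list(
    auc = auc, mean_auc = auc, sd_auc = NA_real_,
    roc = .roc_points(s, as.character(fm_test$labels), pos),
    signature_type = fm_train$type, repeats = 1L,
    train_frac = 1, cost = cost, rng_seed = NA_integer_),
    class = "classification_report")
}
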