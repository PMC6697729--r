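#' Confusion matrix of subtype predictions
#'
#' Tallies truth x prediction counts over the class vocabulary. Samples the
#' classifier declined to call (`UNCLASSIFIED`) are tallied separately per
#' true class and, by default, excluded from the scored counts -- the
#' decline rate is a quantity of its own, reported alongside accuracy.
#'
#' @param truth Named factor (or character vector) of true labels.
#' @param predictions Data frame from [predict_spectra()] and friends, or a
#'   named character vector of predicted labels.
#' @param include_unclassified Keep an explicit UNCLASSIFIED column in the
#'   returned counts (it is never part of the scored K x K block).
#' @return A `confusion_matrix`: list with `counts` (K x K, rows = truth),
#'   `unclassified` (per-true-class counts), `classes`.
#' @export
confusion <- function(truth, predictions, include_unclassified = TRUE) {
  if (is.data.frame(predictions)) {
    pred <- stats::setNames(predictions$label, predictions$sample_id)
  } else {
    pred <- predictions
  }
  stopifnot(!is.null(names(pred)), !is.null(names(truth)))
  unlabeled <- setdiff(names(pred), names(truth))
  if (length(unlabeled) > 0L)
    stop("predicted sample(s) without a truth label: ",
         paste(unlabeled, collapse = ", "))
  truth <- truth[names(pred)]
  classes <- if (is.factor(truth)) levels(truth) else sort(unique(truth))
  bad <- setdiff(unique(pred), c(classes, "UNCLASSIFIED"))
  if (length(bad) > 0L)
    stop("predicted label(s) outside the vocabulary: ",
         paste(bad, collapse = ", "))
  is_unc <- pred == "UNCLASSIFIED"
  counts <- table(factor(as.character(truth)[!is_unc], levels = classes),
                  factor(pred[!is_unc], levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(truth = classes, prediction = classes))
  unclassified <- table(factor(as.character(truth)[is_unc], levels = classes))
  unclassified <- stats::setNames(as.integer(unclassified), classes)
  structure(list(counts = counts, unclassified = unclassified,
                 classes = classes,
                 include_unclassified = include_unclassified),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- x$counts
  if (x$include_unclassified && any(x$unclassified > 0L))
    m <- cbind(m, UNCLASSIFIED = x$unclassified)
  print(m)
  invisible(x)
}

#' Classification performance metrics
#'
#' Per-class one-vs-rest sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and balanced accuracy `(sensitivity+specificity)/2`, their
#' macro means over classes, overall accuracy (trace over scored total),
#' and the unclassified rate. A class absent from the truth has undefined
#' sensitivity; it is reported as `NA` and excluded from the macro means.
#'
#' @param cm A `confusion_matrix`.
#' @return An `eval_report`: list with `per_class` data frame and scalar
#'   `mean_sensitivity`, `mean_specificity`, `mean_balanced_accuracy`,
#'   `accuracy`, `unclassified_rate`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- cm$counts
  total <- sum(m)
  if (total == 0L) stop("no scored samples")
  tp <- diag(m)
  fn <- rowSums(m) - tp
  fp <- colSums(m) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  bacc <- (sens + spec) / 2
  per_class <- data.frame(class = cm$classes, tp = tp, fn = fn, fp = fp,
                          tn = tn, sensitivity = sens, specificity = spec,
                          balanced_accuracy = bacc, row.names = NULL)
  n_unc <- sum(cm$unclassified)
  structure(list(
    per_class = per_class,
    mean_sensitivity = mean(sens, na.rm = TRUE),
    mean_specificity = mean(spec, na.rm = TRUE),
    mean_balanced_accuracy = mean(bacc, na.rm = TRUE),
    accuracy = sum(tp) / total,
    unclassified_rate = n_unc / (total + n_unc)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$per_class, digits = 4)
  cat(sprintf(paste0("mean sensitivity %.4f | mean specificity %.4f | ",
                     "mean balanced accuracy %.4f\n",
                     "overall accuracy %.4f | unclassified rate %.4f\n"),
              x$mean_sensitivity, x$mean_specificity,
              x$mean_balanced_accuracy, x$accuracy, x$unclassified_rate))
  invisible(x)
}

#' Write an evaluation report as TSV
#' @param report An `eval_report`.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  per <- report$per_class
  summary <- data.frame(
    class = c("mean", "overall"),
    tp = NA, fn = NA, fp = NA, tn = NA,
    sensitivity = c(report$mean_sensitivity, NA),
    specificity = c(report$mean_specificity, NA),
    balanced_accuracy = c(report$mean_balanced_accuracy, report$accuracy))
  utils::write.table(rbind(per, summary), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Average silhouette width of labelled points
#'
#' Quantifies within-class compactness against between-class separation
#' with the standard silhouette coefficient on Euclidean distances
#' (computed via `cluster::silhouette`); singleton-class samples get width
#' 0. Used to compare the deep-feature space with the raw expression space.
#'
#' @param features Numeric matrix, samples x dimensions.
#' @param labels Factor/character labels, one per row (>= 2 classes).
#' @return List with `asw` (mean width) and `widths` (per sample).
#' @export
average_silhouette_width <- function(features, labels) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  cl <- as.integer(factor(as.character(labels)))
  if (length(unique(cl)) < 2L)
    stop("silhouette needs >= 2 classes")
  sil <- cluster::silhouette(cl, dist(features))
  widths <- sil[, "sil_width"]
  list(asw = mean(widths), widths = widths)
}

#' Correlate deep features with gene-set enrichment scores
#'
#' Pearson correlation of every (feature, set) pair over the same samples,
#' plus a per-feature top-k table ranked by |r| -- highly correlated sets,
#' positively or negatively, annotate what each learned feature encodes.
#' A constant feature or set column yields r = 0 with a flag rather than NA.
#'
#' @param features Numeric matrix, samples x features (see [deep_features()]).
#' @param spectra Numeric matrix, samples x sets, same samples in the same
#'   order.
#' @param k Sets listed per feature in the top table.
#' @return List with `correlation` (features x sets), `flagged` (logical
#'   matrix marking constant pairs), `top` (data frame: feature, set_name,
#'   r, rank).
#' @export
feature_set_correlation <- function(features, spectra, k = 10L) {
  features <- as.matrix(features)
  spectra <- as.matrix(spectra)
  if (nrow(features) != nrow(spectra) ||
      (!is.null(rownames(features)) && !is.null(rownames(spectra)) &&
       !identical(rownames(features), rownames(spectra))))
    stop("features and spectra must cover the same samples in the same order")
  const_f <- apply(features, 2L, function(x) stats::sd(x) == 0)
  const_s <- apply(spectra, 2L, function(x) stats::sd(x) == 0)
  r <- suppressWarnings(stats::cor(features, spectra))
  flagged <- outer(const_f, const_s, `|`)
  r[is.na(r)] <- 0
  r[flagged] <- 0
  k <- min(k, ncol(spectra))
  top <- do.call(rbind, lapply(seq_len(nrow(r)), function(i) {
    ord <- order(-abs(r[i, ]), seq_len(ncol(r)))[seq_len(k)]
    data.frame(feature = rownames(r)[i] %||% paste0("DF", i),
               set_name = colnames(r)[ord], r = r[i, ord], rank = seq_len(k),
               row.names = NULL)
  }))
  list(correlation = r, flagged = flagged, top = top)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster deep features by absolute correlation
#'
#' Average-linkage hierarchical clustering on the distance `1 - |r|`
#' between features: a feature and its negation are identical under this
#' metric, so groups collect features encoding the same axis regardless of
#' sign.
#'
#' @param features Numeric matrix, samples x features (>= 2 features).
#' @param groups Number of groups to cut the dendrogram into.
#' @return List with `hclust` (the dendrogram) and `groups` (named integer
#'   membership).
#' @export
feature_cluster <- function(features, groups = 3L) {
  features <- as.matrix(features)
  if (ncol(features) < 2L) stop("need >= 2 features to cluster")
  r <- suppressWarnings(stats::cor(features))
  r[is.na(r)] <- 0
  diag(r) <- 1
  d <- stats::as.dist(1 - abs(r))
  hc <- stats::hclust(d, method = "average")
  groups <- min(groups, ncol(features))
  list(hclust = hc, groups = stats::cutree(hc, k = groups))
}

#' Project samples onto principal components
#'
#' Column-centred PCA (no scaling) used to visualise samples in feature or
#' expression space. Component signs follow a deterministic convention:
#' each component's largest-magnitude loading is made positive.
#'
#' @param x Numeric matrix, samples x dimensions.
#' @param n_components Number of components (<= min(dim(x))).
#' @return List with `scores` (samples x n_components), `loadings`, and
#'   `explained_variance` (fractions of total variance).
#' @export
pca_project <- function(x, n_components = 2L) {
  x <- as.matrix(x)
  if (n_components > min(dim(x)))
    stop("n_components exceeds min(n, p)")
  total_var <- sum(apply(x, 2L, stats::var))
  if (!is.finite(total_var) || total_var == 0)
    stop("degenerate input: zero total variance")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- seq_len(n_components)
  rot <- p$rotation[, keep, drop = FALSE]
  scores <- p$x[, keep, drop = FALSE]
  for (j in keep) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = rot,
       explained_variance = (p$sdev^2 / sum(p$sdev^2))[keep])
}
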