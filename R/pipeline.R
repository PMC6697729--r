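#' Train a subtype classifier from expression data
#'
#' End-to-end training: the cohort is transformed to functional spectra
#' (cohort-mean background), the network is trained on the labelled
#' spectra, and the cohort-average reference profile is stored so the model
#' can later score single samples from any platform.
#'
#' @param expr Numeric matrix, genes x samples, unique rownames.
#' @param labels Named factor of class labels for every sample.
#' @param collection A `gene_set_collection`; its size fixes the network's
#'   input dimension.
#' @param arch Optional `architecture_spec`; defaults to the standard
#'   2000/500/120/30/10 hidden layout sized to the collection and labels.
#' @param config A `training_config`.
#' @param min_overlap Passed to [batch_spectra()].
#' @return A `deep_classifier_model`.
#' @export
train_classifier <- function(expr, labels, collection, arch = NULL,
                             config = training_config(), min_overlap = 1L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!all(colnames(expr) %in% names(labels)))
    stop("unlabeled sample(s): ",
         paste(setdiff(colnames(expr), names(labels)), collapse = ", "))
  labels <- droplevels(labels[colnames(expr)])
  classes <- levels(labels)
  if (is.null(arch))
    arch <- architecture_spec(length(collection), length(classes))
  if (arch$input_dim != length(collection))
    stop("arch input_dim must equal the collection size")
  spectra <- batch_spectra(expr, collection, "cohort_mean", min_overlap)
  fit <- net_train(spectra, labels, arch, config)
  structure(list(params = fit$params, arch = arch,
                 classes = fit$classes, collection = collection,
                 reference = build_reference(expr),
                 training_config = config,
                 loss_trace = fit$loss_trace,
                 format_version = "1.0"),
            class = "deep_classifier_model")
}

#' @export
print.deep_classifier_model <- function(x, ...) {
  cat(sprintf(
    "deep_classifier_model: %d gene sets -> [%s] -> %d classes (%s)\n",
    x$arch$input_dim, paste(x$arch$hidden_dims, collapse = ", "),
    x$arch$n_classes, paste(x$classes, collapse = ", ")))
  invisible(x)
}

# align spectra columns to the model's collection by set NAME; refuse on any
# mismatch to prevent silent misalignment between collections
align_spectra <- function(model, spectra) {
  want <- names(model$collection)
  have <- colnames(spectra)
  if (is.null(have)) stop("spectra matrix has no set names")
  missing <- setdiff(want, have)
  extra <- setdiff(have, want)
  if (length(missing) > 0L || length(extra) > 0L)
    stop("spectra do not match the model's gene sets; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]")
  spectra[, want, drop = FALSE]
}

#' Classify precomputed spectra
#'
#' Each sample is assigned the class with the largest posterior if that
#' posterior strictly exceeds `threshold`, and `"UNCLASSIFIED"` otherwise
#' -- an explicit outcome for samples the model cannot place confidently.
#'
#' @param model A `deep_classifier_model`.
#' @param spectra Numeric matrix, samples x sets; set names must match the
#'   model's collection.
#' @param threshold Posterior cutoff (strict `>`); default 0.5.
#' @return Data frame: `sample_id`, one posterior column per class,
#'   `max_posterior`, `label`.
#' @export
predict_spectra <- function(model, spectra, threshold = 0.5) {
  stopifnot(inherits(model, "deep_classifier_model"))
  spectra <- align_spectra(model, spectra)
  post <- net_forward(model$params, spectra)$posteriors
  colnames(post) <- model$classes
  best <- max.col(post, ties.method = "first")
  max_post <- post[cbind(seq_len(nrow(post)), best)]
  label <- ifelse(max_post > threshold, model$classes[best], "UNCLASSIFIED")
  out <- data.frame(sample_id = rownames(spectra), post,
                    max_posterior = max_post, label = label,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  out
}

#' Classify an expression cohort
#'
#' Computes cohort-mean-background spectra, then classifies them. A single
#' sample cannot define its own cohort background; use
#' [predict_single_sample()] for that case.
#'
#' @inheritParams predict_spectra
#' @param expr Numeric matrix, genes x samples (>= 2 samples).
#' @param min_overlap Passed to [batch_spectra()].
#' @return As [predict_spectra()].
#' @export
predict_expression <- function(model, expr, threshold = 0.5,
                               min_overlap = 1L) {
  if (ncol(expr) < 2L)
    stop("cohort prediction needs >= 2 samples; ",
         "use predict_single_sample() for an individual profile")
  spectra <- batch_spectra(expr, model$collection, "cohort_mean", min_overlap)
  predict_spectra(model, spectra, threshold)
}

#' Classify one sample via the single-sample predictor
#'
#' The profile is rescaled to the model's stored reference (or a supplied
#' override) by linear regression; the residual fold changes yield the
#' spectrum, which is classified as usual. This is the path that makes the
#' classifier usable on individual patients from any platform.
#'
#' @inheritParams predict_spectra
#' @param profile Named numeric vector, one expression profile.
#' @param reference Optional named numeric vector overriding the model's
#'   stored reference profile.
#' @param min_overlap Minimum genes shared with the reference (default 10).
#' @return One-row data frame as [predict_spectra()].
#' @export
predict_single_sample <- function(model, profile, threshold = 0.5,
                                  reference = NULL, min_overlap = 10L) {
  ref <- if (is.null(reference)) model$reference else reference
  d <- ssp_fold_changes(profile, ref, min_overlap)
  es <- functional_spectrum(d, model$collection)
  spectra <- matrix(es, nrow = 1L,
                    dimnames = list("sample", names(model$collection)))
  predict_spectra(model, spectra, threshold)
}

#' Save / load a trained model bundle
#'
#' One file holding the layer weights and biases, architecture, class
#' vocabulary, gene-set collection, reference profile and training
#' configuration. Loading validates that every layer's shape is consistent
#' with the declared architecture.
#'
#' @param model A `deep_classifier_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "deep_classifier_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "deep_classifier_model"))
    stop("not a deep_classifier_model bundle: ", path)
  dims <- layer_dims(model$arch)
  for (l in seq_along(model$params$layers)) {
    W <- model$params$layers[[l]]$W
    if (!all(dim(W) == c(dims[l + 1L], dims[l])))
      stop(sprintf("layer %d weight shape %dx%d inconsistent with architecture",
                   l, nrow(W), ncol(W)))
  }
  if (model$arch$input_dim != length(model$collection))
    stop("model input dimension does not match its gene-set collection")
  if (model$arch$n_classes != length(model$classes))
    stop("model class count does not match its vocabulary")
  model
}

# stratified holdout split: returns list(train=ids, test=ids)
stratified_split <- function(labels, holdout_fraction = 0.3) {
  ids <- names(labels)
  test <- unlist(lapply(split(ids, labels), function(g) {
    sample(g, size = round(length(g) * holdout_fraction))
  }), use.names = FALSE)
  list(train = setdiff(ids, test), test = test)
}

#' Gene-subsampling robustness experiment
#'
#' Measures how classification degrades when spectra are computed from only
#' the top-`size` most variable genes (MAD-ranked over the full cohort),
#' emulating cross-platform gene loss. For every size and repetition a
#' stratified holdout split is drawn, a classifier is trained on the
#' restricted training split, and holdout performance is recorded.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param labels Named factor of class labels.
#' @param collection A `gene_set_collection`.
#' @param sizes Integer vector of gene-subset sizes (each <= nrow(expr)).
#' @param reps Repetitions per size.
#' @param seed Integer seed governing splits and training.
#' @param holdout_fraction Stratified holdout fraction (default 0.3).
#' @param arch Optional `architecture_spec` shared by all runs.
#' @param config `training_config` shared by all runs.
#' @param threshold Posterior cutoff for evaluation.
#' @return Data frame: size, rep, balanced_accuracy, accuracy,
#'   mean_sensitivity, mean_specificity, unclassified_rate.
#' @export
gene_subsampling_experiment <- function(expr, labels, collection, sizes,
                                        reps = 1L, seed = 1L,
                                        holdout_fraction = 0.3, arch = NULL,
                                        config = training_config(),
                                        threshold = 0.5) {
  if (any(sizes > nrow(expr)))
    stop("subset size exceeds the number of genes (", nrow(expr), ")")
  stopifnot(reps >= 1L)
  labels <- labels[colnames(expr)]
  rows <- vector("list", length(sizes) * reps)
  k <- 0L
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    split <- stratified_split(labels, holdout_fraction)
    for (size in sizes) {
      genes <- select_top_variable_genes(expr, size)
      sub <- expr[genes, , drop = FALSE]
      cfg <- config
      cfg$seed <- rep_seeds[r] %% 1000000L + 1L
      model <- train_classifier(sub[, split$train, drop = FALSE],
                                labels[split$train], collection,
                                arch = arch, config = cfg)
      pred <- predict_expression(model, sub[, split$test, drop = FALSE],
                                 threshold)
      rep_metrics <- metrics(confusion(labels[split$test], pred))
      k <- k + 1L
      rows[[k]] <- data.frame(
        size = size, rep = r,
        balanced_accuracy = rep_metrics$mean_balanced_accuracy,
        accuracy = rep_metrics$accuracy,
        mean_sensitivity = rep_metrics$mean_sensitivity,
        mean_specificity = rep_metrics$mean_specificity,
        unclassified_rate = rep_metrics$unclassified_rate)
    }
  }
  do.call(rbind, rows)
}
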