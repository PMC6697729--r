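#' Design of a synthetic subtype cohort
#'
#' The generator emulates the structure the functional-spectrum classifier
#' exploits in real tumours: subtype identity is carried by coordinated
#' expression shifts of whole gene sets (pathways), not by single marker
#' genes. Each class activates its own disjoint gene sets; genes inside an
#' active set are shifted upward by `effect_size` on the log2 scale in
#' samples of that class, on top of gene-level baselines with Gaussian
#' noise.
#'
#' Defaults mirror a compact four-subtype cohort: 2000 genes, 200 samples,
#' 100 gene sets of 20 genes of which 8 are active (2 per class), effect
#' size 2 (a four-fold expression change of pathway members -- a strong but
#' realistic pathway activation on the log2 scale), noise sd 1.
#'
#' @param n_genes,n_samples,n_classes,n_sets,set_size Cohort dimensions.
#' @param active_sets_per_class Named list: class name -> integer indices of
#'   its active sets (disjoint across classes). Default: 2 consecutive sets
#'   per class.
#' @param effect_size Mean log2 shift of active-set member genes (>= 0;
#'   zero gives a signal-free null cohort).
#' @param noise_sd Gaussian noise sd on the log2 scale (> 0).
#' @param seed Integer seed; everything downstream is bit-reproducible.
#' @return A `simulation_design`.
#' @export
simulation_design <- function(n_genes = 2000L, n_samples = 200L,
                              n_classes = 4L, n_sets = 100L, set_size = 20L,
                              active_sets_per_class = NULL,
                              effect_size = 2, noise_sd = 1, seed = 1L) {
  stopifnot(n_genes >= 1L, n_samples >= 1L, n_classes >= 2L, n_sets >= 1L,
            set_size >= 1L, effect_size >= 0, noise_sd > 0)
  if (n_sets * set_size > n_genes)
    stop("n_sets * set_size exceeds n_genes: disjoint sets infeasible")
  classes <- paste0("C", seq_len(n_classes))
  if (is.null(active_sets_per_class)) {
    per <- 2L
    if (n_classes * per > n_sets)
      stop("not enough sets for 2 active sets per class")
    active_sets_per_class <- stats::setNames(
      lapply(seq_len(n_classes), function(k) ((k - 1L) * per + 1L):(k * per)),
      classes)
  }
  idx <- unlist(active_sets_per_class, use.names = FALSE)
  if (anyDuplicated(idx))
    stop("active sets must be disjoint across classes")
  if (any(idx < 1L | idx > n_sets)) stop("active set index out of range")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes), classes = classes,
                 n_sets = as.integer(n_sets), set_size = as.integer(set_size),
                 active_sets_per_class = active_sets_per_class,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Synthetic gene-set collection for a design
#'
#' Disjoint sets of `set_size` genes drawn from the design's gene universe
#' by a seeded permutation; identical seeds give identical collections.
#'
#' @param design A `simulation_design`.
#' @return A `gene_set_collection` of `n_sets` sets.
#' @export
make_collection <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$seed)
  gene_ids <- sprintf("g%05d", seq_len(design$n_genes))
  perm <- sample(gene_ids)
  sets <- lapply(seq_len(design$n_sets), function(s) {
    perm[((s - 1L) * design$set_size + 1L):(s * design$set_size)]
  })
  names(sets) <- sprintf("set%03d", seq_len(design$n_sets))
  gene_set_collection(
    sets, stats::setNames(rep("synthetic gene set", design$n_sets),
                          names(sets)))
}

#' Simulate a subtype-structured expression cohort
#'
#' Gene-level log2 baselines are drawn from Uniform(4, 12); expression is
#' baseline plus Gaussian noise (`noise_sd`), and every gene belonging to
#' an active set of a sample's class is shifted by `+effect_size`. Labels
#' are assigned round-robin, so classes are balanced to within one sample.
#'
#' @param design A `simulation_design`.
#' @return A `synthetic_cohort`: list with `expr` (genes x samples),
#'   `labels` (named factor), `collection`, and `design`.
#' @export
make_cohort <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  collection <- make_collection(design)  # seeds the stream with design$seed
  gene_ids <- sprintf("g%05d", seq_len(design$n_genes))
  sample_ids <- sprintf("s%04d", seq_len(design$n_samples))
  labels <- stats::setNames(
    factor(design$classes[(seq_len(design$n_samples) - 1L) %%
                            design$n_classes + 1L],
           levels = design$classes),
    sample_ids)
  mu <- stats::runif(design$n_genes, 4, 12)
  expr <- matrix(stats::rnorm(design$n_genes * design$n_samples,
                              mean = mu, sd = design$noise_sd),
                 nrow = design$n_genes,
                 dimnames = list(gene_ids, sample_ids))
  for (cls in design$classes) {
    active <- design$active_sets_per_class[[cls]]
    genes <- unlist(collection$sets[active], use.names = FALSE)
    cols <- which(labels == cls)
    expr[genes, cols] <- expr[genes, cols] + design$effect_size
  }
  structure(list(expr = expr, labels = labels, collection = collection,
                 design = design),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d samples, %d classes, %d sets\n",
              nrow(x$expr), ncol(x$expr), x$design$n_classes,
              length(x$collection)))
  invisible(x)
}

#' Platform variant of a cohort
#'
#' Emulates measuring the same samples on a different platform: a random
#' subset of genes is retained (platforms annotate different gene
#' universes) and each kept gene is distorted by a gene-wise affine map
#' `a_g + b_g * x` with `a_g ~ Normal(0, shift_sd)` and
#' `b_g ~ Uniform(scale_range)`.
#'
#' @param cohort A `synthetic_cohort` or an expression matrix.
#' @param keep_fraction Fraction of genes retained, in (0, 1].
#' @param shift_sd Sd of the additive gene-wise shift.
#' @param scale_range Length-2 range of the multiplicative gene-wise scale.
#' @param seed Integer seed.
#' @return Expression matrix over the retained genes (original gene order).
#' @export
make_platform_variant <- function(cohort, keep_fraction = 1, shift_sd = 0,
                                  scale_range = c(1, 1), seed = 1L) {
  expr <- if (inherits(cohort, "synthetic_cohort")) cohort$expr else cohort
  stopifnot(is.matrix(expr), keep_fraction > 0, keep_fraction <= 1,
            length(scale_range) == 2L)
  n_keep <- floor(keep_fraction * nrow(expr))
  if (n_keep < 10L) stop("keep_fraction leaves fewer than 10 genes")
  set.seed(as.integer(seed))
  keep <- sort(sample.int(nrow(expr), n_keep))
  a <- stats::rnorm(n_keep, 0, shift_sd)
  b <- stats::runif(n_keep, scale_range[1L], scale_range[2L])
  out <- expr[keep, , drop = FALSE] * b + a
  out
}

#' Write a complete synthetic cohort to a directory
#'
#' Emits `expression.tsv`, `labels.tsv` and `sets.gmt` -- the standard
#' text fixtures the command-line workflow consumes.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expr, file.path(dir, "expression.tsv"))
  write_labels(cohort$labels, file.path(dir, "labels.tsv"))
  write_gmt(cohort$collection, file.path(dir, "sets.gmt"))
  invisible(dir)
}
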