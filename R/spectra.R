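#' Per-sample log2 fold changes against a background profile
#'
#' The functional-spectrum transform starts from each sample's deviation
#' from a background signal: `d[g] = sample[g] - background[g]` over the
#' genes the two share. A warning is emitted when fewer than half of the
#' sample's genes are covered by the background.
#'
#' @param sample Named numeric vector, one expression profile (log2 scale).
#' @param background Named numeric vector of per-gene background values.
#' @return Named numeric vector of log2 fold changes over the intersection,
#'   in the sample's gene order.
#' @export
compute_fold_changes <- function(sample, background) {
  stopifnot(!is.null(names(sample)), !is.null(names(background)))
  genes <- names(sample)[names(sample) %in% names(background)]
  if (length(genes) == 0L) stop("no genes shared between sample and background")
  if (length(genes) < 0.5 * length(sample))
    warning(sprintf("background covers only %d of %d sample genes",
                    length(genes), length(sample)))
  sample[genes] - background[genes]
}

#' Rank a fold-change vector into a descending gene list
#'
#' Stable sort: ties keep the input gene order, so rankings are
#' deterministic across runs and platforms.
#'
#' @param fc Named numeric vector of fold changes.
#' @return A `ranked_gene_list`: list with `gene_ids` and non-increasing `d`.
#' @export
rank_genes <- function(fc) {
  stopifnot(!is.null(names(fc)))
  ord <- order(-fc, seq_along(fc))
  structure(list(gene_ids = names(fc)[ord], d = unname(fc[ord])),
            class = "ranked_gene_list")
}

# Running-sum ES on an already-ranked list given a logical hit indicator.
# Hits are weighted by |d| normalised over the hits; every miss is penalised
# by 1/(N - n_hit). The ES is the cumulative-sum value furthest from zero;
# on an exact tie in absolute value the earliest position wins.
es_running_sum <- function(d, hit) {
  n <- length(d)
  n_hit <- sum(hit)
  if (n_hit == 0L)
    stop(errorCondition("gene set has no overlap with the ranked list",
                        class = c("empty_overlap_error", "error", "condition")))
  if (n_hit == n)
    stop("gene set covers the whole ranked list: miss penalty undefined")
  w <- abs(d[hit])
  sw <- sum(w)
  if (sw == 0)
    stop(errorCondition("all hit weights are zero (degenerate fold changes)",
                        class = c("degenerate_weights_error", "error",
                                  "condition")))
  scores <- rep.int(-1 / (n - n_hit), n)
  scores[hit] <- w / sw
  cs <- cumsum(scores)
  cs[which.max(abs(cs))]
}

#' Weighted running-sum enrichment score of one gene set
#'
#' Walks the ranked gene list from top to bottom, stepping up by
#' `|d_g| / sum(|d| over hits)` at genes belonging to the set and down by
#' `1 / (N - |C|)` elsewhere; the enrichment score is the signed extremum of
#' this running sum, always in `[-1, 1]`. Positive scores mean the set's
#' genes concentrate at the top of the ranking.
#'
#' Genes of the set absent from the ranked list are ignored (the observed
#' overlap plays the role of the set). No overlap raises an
#' `empty_overlap_error`; a set covering every ranked gene, or all-zero hit
#' weights, is an error.
#'
#' @param ranked A `ranked_gene_list` from [rank_genes()].
#' @param set Character vector of member gene ids, or a single-set element
#'   of a `gene_set_collection`.
#' @return Enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(ranked, set) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  members <- if (is.list(set)) unlist(set, use.names = FALSE) else set
  es_running_sum(ranked$d, ranked$gene_ids %in% members)
}

#' Functional spectrum of one fold-change vector
#'
#' One enrichment score per set, in collection order. Sets whose overlap
#' with the measured genes falls below `min_overlap` (including empty
#' overlap) receive a score of 0, keeping the spectrum's dimensionality
#' fixed across platforms with different gene coverage -- the property that
#' lets one trained classifier serve data from any platform.
#'
#' @param fc Named numeric vector of log2 fold changes.
#' @param collection A `gene_set_collection`.
#' @param min_overlap Minimum measured genes a set needs for a real score.
#' @return Named numeric vector of enrichment scores (set names).
#' @export
functional_spectrum <- function(fc, collection, min_overlap = 1L) {
  stopifnot(inherits(collection, "gene_set_collection"), min_overlap >= 1L)
  if (length(fc) == 0L) stop("empty fold-change vector")
  ranked <- rank_genes(fc)
  es <- vapply(collection$sets, function(members) {
    hit <- ranked$gene_ids %in% members
    if (sum(hit) < min_overlap) return(0)
    es_running_sum(ranked$d, hit)
  }, numeric(1L))
  es
}

#' Functional spectra of a cohort
#'
#' Transforms an expression matrix into the samples x gene-sets matrix of
#' enrichment scores that is the classifier's input space. The background
#' for each sample's fold changes is either the cohort's per-gene mean
#' (`background = "cohort_mean"`, needs >= 2 samples) or a fixed reference
#' profile (named numeric vector), which also enables single-sample use.
#'
#' @param expr Numeric matrix, genes x samples, unique rownames.
#' @param collection A `gene_set_collection`.
#' @param background `"cohort_mean"` or a named numeric reference profile.
#' @param min_overlap Passed to [functional_spectrum()].
#' @return Numeric matrix, samples x sets, values in `[-1, 1]`.
#' @export
batch_spectra <- function(expr, collection, background = "cohort_mean",
                          min_overlap = 1L) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene ids; run collapse_duplicate_genes() first")
  if (identical(background, "cohort_mean")) {
    if (ncol(expr) < 2L)
      stop("cohort_mean background needs >= 2 samples; ",
           "use a reference profile for single samples")
    bg <- rowMeans(expr)
  } else {
    stopifnot(is.numeric(background), !is.null(names(background)))
    bg <- background
  }
  out <- matrix(NA_real_, nrow = ncol(expr), ncol = length(collection),
                dimnames = list(colnames(expr), names(collection)))
  failures <- character(0L)
  messages <- character(0L)
  for (j in seq_len(ncol(expr))) {
    res <- tryCatch({
      fc <- compute_fold_changes(expr[, j], bg)
      functional_spectrum(fc, collection, min_overlap)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, colnames(expr)[j])
      messages <- c(messages, conditionMessage(res))
    } else {
      out[j, ] <- res
    }
  }
  if (length(failures) > 0L)
    stop("spectra failed for sample(s) ", paste(failures, collapse = ", "),
         ": ", messages[1L])
  out
}

#' Cohort-average reference profile
#'
#' The per-gene arithmetic mean over all cohort samples; stored with a
#' trained model so single samples can later be rescaled against the
#' training cohort's expression landscape.
#'
#' @param expr Numeric matrix, genes x samples.
#' @return Named numeric vector of per-gene means.
#' @export
build_reference <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 1L, !is.null(rownames(expr)))
  rowMeans(expr)
}

#' Single-sample fold changes via reference rescaling
#'
#' A lone sample has no cohort to supply a background, and its platform may
#' scale expression differently from the training data. The sample is
#' therefore rescaled to the reference by ordinary least squares
#' (`lm(sample ~ reference)` over the shared genes); the residuals -- the
#' sample's deviation from its expected expression -- serve as the fold
#' changes. Residuals are invariant to additive shifts of the sample and
#' scale jointly under positive scaling, so enrichment-score ranks survive
#' affine platform distortions.
#'
#' @param sample Named numeric vector, one expression profile.
#' @param reference Named numeric reference profile (see [build_reference()]).
#' @param min_overlap Minimum shared genes for a meaningful fit (default 10).
#' @return Named numeric vector of residual fold changes over shared genes.
#' @export
ssp_fold_changes <- function(sample, reference, min_overlap = 10L) {
  stopifnot(!is.null(names(sample)), !is.null(names(reference)))
  genes <- names(sample)[names(sample) %in% names(reference)]
  if (length(genes) < min_overlap)
    stop(sprintf("only %d genes overlap the reference (need >= %d)",
                 length(genes), min_overlap))
  x <- reference[genes]
  y <- sample[genes]
  if (stats::sd(x) == 0) stop("reference profile is constant over the overlap")
  fit <- stats::lm(y ~ x)
  d <- stats::setNames(unname(stats::residuals(fit)), genes)
  if (max(abs(d)) < 1e-9)
    stop(errorCondition(
      "sample is an affine transform of the reference: all residuals ~ 0",
      class = c("degenerate_weights_error", "error", "condition")))
  d
}

#' Write/read a spectra matrix as TSV (samples in rows)
#' @param spectra Numeric matrix, samples x sets, with dimnames.
#' @param path File path.
#' @export
write_spectra <- function(spectra, path) {
  write_expression(t(spectra), path, id_column = "set_name") # reuse writer
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  t(read_expression(path))
}

#' Write/read a reference profile as two-column TSV
#' @param reference Named numeric vector.
#' @param path File path.
#' @export
write_reference <- function(reference, path) {
  utils::write.table(
    data.frame(gene_id = names(reference), mean_log2_expression = reference),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
}
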