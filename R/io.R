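#' Read a tab-separated gene expression table
#'
#' Expression tables have gene identifiers in the first column and one
#' column per sample, with a header row of sample identifiers. Values are
#' expected on the log2 scale. Duplicate gene identifiers are allowed at
#' load time (collapse them with [collapse_duplicate_genes()]); duplicate
#' sample identifiers, empty tables, and non-numeric or missing cells are
#' rejected so downstream spectra stay deterministic.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (genes x samples) with gene ids as rownames and
#'   sample ids as colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L || ncol(tab) < 2L) stop("empty expression table: ", path)
  gene_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  values <- suppressWarnings(
    vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  values <- matrix(values, nrow = nrow(tab),
                   dimnames = list(gene_ids, sample_ids))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], sample_ids[bad[2L]]))
  }
  values
}

#' Write an expression matrix as TSV
#'
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @param id_column Name used for the gene id column header.
#' @export
write_expression <- function(expr, path, id_column = "gene_id") {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  out <- data.frame(rownames(expr), expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out)[1L] <- id_column
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' GMT is the standard tab-separated carrier for gene-set collections
#' (e.g. MSigDB): one set per line as `name<TAB>description<TAB>member...`.
#' Member genes repeated within one line are deduplicated (first occurrence
#' kept); a duplicate set name is an error because set names index spectrum
#' columns.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection` object.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3L))
    stop("malformed GMT line ", which(n_fields < 3L)[1L],
         ": expected at least 3 tab-separated fields")
  nm <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  desc <- vapply(fields, `[`, character(1L), 2L)
  names(desc) <- nm
  gene_set_collection(sets, desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene identifiers; the list
#'   order is the spectrum column order.
#' @param descriptions Optional named character vector of descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("gene set names must be unique")
  if (any(lengths(sets) < 1L)) stop("every gene set needs at least one member")
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  } else {
    descriptions <- stats::setNames(as.character(descriptions[names(sets)]),
                                    names(sets))
    descriptions[is.na(descriptions)] <- ""
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, member sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read per-sample class labels
#'
#' Two-column TSV: sample id, class label. Returns a named factor whose
#' levels form the class vocabulary (order of first appearance unless all
#' labels sort naturally; levels are kept in first-appearance order so the
#' vocabulary is stable).
#'
#' @param path Path to a two-column TSV with a header row.
#' @return Named factor of labels, names are sample ids.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L || nrow(tab) == 0L) stop("label file needs two columns")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample id(s) in labels: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lab <- as.character(tab[[2L]])
  stats::setNames(factor(lab, levels = unique(lab)), ids)
}

#' Write labels as two-column TSV
#' @param labels Named factor or character vector.
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  stopifnot(!is.null(names(labels)))
  utils::write.table(
    data.frame(sample_id = names(labels), label = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse duplicate gene rows
#'
#' Microarray tables often carry several probes per gene; keeping them all
#' would overweight those genes in the running-sum enrichment statistic.
#' Among rows sharing a gene id, the row with the highest mean expression
#' across samples is retained (ties: first occurrence). The relative row
#' order of the retained rows is preserved, so the operation is idempotent.
#'
#' @param expr Numeric matrix, genes x samples, rownames may repeat.
#' @return Matrix with unique rownames.
#' @export
collapse_duplicate_genes <- function(expr) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  ids <- rownames(expr)
  if (!anyDuplicated(ids)) return(expr)
  means <- rowMeans(expr)
  keep <- vapply(split(seq_along(ids), factor(ids, levels = unique(ids))),
                 function(idx) idx[which.max(means[idx])], integer(1L))
  expr[sort(keep), , drop = FALSE]
}

#' Log-transform scaled abundance estimates to log2 TPM
#'
#' Scaled per-gene abundance estimates (fractions summing to ~1 per sample)
#' are converted to transcripts per million by multiplying with 10^6, then
#' log2-transformed with a pseudocount of 1 so zero abundance maps to 0.
#'
#' @param raw Nonnegative numeric matrix of scaled abundance estimates.
#' @param pseudocount Added before the log; default 1.
#' @return log2(raw * 1e6 + pseudocount), same shape and dimnames.
#' @export
tpm_log_transform <- function(raw, pseudocount = 1) {
  if (any(raw < 0)) stop("negative abundance estimate")
  log2(raw * 1e6 + pseudocount)
}

#' Rank genes by variability (median absolute deviation)
#'
#' Genes are ordered by descending raw MAD across samples (no 1.4826 scale
#' constant -- it does not change the ranking). Ties keep input gene order.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param k Number of top-variable gene ids to return, 1 <= k <= nrow(expr).
#' @return Character vector of k gene ids, most variable first.
#' @export
select_top_variable_genes <- function(expr, k) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (k < 1L || k > nrow(expr))
    stop("k must be between 1 and the number of genes (", nrow(expr), ")")
  mads <- apply(expr, 1L, function(x) stats::median(abs(x - stats::median(x))))
  ord <- order(-mads, seq_along(mads))
  rownames(expr)[ord[seq_len(k)]]
}
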