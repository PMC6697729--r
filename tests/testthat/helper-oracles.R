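# Independent oracles used to cross-check the optimized implementations.

# Naive per-position running-sum enrichment score: explicit loop carrying
# the accumulator, tracking the extremum as it goes (earliest wins on ties).
naive_es <- function(d, hit) {
  n <- length(d)
  n_hit <- sum(hit)
  stopifnot(n_hit >= 1L, n_hit < n)
  sw <- sum(abs(d[hit]))
  stopifnot(sw > 0)
  acc <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) acc <- acc + abs(d[i]) / sw else acc <- acc - 1 / (n - n_hit)
    if (abs(acc) > abs(best)) best <- acc
  }
  best
}

# Classic unweighted KS running-sum statistic: every hit steps up 1/|C|.
unweighted_ks <- function(n, hit) {
  n_hit <- sum(hit)
  acc <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (hit[i]) acc <- acc + 1 / n_hit else acc <- acc - 1 / (n - n_hit)
    if (abs(acc) > abs(best)) best <- acc
  }
  best
}

# Random ranked-list + set instance for property checks. Guarantees a
# proper subset overlap and nonzero hit weights.
random_es_instance <- function() {
  n <- sample(10:60, 1L)
  d <- sort(stats::rnorm(n), decreasing = TRUE)
  n_hit <- sample.int(n - 1L, 1L)
  hit <- rep(FALSE, n)
  hit[sample.int(n, n_hit)] <- TRUE
  ranked <- structure(list(gene_ids = paste0("g", seq_len(n)), d = d),
                      class = "ranked_gene_list")
  list(ranked = ranked, d = d, hit = hit,
       members = ranked$gene_ids[hit])
}

# O(n^2) double-loop silhouette widths on Euclidean distance.
naive_silhouette <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(features)
  dmat <- as.matrix(dist(features))
  widths <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i])
    if (length(same) == 1L) { widths[i] <- 0; next }
    a <- mean(dmat[i, setdiff(same, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(dmat[i, labels == cl])
    }, numeric(1L)))
    widths[i] <- (b - a) / max(a, b)
  }
  widths
}

# Textbook two-pass Pearson correlation.
two_pass_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

make_ranked <- function(d, ids = paste0("g", seq_along(d))) {
  structure(list(gene_ids = ids, d = d), class = "ranked_gene_list")
}
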