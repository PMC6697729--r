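test_that("fold changes subtract the background over the gene intersection", {
  s <- setNames(c(5, 1), c("g1", "g2"))
  b <- setNames(c(3, 2, 9), c("g1", "g2", "g3"))
  expect_equal(compute_fold_changes(s, b), setNames(c(2, -1), c("g1", "g2")))
  expect_equal(compute_fold_changes(s, s), setNames(c(0, 0), c("g1", "g2")))
  expect_error(compute_fold_changes(s, setNames(1, "gX")), "no genes shared")
  expect_warning(
    compute_fold_changes(setNames(1:3, c("g1", "gX", "gY")), b),
    "only 1 of 3")
})

test_that("gene ranking is descending with stable ties", {
  fc <- setNames(c(1, 3, 2), c("gA", "gB", "gC"))
  expect_identical(rank_genes(fc)$gene_ids, c("gB", "gC", "gA"))
  tied <- setNames(c(2, 2), c("gA", "gB"))
  expect_identical(rank_genes(tied)$gene_ids, c("gA", "gB"))
  sorted <- setNames(c(3, 2, 1), c("g1", "g2", "g3"))
  expect_identical(rank_genes(sorted)$gene_ids, c("g1", "g2", "g3"))
  expect_true(all(diff(rank_genes(fc)$d) <= 0))
})

test_that("enrichment score reproduces the worked examples", {
  r1 <- rank_genes(setNames(c(4, 3, 2, 1), c("gA", "gB", "gC", "gD")))
  expect_identical(enrichment_score(r1, "gA"), 1)    # saturates at the top
  expect_identical(enrichment_score(r1, "gD"), -1)   # bottom-gene set
  r2 <- rank_genes(setNames(c(3, 1, -1, -2), paste0("g", 1:4)))
  expect_equal(enrichment_score(r2, c("g1", "g4")), 0.6, tolerance = 1e-15)
})

test_that("enrichment score signals degenerate inputs", {
  r <- make_ranked(c(3, 2, 1))
  expect_error(enrichment_score(r, c("gX", "gY")),
               class = "empty_overlap_error")
  expect_error(enrichment_score(r, c("g1", "g2", "g3")), "whole ranked list")
  expect_error(enrichment_score(make_ranked(c(0, 0, 1)), c("g1", "g2")),
               class = "degenerate_weights_error")
})

test_that("ES stays in [-1,1] and matches the naive loop on random cases", {
  set.seed(301)
  for (i in 1:300) {
    inst <- random_es_instance()
    es <- enrichment_score(inst$ranked, inst$members)
    expect_gte(es, -1)
    expect_lte(es, 1)
    expect_equal(es, naive_es(inst$d, inst$hit), tolerance = 1e-13)
  }
})

test_that("functional spectrum zero-fills undersized sets, keeps order", {
  fc <- setNames(c(4, 3, 2, 1), c("gA", "gB", "gC", "gD"))
  col <- gene_set_collection(list(top = "gA", absent = c("zX", "zY"),
                                  bottom = "gD"))
  sp <- functional_spectrum(fc, col)
  expect_identical(names(sp), c("top", "absent", "bottom"))
  expect_equal(unname(sp), c(1, 0, -1))
  # min_overlap zero-fills sets with too few measured genes
  sp2 <- functional_spectrum(fc, col, min_overlap = 2L)
  expect_equal(unname(sp2), c(0, 0, 0))
  expect_error(functional_spectrum(numeric(0), col), "empty")
})

test_that("batch spectra: cohort mean background, bounds, equivariance", {
  design <- small_design(seed = 3L)
  cohort <- make_cohort(design)
  sp <- batch_spectra(cohort$expr, cohort$collection)
  expect_identical(dim(sp), c(40L, 12L))
  expect_identical(rownames(sp), colnames(cohort$expr))
  expect_true(all(sp >= -1 & sp <= 1))

  # row-permutation equivariance over samples
  perm <- sample(ncol(cohort$expr))
  sp_perm <- batch_spectra(cohort$expr[, perm], cohort$collection)
  expect_equal(sp_perm, sp[perm, ])

  # gene-row permutation invariance
  gperm <- sample(nrow(cohort$expr))
  expect_equal(batch_spectra(cohort$expr[gperm, ], cohort$collection), sp)

  # reference mode works for a single sample
  ref <- build_reference(cohort$expr)
  one <- batch_spectra(cohort$expr[, 1, drop = FALSE], cohort$collection, ref)
  expect_identical(dim(one), c(1L, 12L))
  expect_error(batch_spectra(cohort$expr[, 1, drop = FALSE],
                             cohort$collection), ">= 2 samples")
})

test_that("identical samples under cohort mean fail naming every sample", {
  expr <- matrix(rep(c(1, 5, 2, 7), 2), ncol = 2,
                 dimnames = list(paste0("g", 1:4), c("sA", "sB")))
  col <- gene_set_collection(list(S = c("g1", "g2")))
  err <- expect_error(batch_spectra(expr, col), "sA, sB")
  expect_match(conditionMessage(err), "degenerate|zero")
})

test_that("reference profile is the per-gene mean", {
  expr <- matrix(c(2, 4, 0, 8), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(build_reference(expr), setNames(c(1, 6), c("g1", "g2")))
  one <- expr[, 1, drop = FALSE]
  expect_equal(build_reference(one), setNames(expr[, 1], rownames(expr)))
  expect_equal(build_reference(expr[, c(2, 1)]), build_reference(expr))
})

test_that("SSP residuals match the closed-form least squares solution", {
  ref <- setNames(c(1, 2, 3, 4), paste0("g", 1:4))
  smp <- setNames(c(1, 2, 3, 8), paste0("g", 1:4))
  d <- ssp_fold_changes(smp, ref, min_overlap = 4L)
  expect_equal(unname(d), c(0.8, -0.4, -1.6, 1.2), tolerance = 1e-12)
  # shifting the sample is absorbed by the intercept
  expect_equal(ssp_fold_changes(smp + 10, ref, min_overlap = 4L), d,
               tolerance = 1e-12)
})

test_that("SSP rejects tiny overlap, constant reference, perfect fits", {
  ref <- setNames(seq_len(20) + 0.5, paste0("g", 1:20))
  smp <- setNames(rnorm(20), paste0("g", 1:20))
  expect_error(ssp_fold_changes(smp[1:5], ref), "overlap")
  expect_error(ssp_fold_changes(smp, setNames(rep(1, 20), names(ref)),
                                min_overlap = 10L), "constant")
  expect_error(ssp_fold_changes(2 * ref + 1, ref),
               class = "degenerate_weights_error")
})

test_that("SSP residuals scale with positive affine sample transforms", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    ids <- paste0("g", seq_len(n))
    ref <- setNames(rnorm(n, 8, 2), ids)
    smp <- setNames(rnorm(n, 8, 2), ids)
    alpha <- runif(1, 0.2, 5)
    beta <- rnorm(1, 0, 4)
    d1 <- ssp_fold_changes(smp, ref)
    d2 <- ssp_fold_changes(alpha * smp + beta, ref)
    expect_equal(d2, alpha * d1, tolerance = 1e-8)
    expect_identical(order(-d2), order(-d1))   # ES ranks unchanged
  }
})

test_that("spectra and reference profiles round-trip through TSV", {
  design <- small_design(seed = 5L)
  cohort <- make_cohort(design)
  sp <- batch_spectra(cohort$expr, cohort$collection)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectra(sp, f)
  expect_equal(read_spectra(f), sp, tolerance = 1e-12)
  ref <- build_reference(cohort$expr)
  g <- withr::local_tempfile(fileext = ".tsv")
  write_reference(ref, g)
  expect_equal(read_reference(g), ref, tolerance = 1e-12)
})
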