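test_that("confusion tallies counts and handles UNCLASSIFIED separately", {
  truth <- setNames(factor(c("A", "A", "B", "B")), paste0("s", 1:4))
  pred <- setNames(c("A", "B", "B", "B"), paste0("s", 1:4))
  cm <- confusion(truth, pred)
  expect_equal(cm$counts["A", "A"], 1L)
  expect_equal(cm$counts["A", "B"], 1L)
  expect_equal(cm$counts["B", "B"], 2L)
  expect_equal(sum(cm$counts), 4L)

  # perfect predictions -> diagonal
  cm2 <- confusion(truth, setNames(as.character(truth), names(truth)))
  expect_equal(unname(diag(cm2$counts)), c(2L, 2L))
  expect_equal(sum(cm2$counts) - sum(diag(cm2$counts)), 0L)

  # one UNCLASSIFIED: separate tally, scored denominator shrinks
  pred3 <- setNames(c("A", "UNCLASSIFIED", "B", "B"), paste0("s", 1:4))
  cm3 <- confusion(truth, pred3)
  expect_equal(sum(cm3$counts), 3L)
  expect_equal(unname(cm3$unclassified["A"]), 1L)
  expect_equal(metrics(cm3)$unclassified_rate, 0.25)

  expect_error(confusion(truth[1:3], pred), "without a truth label")
})

test_that("metrics reproduce the hand-enumerated TP/FN/FP/TN example", {
  truth <- setNames(factor(c("A", "A", "B", "B")), paste0("s", 1:4))
  pred <- setNames(c("A", "B", "B", "B"), paste0("s", 1:4))
  rep <- metrics(confusion(truth, pred))
  pc <- rep$per_class
  expect_equal(pc$sensitivity[pc$class == "A"], 0.5)
  expect_equal(pc$specificity[pc$class == "A"], 1.0)
  expect_equal(pc$sensitivity[pc$class == "B"], 1.0)
  expect_equal(pc$specificity[pc$class == "B"], 0.5)
  expect_equal(rep$mean_balanced_accuracy, 0.75)
  expect_equal(rep$accuracy, 0.75)

  # diagonal matrix -> all metrics 1
  perfect <- metrics(confusion(truth, setNames(as.character(truth),
                                               names(truth))))
  expect_equal(perfect$mean_balanced_accuracy, 1.0)
  expect_equal(perfect$accuracy, 1.0)
})

test_that("confusion identities and permutation invariance hold", {
  set.seed(10)
  classes <- c("A", "B", "C")
  truth <- setNames(factor(sample(classes, 60, TRUE), levels = classes),
                    paste0("s", 1:60))
  pred <- setNames(sample(classes, 60, TRUE), names(truth))
  cm <- confusion(truth, pred)
  rep <- metrics(cm)
  expect_equal(sum(rep$per_class$tp), sum(diag(cm$counts)))
  expect_equal(rep$per_class$tp + rep$per_class$fn,
               unname(rowSums(cm$counts)))
  expect_equal(rep$accuracy, sum(diag(cm$counts)) / sum(cm$counts))

  truth2 <- factor(truth, levels = c("C", "A", "B"))
  rep2 <- metrics(confusion(truth2, pred))
  expect_equal(rep2$mean_balanced_accuracy, rep$mean_balanced_accuracy)
  expect_equal(rep2$accuracy, rep$accuracy)
})

test_that("a class absent from the truth is excluded from macro means", {
  truth <- setNames(factor(c("A", "A", "B"), levels = c("A", "B", "C")),
                    paste0("s", 1:3))
  pred <- setNames(c("A", "C", "B"), names(truth))
  rep <- metrics(confusion(truth, pred))
  expect_true(is.na(rep$per_class$sensitivity[rep$per_class$class == "C"]))
  expect_equal(rep$mean_sensitivity, mean(c(0.5, 1)))
})

test_that("silhouette: separated pairs, null clouds, naive oracle", {
  feats <- matrix(c(0, 0, 10, 10), ncol = 1)
  res <- average_silhouette_width(feats, c(1, 1, 2, 2))
  expect_equal(res$asw, 1)
  expect_true(all(res$widths == 1))
  expect_error(average_silhouette_width(feats, rep(1, 4)), ">= 2 classes")

  # random labels on one isotropic cloud -> ASW near 0
  set.seed(77)
  asws <- replicate(100, {
    x <- matrix(rnorm(200 * 2), 200, 2)
    average_silhouette_width(x, sample(rep(1:2, 100)))$asw
  })
  expect_true(all(abs(asws) < 0.1))

  # oracle equivalence on random labelled instances
  set.seed(78)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(c("a", "b", "c"), n, TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(average_silhouette_width(x, lab)$widths,
                 naive_silhouette(x, lab), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("feature/set correlation matches two-pass Pearson, flags constants", {
  set.seed(12)
  n <- 30
  spectra <- matrix(rnorm(n * 5), n, 5,
                    dimnames = list(paste0("s", 1:n), paste0("set", 1:5)))
  feats <- cbind(DF1 = spectra[, 2],            # identical to set2
                 DF2 = -spectra[, 3],           # negated set3
                 DF3 = rnorm(n))
  rownames(feats) <- rownames(spectra)
  res <- feature_set_correlation(feats, spectra, k = 2)
  expect_equal(res$correlation["DF1", "set2"], 1, tolerance = 1e-12)
  expect_equal(res$correlation["DF2", "set3"], -1, tolerance = 1e-12)
  top2 <- res$top[res$top$feature == "DF2" & res$top$rank == 1, ]
  expect_identical(top2$set_name, "set3")       # |r| ranks the top table
  for (j in 1:5)
    expect_equal(res$correlation["DF3", j],
                 two_pass_pearson(feats[, 3], spectra[, j]),
                 tolerance = 1e-12)

  # constant feature -> r = 0 with flag, not NA
  feats2 <- cbind(feats, DF4 = rep(1, n))
  res2 <- feature_set_correlation(feats2, spectra)
  expect_true(all(res2$correlation["DF4", ] == 0))
  expect_true(all(res2$flagged["DF4", ]))

  expect_error(feature_set_correlation(feats[1:10, ], spectra),
               "same samples")
})

test_that("feature clustering groups by absolute correlation", {
  set.seed(13)
  n <- 60
  base <- matrix(rnorm(n * 3), n, 3)
  # 3 planted blocks of 3 features each (one member negated per block)
  feats <- cbind(base[, 1] + rnorm(n, 0, 0.1), -base[, 1] + rnorm(n, 0, 0.1),
                 base[, 1] + rnorm(n, 0, 0.1),
                 base[, 2] + rnorm(n, 0, 0.1), base[, 2] + rnorm(n, 0, 0.1),
                 -base[, 2] + rnorm(n, 0, 0.1),
                 base[, 3] + rnorm(n, 0, 0.1), -base[, 3] + rnorm(n, 0, 0.1),
                 base[, 3] + rnorm(n, 0, 0.1))
  colnames(feats) <- paste0("DF", 1:9)
  cl <- feature_cluster(feats, groups = 3)
  truth <- rep(1:3, each = 3)
  # same planted block <=> same recovered group
  expect_identical(outer(cl$groups, cl$groups, `==`) ,
                   outer(truth, truth, `==`), ignore_attr = TRUE)

  # duplicated feature and a negation sit at distance 0 -> merged first
  dup <- cbind(a = base[, 1], b = base[, 1], c = -base[, 1], d = base[, 2])
  cl2 <- feature_cluster(dup, groups = 2)
  expect_equal(cl2$groups[["a"]], cl2$groups[["b"]])
  expect_equal(cl2$groups[["a"]], cl2$groups[["c"]])  # |r| ignores sign
  expect_error(feature_cluster(dup[, 1, drop = FALSE]), ">= 2 features")
})

test_that("PCA projection: line capture, translation invariance, eigen oracle", {
  t_param <- seq(-2, 2, length.out = 30)
  line <- cbind(3 * t_param, -1 * t_param) + 5
  p <- pca_project(line, 1)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)

  set.seed(14)
  x <- matrix(rnorm(50 * 4), 50, 4)
  p1 <- pca_project(x, 2)
  p2 <- pca_project(x + 100, 2)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-8)

  # explained variance fractions match covariance eigenvalues
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(p1$explained_variance, (ev / sum(ev))[1:2], tolerance = 1e-12)

  # deterministic sign convention: top loading positive
  expect_true(all(apply(p1$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  expect_error(pca_project(matrix(1, 5, 2)), "zero total variance")
  expect_error(pca_project(x, 10), "exceeds")
})
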