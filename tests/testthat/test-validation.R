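test_that("euclidean distances match hand values and the naive oracle", {
  X <- rbind(c(0, 0), c(3, 4), c(0, 0))
  d <- as.matrix(euclidean_distances(X))
  expect_equal(d[1, 2], 5)
  expect_equal(d[1, 3], 0)
  set.seed(1)
  Y <- matrix(rnorm(15), 5, 3)
  d2 <- as.matrix(euclidean_distances(Y))
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d2[i, j], sqrt(sum((Y[i, ] - Y[j, ])^2)), tolerance = 1e-12)
  }
  expect_error(euclidean_distances(rbind(c(1, NA))), "missing")
})

test_that("UPGMA separates two obvious clusters on a line", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  rownames(x) <- letters[1:4]
  cl <- cluster_genotypes(euclidean_distances(x), linkage = "upgma", k = 2)
  a <- cl$assignments
  expect_equal(a[["a"]], a[["b"]])
  expect_equal(a[["c"]], a[["d"]])
  expect_false(a[["a"]] == a[["c"]])
})

test_that("merge heights equal the naive UPGMA recurrence", {
  set.seed(2)
  X <- matrix(rnorm(12), 6, 2)
  d <- euclidean_distances(X)
  cl <- cluster_genotypes(d, linkage = "upgma", k = 2)
  expect_equal(cl$tree$height, upgma_heights(d), tolerance = 1e-10)
  # heights are monotone under both linkages
  expect_true(all(diff(cl$tree$height) >= -1e-12))
  clw <- cluster_genotypes(d, linkage = "ward", k = 2)
  expect_true(all(diff(clw$tree$height) >= -1e-12))
})

test_that("cluster assignments are invariant to row order", {
  set.seed(3)
  X <- matrix(rnorm(20), 10, 2)
  rownames(X) <- paste0("g", 1:10)
  perm <- sample(10)
  a1 <- cluster_genotypes(euclidean_distances(X), k = 3)$assignments
  a2 <- cluster_genotypes(euclidean_distances(X[perm, ]), k = 3)$assignments
  a2 <- a2[names(a1)]
  # same partition (labels may be renumbered)
  expect_equal(length(unique(paste(a1, a2))), 3)
})

test_that("two points embed at +-d/2 with full variance on one axis", {
  d <- matrix(c(0, 1, 1, 0), 2, 2)
  p <- pcoa(d)
  expect_equal(sort(p$coordinates[, 1]), c(-0.5, 0.5))
  expect_equal(p$explained[1], 100)
})

test_that("PCoA recovers planar configurations up to rigid motion", {
  set.seed(4)
  X <- matrix(rnorm(16), 8, 2)
  p <- pcoa(euclidean_distances(X))
  expect_equal(as.matrix(euclidean_distances(p$coordinates[, 1:2])),
               as.matrix(euclidean_distances(X)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCoA of Euclidean distances equals centered-data PCA", {
  set.seed(5)
  X <- matrix(rnorm(40), 10, 4)
  p <- pcoa(euclidean_distances(X))
  pca_eig <- prcomp(X, center = TRUE, scale. = FALSE)$sdev^2 * (10 - 1)
  expect_equal(p$eigenvalues, pca_eig[seq_along(p$eigenvalues)],
               tolerance = 1e-8)
})

test_that("Mantel self-correlation is 1 and p is bounded below", {
  set.seed(6)
  d <- euclidean_distances(matrix(rnorm(20), 10, 2))
  mt <- mantel_test(d, d, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_gte(mt$p, 1 / 100)
  # affine transforms leave the statistic at 1
  mt2 <- mantel_test(d, 3 * d + 1, n_perm = 99, seed = 1)
  expect_equal(mt2$r, 1, tolerance = 1e-12)
  expect_error(mantel_test(d, euclidean_distances(matrix(0, 10, 2))),
               "constant")
})

test_that("Mantel null rejection rate is near the nominal level", {
  set.seed(7)
  rej <- replicate(600, {
    d1 <- euclidean_distances(matrix(rnorm(20), 10, 2))
    d2 <- euclidean_distances(matrix(rnorm(20), 10, 2))
    mantel_test(d1, d2, n_perm = 99)$p <= 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("identical group means give null canonical structure", {
  set.seed(8)
  X <- matrix(rnorm(40), 20, 2)
  X[11:20, ] <- X[1:10, ]           # second group is an exact copy
  g <- rep(c("a", "b"), each = 10)
  cd <- canonical_discriminant(X, g)
  expect_equal(cd$eigenvalues, 0, tolerance = 1e-10)
  expect_equal(cd$wilks_lambda, 1, tolerance = 1e-10)
})

test_that("one-trait two-group eigenvalue matches the t statistic", {
  set.seed(9)
  x <- matrix(c(rnorm(12, 0), rnorm(10, 1.5)), ncol = 1)
  g <- rep(c("a", "b"), c(12, 10))
  cd <- canonical_discriminant(x, g)
  tt <- t.test(x[g == "a"], x[g == "b"], var.equal = TRUE)$statistic
  expect_equal(cd$eigenvalues * (22 - 2), unname(tt^2), tolerance = 1e-8)
})

test_that("collinear centroids put all separation on one function", {
  set.seed(10)
  centers <- rbind(c(0, 0), c(5, 5), c(10, 10))   # on a line
  X <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(20, 0, 0.4), 10, 2), 2, centers[i, ], `+`)
  }))
  g <- rep(letters[1:3], each = 10)
  cd <- canonical_discriminant(X, g)
  expect_gt(cd$explained[1], 99.5)
})

test_that("Wilks' lambda equals the canonical eigenvalue product identity", {
  set.seed(11)
  X <- matrix(rnorm(90), 30, 3)
  X[11:20, ] <- X[11:20, ] + 1
  g <- rep(letters[1:3], each = 10)
  cd <- canonical_discriminant(X, g)
  sm <- summary(manova(X ~ factor(g)), test = "Wilks")$stats
  expect_equal(cd$wilks_lambda, unname(sm[1, "Wilks"]), tolerance = 1e-8)
})

test_that("homogeneous covariances keep the linear classifier", {
  set.seed(12)
  X <- matrix(rnorm(120), 60, 2)
  g <- rep(c("a", "b", "c"), each = 20)
  dc <- discriminant_classify(X, g)
  expect_gt(dc$box_m$p, 0.05)
  expect_identical(dc$classifier, "lda")
})

test_that("well-separated groups classify with zero resubstitution error", {
  set.seed(13)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12), c(12, 12), c(6, 20))
  X <- do.call(rbind, lapply(1:5, function(i) {
    sweep(matrix(rnorm(16, 0, sd = i / 4), 8, 2), 2, centers[i, ], `+`)
  }))
  g <- rep(paste0("grp", 1:5), each = 8)
  dc <- discriminant_classify(X, g)
  expect_equal(dc$resubstitution_error, 0)
})

test_that("classifier decisions equal the Gaussian log-density oracle", {
  set.seed(14)
  X <- rbind(matrix(rnorm(24, 0, 1), 12, 2),
             sweep(matrix(rnorm(24, 0, 2.5), 12, 2), 2, c(3, 3), `+`))
  g <- rep(c("a", "b"), each = 12)
  dc <- discriminant_classify(X, g, method = "qda")
  means <- lapply(split(as.data.frame(X), g), colMeans)
  covs <- lapply(split(as.data.frame(X), g), cov)
  oracle <- gaussian_argmax(X, means, covs)
  expect_identical(as.character(dc$predicted), oracle)
})

test_that("MANOVA reduces to one-way ANOVA for a single trait", {
  set.seed(15)
  y <- c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 0.5))
  g <- rep(letters[1:3], each = 10)
  mv <- group_manova(matrix(y, dimnames = list(NULL, "y")), g)
  af <- anova(lm(y ~ g))
  expect_equal(mv$wilks$f, af$`F value`[1], tolerance = 1e-10)
  expect_equal(mv$wilks$p, af$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("identical group means give Wilks' lambda of one", {
  X <- matrix(rnorm(60), 30, 2)
  X2 <- rbind(X[1:15, ], X[1:15, ])
  g <- rep(c("a", "b"), each = 15)
  mv <- group_manova(X2, g)
  expect_equal(mv$wilks$lambda, 1, tolerance = 1e-10)
})

test_that("MANOVA null rejection rate stays near nominal", {
  set.seed(16)
  rej <- replicate(200, {
    X <- matrix(rnorm(60), 30, 2)
    g <- rep(letters[1:3], each = 10)
    group_manova(X, g)$wilks$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.04)
})

test_that("least-squares means reproduce the group means", {
  set.seed(17)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("u", "v")))
  g <- rep(c("a", "b"), each = 10)
  mv <- group_manova(X, g)
  expect_equal(mv$ls_means["u", "a"], mean(X[g == "a", "u"]),
               tolerance = 1e-10)
  expect_equal(mv$ls_means["v", "b"], mean(X[g == "b", "v"]),
               tolerance = 1e-10)
})

test_that("group validation runs end-to-end on the published profile", {
  prof <- tolerance_score(reference_membership_long())
  v <- validate_groups(prof, n_perm = 199, seed = 1)
  expect_equal(attr(v$distances, "Size"), 25)
  expect_equal(length(unique(v$clustering$assignments)), 5)
  expect_true(v$mantel$r > 0)
  expect_true(v$mantel$p <= 0.05)
  expect_equal(sum(v$canonical$explained), 100, tolerance = 1e-8)
  expect_lte(length(v$canonical$eigenvalues), 3)  # min(groups-1, traits)
  expect_true(v$manova$wilks$lambda < 0.5)
  expect_identical(levels(v$groups), c("HT", "I", "S", "T"))
  newick <- cluster_newick(v$clustering)
  expect_match(newick, "^\\(.*\\);$")
  expect_true(all(vapply(prof$genotype, grepl, TRUE, x = newick,
                         fixed = TRUE)))
})
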