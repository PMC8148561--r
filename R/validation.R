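#' Genotype score matrix from a membership profile
#'
#' Extracts the numeric score block used by the multivariate validation
#' stages: per default the trait x season membership scores (e.g. 8 columns
#' for four traits in two seasons); alternatively the per-season overall
#' indices.
#'
#' @param profile A [tolerance_score()] profile.
#' @param columns `"trait_season"` (default) or `"season"` (the `Fi_<season>`
#'   columns).
#' @return Numeric matrix with genotype rownames.
#' @export
membership_matrix <- function(profile, columns = c("trait_season", "season")) {
  columns <- match.arg(columns)
  seasons <- attr(profile, "seasons")
  nm <- names(profile)
  cols <- if (columns == "trait_season") {
    setdiff(nm[vapply(profile, is.numeric, TRUE)],
            c(paste0("Fi_", seasons), "Fi_combined"))
  } else {
    paste0("Fi_", seasons)
  }
  m <- as.matrix(profile[cols])
  rownames(m) <- profile$genotype
  m
}

#' Euclidean distance matrix
#'
#' @param x Numeric matrix/data frame (rows are items).
#' @return A [stats::dist] object.
#' @export
euclidean_distances <- function(x) {
  m <- as.matrix(x)
  if (any(!is.finite(m))) stop("missing or non-finite values")
  stats::dist(m, method = "euclidean")
}

#' Agglomerative clustering of genotypes
#'
#' Hierarchical clustering of a distance matrix under Ward's
#' minimum-variance criterion (`"ward"`, via `ward.D2` on Euclidean
#' distances) or the unweighted average linkage (`"upgma"`), cut into `k`
#' groups.
#'
#' @param d A [stats::dist] object or symmetric distance matrix.
#' @param linkage `"ward"` (default) or `"upgma"`.
#' @param k Number of groups to cut; default 5.
#' @return A `genotype_clustering`: list with the `hclust` tree, `linkage`,
#'   `k`, `assignments` (named integer vector) and `cophenetic` distances.
#' @export
cluster_genotypes <- function(d, linkage = c("ward", "upgma"), k = 5) {
  linkage <- match.arg(linkage)
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k < 1 || k > n) stop("k must lie between 1 and the number of items")
  hc <- stats::hclust(d, method = switch(linkage, ward = "ward.D2",
                                         upgma = "average"))
  structure(
    list(tree = hc, linkage = linkage, k = k,
         assignments = stats::cutree(hc, k = k),
         cophenetic = stats::cophenetic(hc)),
    class = "genotype_clustering")
}

#' @export
print.genotype_clustering <- function(x, ...) {
  cat("Hierarchical clustering (", x$linkage, " linkage), k = ", x$k,
      " groups\n", sep = "")
  print(table(x$assignments))
  invisible(x)
}

#' Newick string for a clustering tree
#'
#' @param clustering A [cluster_genotypes()] result.
#' @return Newick-format character string.
#' @export
cluster_newick <- function(clustering) {
  hc <- clustering$tree
  lab <- hc$labels
  build <- function(i) {
    if (i < 0) return(lab[-i])
    paste0("(", build(hc$merge[i, 1]), ",", build(hc$merge[i, 2]), "):",
           format(hc$height[i], digits = 6))
  }
  n <- length(lab)
  paste0("(", build(hc$merge[n - 1, 1]), ",", build(hc$merge[n - 1, 2]), ");")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers `-D^2/2`, eigendecomposes, and returns coordinates scaled
#' by the square root of the positive eigenvalues. For Euclidean input the
#' eigenvalues equal those of a centered-data PCA of the original matrix.
#'
#' @param d Distance matrix ([stats::dist] or symmetric matrix).
#' @return List with `coordinates`, `eigenvalues` (positive ones) and
#'   `explained` (percent of the positive-eigenvalue total).
#' @export
pcoa <- function(d) {
  d <- stats::as.dist(d)
  if (all(d == 0)) stop("all distances are zero")
  n <- attr(d, "Size")
  sc <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  pos <- sc$eig[sc$eig > 1e-9]
  k <- length(pos)
  list(coordinates = sc$points[, seq_len(k), drop = FALSE],
       eigenvalues = pos,
       explained = 100 * pos / sum(pos))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the corresponding off-diagonal entries, with the
#' permutation p-value `(count of permuted r >= observed + 1)/(n_perm + 1)`.
#' The permutations are delegated to [vegan::mantel()].
#'
#' @param d1,d2 Distance matrices over the same items.
#' @param n_perm Number of permutations; default 9999.
#' @param seed Optional RNG seed for reproducible permutations.
#' @return List with `r`, `p` and `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = NULL) {
  d1 <- stats::as.dist(d1); d2 <- stats::as.dist(d2)
  if (attr(d1, "Size") != attr(d2, "Size")) stop("sizes differ")
  if (attr(d1, "Size") < 4) stop("need at least 4 items")
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2)) {
    stop("item labels differ between the two matrices")
  }
  if (stats::sd(d1) == 0 || stats::sd(d2) == 0) {
    stop("constant off-diagonal distances; correlation undefined")
  }
  if (!is.null(seed)) set.seed(seed)
  mt <- vegan::mantel(d1, d2, permutations = n_perm)
  list(r = unname(mt$statistic), p = unname(mt$signif), n_perm = n_perm)
}

.sscp <- function(x, groups) {
  x <- as.matrix(x)
  groups <- factor(groups)
  grand <- colMeans(x)
  W <- matrix(0, ncol(x), ncol(x))
  B <- matrix(0, ncol(x), ncol(x))
  for (g in levels(groups)) {
    xi <- x[groups == g, , drop = FALSE]
    mi <- colMeans(xi)
    W <- W + crossprod(sweep(xi, 2, mi))
    B <- B + nrow(xi) * tcrossprod(mi - grand)
  }
  dimnames(W) <- dimnames(B) <- list(colnames(x), colnames(x))
  list(W = W, B = B, groups = groups)
}

#' Canonical discriminant analysis
#'
#' Eigen-analysis of `W^-1 B` (within- and between-group SSCP matrices):
#' canonical eigenvalues, percent of between-group variation explained per
#' function, raw coefficients scaled so the pooled within-group variance of
#' each canonical variate is 1, structure loadings (pooled within-group
#' correlations of traits with the variates) and group centroids on the
#' canonical axes.
#'
#' @param x Numeric matrix/data frame of scores (rows are items).
#' @param groups Group labels, one per row; at least 2 groups of >= 2 items.
#' @param regularize Ridge fraction added to the diagonal of `W` when it is
#'   numerically singular; `NULL` (default) errors instead.
#' @return A `discriminant_model`-style list: `eigenvalues`, `explained`,
#'   `coefficients`, `loadings`, `centroids`, `scores`, `wilks_lambda`.
#' @export
canonical_discriminant <- function(x, groups, regularize = NULL) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  sc <- .sscp(x, groups)
  W <- sc$W; B <- sc$B
  if (rcond(W) < 1e-12) {
    if (is.null(regularize)) stop("within-group SSCP is singular")
    W <- W + diag(regularize * mean(diag(W)), ncol(W))
  }
  m <- min(nlevels(groups) - 1, ncol(x))
  ev <- eigen(solve(W, B))
  ord <- order(Re(ev$values), decreasing = TRUE)[seq_len(m)]
  lambda <- pmax(Re(ev$values[ord]), 0)
  V <- Re(ev$vectors[, ord, drop = FALSE])
  n <- nrow(x); g <- nlevels(groups)
  Sw <- W / (n - g)
  # scale: unit pooled within-group variance on each canonical variate
  V <- sweep(V, 2, sqrt(diag(t(V) %*% Sw %*% V)), "/")
  dimnames(V) <- list(colnames(x), paste0("Can", seq_len(m)))
  scores <- scale(x, center = TRUE, scale = FALSE) %*% V
  centroids <- apply(scores, 2, tapply, groups, mean)
  sdw <- sqrt(diag(Sw))
  loadings <- stats::cov2cor(Sw) %*% (V * sdw)  # within-group structure
  expl <- if (sum(lambda) > 0) 100 * lambda / sum(lambda) else lambda
  list(eigenvalues = lambda, explained = expl,
       coefficients = V, loadings = loadings,
       centroids = centroids, scores = scores,
       wilks_lambda = prod(1 / (1 + lambda)))
}

#' Box's M test of covariance homogeneity
#'
#' Chi-squared approximation to Box's M for equality of the group covariance
#' matrices; a significant result motivates quadratic (per-group covariance)
#' discriminant classification.
#'
#' @param x Numeric matrix/data frame.
#' @param groups Group labels; every group needs more members than traits
#'   for a nonsingular covariance estimate.
#' @return List with `statistic` (M), `chi_sq`, `df` and `p`.
#' @export
box_m <- function(x, groups) {
  x <- as.matrix(x)
  groups <- factor(groups)
  p <- ncol(x); g <- nlevels(groups)
  ni <- as.vector(table(groups))
  if (any(ni <= p)) {
    stop("each group needs more members than traits for Box's M")
  }
  n <- nrow(x)
  covs <- lapply(levels(groups),
                 function(l) stats::cov(x[groups == l, , drop = FALSE]))
  Sp <- Reduce(`+`, Map(function(S, m) (m - 1) * S, covs, ni)) / (n - g)
  logdets <- vapply(covs, function(S) determinant(S)$modulus, 0)
  M <- (n - g) * determinant(Sp)$modulus - sum((ni - 1) * logdets)
  c1 <- (sum(1 / (ni - 1)) - 1 / (n - g)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1))
  chi <- as.numeric(M * (1 - c1))
  df <- p * (p + 1) * (g - 1) / 2
  list(statistic = as.numeric(M), chi_sq = chi, df = df,
       p = stats::pchisq(chi, df, lower.tail = FALSE))
}

#' Discriminant classification with covariance-homogeneity gating
#'
#' Runs [box_m()]; when the covariances are heterogeneous (p < `alpha`) and
#' every group is large enough, classifies with quadratic discriminant
#' analysis (per-group covariances, [MASS::qda()]); otherwise with linear
#' discriminant analysis on the pooled covariance ([MASS::lda()]). Priors
#' are equal across groups. Reports the resubstitution error rate.
#'
#' @param x Numeric matrix/data frame of scores.
#' @param groups Group labels.
#' @param alpha Significance level of the Box's M gate; default 0.05.
#' @param method `"auto"` (default), or force `"lda"`/`"qda"`.
#' @return List with `classifier` (`"lda"` or `"qda"`), `box_m`, `fit`,
#'   `predicted`, `resubstitution_error` (percent) and `pooled_fallback`
#'   (TRUE when QDA was indicated but group sizes forced LDA).
#' @export
discriminant_classify <- function(x, groups, alpha = 0.05,
                                  method = c("auto", "lda", "qda")) {
  method <- match.arg(method)
  x <- as.data.frame(x)
  groups <- factor(groups)
  g <- nlevels(groups)
  p <- ncol(x)
  ni <- table(groups)
  bm <- tryCatch(box_m(x, groups), error = function(e) NULL)
  fallback <- FALSE
  use <- method
  if (method == "auto") {
    want_qda <- !is.null(bm) && bm$p < alpha
    if (want_qda && all(ni > p)) {
      use <- "qda"
    } else {
      use <- "lda"
      fallback <- want_qda
    }
  }
  prior <- rep(1 / g, g)
  fit <- if (use == "qda") {
    MASS::qda(x, grouping = groups, prior = prior)
  } else {
    MASS::lda(x, grouping = groups, prior = prior)
  }
  pred <- stats::predict(fit, x)$class
  list(classifier = use, box_m = bm, fit = fit, predicted = pred,
       resubstitution_error = 100 * mean(pred != groups),
       pooled_fallback = fallback)
}

#' MANOVA across tolerance groups with least-squares means
#'
#' Wilks' lambda MANOVA of the score matrix over the group factor (Rao's F
#' approximation via [stats::manova()]), plus per-trait least-squares group
#' means and unadjusted pairwise contrasts at `alpha` from
#' [emmeans::emmeans()].
#'
#' @param x Numeric matrix/data frame of scores.
#' @param groups Group labels.
#' @param alpha Significance level for the pairwise flags; default 0.05.
#' @return List with `wilks` (lambda, F, dfs, p), `ls_means` (trait x group
#'   matrix) and `pairwise` (long data frame of contrasts with `significant`
#'   flag).
#' @export
group_manova <- function(x, groups, alpha = 0.05) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  groups <- factor(groups)
  if (nrow(x) - nlevels(groups) < ncol(x)) {
    stop("residual degrees of freedom smaller than the number of traits")
  }
  if (ncol(x) == 1) {
    # single response: Wilks' lambda collapses to the one-way ANOVA ratio
    af <- stats::anova(stats::lm(x[, 1] ~ groups))
    ssb <- af$`Sum Sq`[1]; ssw <- af$`Sum Sq`[2]
    wilks <- list(lambda = ssw / (ssb + ssw),
                  f = af$`F value`[1],
                  df1 = af$Df[1], df2 = af$Df[2],
                  p = af$`Pr(>F)`[1])
  } else {
    fit <- stats::manova(x ~ groups)
    sm <- summary(fit, test = "Wilks")$stats
    wilks <- list(lambda = sm["groups", "Wilks"],
                  f = sm["groups", "approx F"],
                  df1 = sm["groups", "num Df"],
                  df2 = sm["groups", "den Df"],
                  p = sm["groups", "Pr(>F)"])
  }
  ls <- NULL
  pw <- NULL
  for (j in seq_len(ncol(x))) {
    d <- data.frame(y = x[, j], group = groups)
    lmfit <- stats::lm(y ~ group, data = d)
    em <- emmeans::emmeans(lmfit, "group")
    ls <- cbind(ls, summary(em)$emmean)
    pr <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
    pw <- rbind(pw, data.frame(trait = colnames(x)[j],
                               contrast = pr$contrast,
                               estimate = pr$estimate,
                               p = pr$p.value,
                               significant = pr$p.value < alpha,
                               stringsAsFactors = FALSE))
  }
  dimnames(ls) <- list(levels(groups), colnames(x))
  list(wilks = wilks, ls_means = t(ls), pairwise = pw)
}

#' End-to-end validation of tolerance groupings
#'
#' Convenience wrapper: clusters the membership score matrix, embeds it by
#' principal coordinates, Mantel-tests the score distances against the
#' cophenetic distances of the dendrogram, then runs canonical discriminant
#' analysis, Box's M-gated classification and MANOVA using the tolerance
#' classes as groups.
#'
#' @param profile A [tolerance_score()] profile.
#' @param columns Score columns to use, see [membership_matrix()].
#' @param linkage,k Passed to [cluster_genotypes()].
#' @param n_perm,seed Passed to [mantel_test()].
#' @return List with `scores`, `distances`, `clustering`, `pcoa`, `mantel`,
#'   `canonical`, `classification`, `manova`, `groups`, and
#'   `singletons_dropped` (genotypes in singleton classes, set aside from the
#'   group-based stages).
#' @export
validate_groups <- function(profile, columns = "trait_season",
                            linkage = "ward", k = 5, n_perm = 999,
                            seed = NULL) {
  m <- membership_matrix(profile, columns = columns)
  grp <- droplevels(factor(profile$class_combined))
  d <- euclidean_distances(m)
  cl <- cluster_genotypes(d, linkage = linkage, k = min(k, nrow(m)))
  # group-based stages need >= 2 members per class; singletons are set aside
  ok_classes <- names(which(table(grp) >= 2))
  sub <- grp %in% ok_classes
  grp2 <- droplevels(grp[sub])
  m2 <- m[sub, , drop = FALSE]
  dropped <- profile$genotype[!sub]
  list(scores = m,
       distances = d,
       clustering = cl,
       pcoa = pcoa(d),
       mantel = mantel_test(d, cl$cophenetic, n_perm = n_perm, seed = seed),
       canonical = tryCatch(canonical_discriminant(m2, grp2),
                            error = function(e) {
         warning("canonical discriminant skipped: ", conditionMessage(e))
         NULL
       }),
       classification = tryCatch(discriminant_classify(m2, grp2),
                                 error = function(e) {
         warning("classification skipped: ", conditionMessage(e))
         NULL
       }),
       manova = tryCatch(group_manova(m2, grp2), error = function(e) {
         warning("MANOVA skipped: ", conditionMessage(e)); NULL
       }),
       groups = grp,
       singletons_dropped = dropped)
}
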