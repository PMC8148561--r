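test_that("orthogonal standardized traits have unit tolerance and VIF", {
  X <- exact_correlation_data(40, diag(3), seed = 2)
  colnames(X) <- c("a", "b", "c")
  rep_ <- collinearity(X)
  expect_equal(rep_$tolerance, rep(1, 3), tolerance = 1e-10)
  expect_equal(rep_$vif, rep(1, 3), tolerance = 1e-10)
})

test_that("a duplicated trait is flagged perfectly collinear", {
  set.seed(3)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  X$a2 <- X$a
  rep_ <- collinearity(X)
  expect_true(is.infinite(rep_$vif[rep_$trait == "a"]))
  expect_true(is.infinite(rep_$vif[rep_$trait == "a2"]))
  expect_equal(rep_$tolerance[rep_$trait == "a"], 0, tolerance = 1e-10)
})

test_that("VIF equals the diagonal of the inverse correlation matrix", {
  R <- matrix(c(1, 0.5, 0.3,
                0.5, 1, -0.2,
                0.3, -0.2, 1), 3, 3,
              dimnames = list(NULL, c("x", "y", "z")))
  X <- exact_correlation_data(30, R, seed = 7)
  rep_ <- collinearity(X)
  expect_equal(rep_$vif, diag(solve(R)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("constant trait columns are rejected by name", {
  X <- data.frame(a = rnorm(10), b = rnorm(10), c = 1)
  expect_error(collinearity(X), "c")
})

test_that("iterative exclusion removes one of a near-linear triple", {
  set.seed(11)
  n <- 60
  DH <- rnorm(n, 75, 3)
  DM <- rnorm(n, 120, 3)
  GFD <- DM - DH + rnorm(n, 0, 0.3)   # near-exact linear dependency
  X <- data.frame(DH = DH, DM = DM, GFD = GFD,
                  GY = rnorm(n, 5, 1), RWC = rnorm(n, 80, 4))
  before <- collinearity(X)
  expect_true(sum(before$vif > 10) >= 3)
  after <- drop_collinear(X, vif_threshold = 10)
  expect_length(attr(after, "excluded"), 1)
  expect_true(attr(after, "excluded") %in% c("DH", "DM", "GFD"))
  expect_true(all(after$vif < 10))
})

test_that("no exclusion happens when all VIF are under threshold", {
  X <- exact_correlation_data(40, diag(4), seed = 5)
  colnames(X) <- letters[1:4]
  rep_ <- drop_collinear(X)
  expect_identical(attr(rep_, "excluded"), character(0))
  expect_setequal(rep_$trait, letters[1:4])
})

test_that("exclusion ties break alphabetically", {
  set.seed(9)
  base <- data.frame(b = rnorm(25), a = rnorm(25), z = rnorm(25))
  X <- data.frame(base, b2 = base$b, a2 = base$a)
  rep_ <- drop_collinear(X, vif_threshold = 10)
  exc <- attr(rep_, "excluded")
  # duplicates give infinite VIF ties; 'a' sorts before 'a2', 'b', 'b2'
  expect_identical(exc[1], "a")
  expect_true(all(rep_$vif < 10))
})

test_that("exclusion threshold must exceed 1", {
  X <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  expect_error(drop_collinear(X, vif_threshold = 1), "exceed 1")
})

test_that("rank-1 PCA has eigenvalues {2, 0} and full first-axis share", {
  x <- rnorm(30)
  X <- cbind(a = x, b = 2 * x + 5)   # perfectly correlated pair
  p <- trait_pca(X)
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-10)
  expect_equal(p$explained[1], 100, tolerance = 1e-10)
  expect_equal(abs(unname(p$loadings[, 1])), rep(1 / sqrt(2), 2),
               tolerance = 1e-10)
})

test_that("independent traits give near-unit eigenvalues", {
  X <- exact_correlation_data(200, diag(5), seed = 21)
  p <- trait_pca(X)
  expect_equal(p$eigenvalues, rep(1, 5), tolerance = 1e-8)
  expect_equal(p$explained, rep(20, 5), tolerance = 1e-8)
})

test_that("PCA eigenvalues match the characteristic-polynomial roots", {
  R <- matrix(c(1, 0.4, 0.2,
                0.4, 1, 0.6,
                0.2, 0.6, 1), 3, 3)
  X <- exact_correlation_data(50, R, seed = 31)
  p <- trait_pca(X)
  # roots of det(R - lambda I) found independently via polyroot
  cfs <- c(-det(R),
           (R[1, 1] * R[2, 2] - R[1, 2]^2) +
             (R[1, 1] * R[3, 3] - R[1, 3]^2) +
             (R[2, 2] * R[3, 3] - R[2, 3]^2),
           -(R[1, 1] + R[2, 2] + R[3, 3]),
           1)
  roots <- sort(Re(polyroot(cfs)), decreasing = TRUE)
  expect_equal(p$eigenvalues, roots, tolerance = 1e-8)
  expect_equal(sum(p$eigenvalues), 3, tolerance = 1e-10)
})

test_that("eigenvalue sum conservation holds on simulated panels", {
  obs <- simulate_trial(trial_design(
    traits = default_trait_panel(c("GY", "RWC", "CT", "GLA", "LAI"))),
    seed = 4)$observations
  cells <- trait_means(obs, by = c("genotype", "season", "regime"))
  p <- trait_pca(cells)
  expect_equal(sum(p$eigenvalues), 5, tolerance = 1e-10)
  expect_equal(sum(p$explained), 100, tolerance = 1e-10)
})

test_that("loadings are column-order invariant up to sign", {
  # distinct eigenvalues so eigenvectors are identified up to sign
  R <- stats::toeplitz(c(1, 0.6, 0.3, 0.1))
  X <- exact_correlation_data(40, R, seed = 41)
  colnames(X) <- c("w", "x", "y", "z")
  p1 <- trait_pca(X)
  p2 <- trait_pca(X[, c(3, 1, 4, 2)])
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-10)
  L2 <- p2$loadings[colnames(X), ]
  agree <- abs(colSums(p1$loadings * L2) /
                 sqrt(colSums(p1$loadings^2) * colSums(L2^2)))
  expect_equal(unname(agree), rep(1, 4), tolerance = 1e-8)
})

test_that("trait selection respects the loading threshold", {
  x <- rnorm(30)
  X <- cbind(a = x, b = 2 * x + 5)
  p <- trait_pca(X)
  expect_setequal(select_traits(p, loading_threshold = 0, components = 1),
                  c("a", "b"))
  expect_length(select_traits(p, loading_threshold = 0.99, components = 1),
                0)
  # rank-1 loadings are +-1/sqrt(2) ~ 0.707 > 0.27
  expect_setequal(select_traits(p, loading_threshold = 0.27,
                                components = 1), c("a", "b"))
  expect_error(select_traits(p, components = 5), "exceeds")
})

test_that("published tolerance/VIF pairs are reciprocal within rounding", {
  ref <- reference_collinearity()
  for (phase in c("before", "after")) {
    tol <- ref[[paste0("tolerance_", phase)]]
    vif <- ref[[paste0("vif_", phase)]]
    ok <- !is.na(vif) & vif > 0
    expect_true(all(abs(1 / vif[ok] - tol[ok]) <= 0.005))
  }
})
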