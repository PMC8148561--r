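# Independent oracles and small fixture builders shared across the suite.

# Build a balanced long plot table from a value-generating function
# f(genotype, season, regime, rep) -> numeric.
make_obs <- function(f, genotypes = c("A", "B"), seasons = c("S1", "S2"),
                     regimes = c("full", "limited"), reps = 1:2,
                     trait = "X") {
  grid <- expand.grid(genotype = genotypes, season = seasons,
                      regime = regimes, rep = reps,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$trait <- trait
  grid$value <- mapply(f, grid$genotype, grid$season, grid$regime, grid$rep)
  grid
}

# Brute-force split-plot sums of squares from explicit cell means: an
# enumeration oracle independent of the aov-based implementation.
brute_force_ss <- function(obs) {
  y <- obs$value
  n <- length(y)
  grand <- mean(y)
  cm <- function(...) {
    # mean of y within each combination of the given factors, mapped back
    # to observations
    key <- interaction(..., drop = TRUE)
    ave(y, key)
  }
  S <- cm(obs$season); I <- cm(obs$regime); G <- cm(obs$genotype)
  SR <- cm(obs$season, obs$rep)
  SI <- cm(obs$season, obs$regime)
  SIR <- cm(obs$season, obs$regime, obs$rep)
  SG <- cm(obs$season, obs$genotype)
  IG <- cm(obs$regime, obs$genotype)
  SIG <- cm(obs$season, obs$regime, obs$genotype)
  ss <- function(v) sum(v^2)
  out <- c(
    S = ss(S - grand),
    `rep(S)` = ss(SR - S),
    I = ss(I - grand),
    SxI = ss(SI - S - I + grand),
    `rep(IxS)` = ss(SIR - SI - SR + S),
    G = ss(G - grand),
    SxG = ss(SG - S - G + grand),
    IxG = ss(IG - I - G + grand),
    SxIxG = ss(SIG - SI - SG - IG + S + I + G - grand))
  out <- c(out, Error = sum((y - grand)^2) - sum(out))
  out
}

# Naive UPGMA agglomeration (merge-height oracle).
upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1)) {
        h <- mean(d[active[[i]], active[[j]]])
        if (h < bh) { bh <- h; best <- c(j, i) }
      }
    }
    heights <- c(heights, bh)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- c(active[-best], list(merged))
  }
  heights
}

# Construct a data matrix whose sample correlation matrix is exactly R:
# centered iid normals span a space orthogonal to the constant vector, so
# their QR orthonormal basis has exactly mean-zero uncorrelated columns;
# multiplying by chol(R) imposes R as the exact sample correlation.
exact_correlation_data <- function(n, R, seed = 1) {
  set.seed(seed)
  p <- ncol(R)
  Z <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  Q <- qr.Q(qr(Z))
  X <- Q %*% chol(R)
  colnames(X) <- colnames(R)
  X
}

# Gaussian per-group log-density classifier (QDA oracle, equal priors).
gaussian_argmax <- function(x, means, covs) {
  labs <- names(means)
  scores <- vapply(labs, function(l) {
    mvn_logdens(x, means[[l]], covs[[l]])
  }, numeric(nrow(x)))
  labs[apply(scores, 1, which.max)]
}

mvn_logdens <- function(x, mu, S) {
  ic <- solve(S)
  ld <- determinant(S)$modulus
  d <- sweep(as.matrix(x), 2, mu)
  -0.5 * (rowSums((d %*% ic) * d) + as.numeric(ld))
}
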