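#' Aggregate a long plot table to a wide trait matrix
#'
#' Averages plot values over replicates (and optionally other factors) and
#' reshapes to one row per aggregation cell, one column per trait. With the
#' default `by = c("genotype")` rows are genotype means; with
#' `by = c("genotype", "season", "regime")` rows are the treatment-cell means
#' used for principal component analysis and yield modelling.
#'
#' @param observations Long plot table.
#' @param by Grouping columns defining the rows of the wide matrix.
#' @param traits Optional subset of traits.
#' @return Data frame with the `by` columns followed by one numeric column
#'   per trait.
#' @export
trait_means <- function(observations, by = "genotype", traits = NULL) {
  if (!is.null(traits)) {
    observations <- observations[observations$trait %in% traits, , drop = FALSE]
  }
  agg <- stats::aggregate(observations["value"],
                          by = c(observations[by],
                                 list(trait = observations$trait)),
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = by, timevar = "trait",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

.numeric_trait_matrix <- function(x) {
  if (is.matrix(x)) {
    if (!is.numeric(x)) stop("no numeric trait columns found")
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
    return(x)
  }
  num <- vapply(x, is.numeric, TRUE)
  m <- as.matrix(x[num])
  if (!ncol(m)) stop("no numeric trait columns found")
  m
}

#' Multicollinearity diagnosis (tolerance and VIF)
#'
#' For each trait `j`, regresses it on all other traits and reports
#' tolerance `1 - R2_j` and variance inflation factor `VIF = 1/tolerance`.
#' A trait that is an exact linear combination of the others has tolerance 0
#' and its VIF is flagged infinite. When there are no more rows than traits
#' the regressions are rank-deficient; the result is computed on the
#' least-squares fit and flagged (`exact = FALSE`).
#'
#' @param x Wide matrix/data frame of trait values (rows are genotype or cell
#'   means, columns traits), e.g. from [trait_means()].
#' @return A `collinearity_report`: data frame with columns `trait`,
#'   `tolerance`, `vif`; attribute `excluded` (empty here, see
#'   [drop_collinear()]).
#' @export
collinearity <- function(x) {
  m <- .numeric_trait_matrix(x)
  if (ncol(m) < 3) stop("need at least 3 traits")
  if (any(!is.finite(m))) stop("non-finite trait values")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait column: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  z <- scale(m)
  tol <- vapply(seq_len(ncol(z)), function(j) {
    fit <- stats::lm.fit(cbind(1, z[, -j, drop = FALSE]), z[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum(z[, j]^2)
    max(rss / tss, 0)
  }, 0)
  vif <- ifelse(tol < 1e-12, Inf, 1 / tol)
  out <- data.frame(trait = colnames(m), tolerance = tol, vif = vif,
                    stringsAsFactors = FALSE)
  structure(out, class = c("collinearity_report", "data.frame"),
            excluded = character(0), exact = nrow(m) > ncol(m))
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("Multicollinearity diagnosis\n")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  exc <- attr(x, "excluded")
  if (length(exc)) cat("excluded (in order):", paste(exc, collapse = ", "), "\n")
  invisible(x)
}

#' Iterative exclusion of collinear traits
#'
#' Repeatedly removes the single trait with the largest VIF while the maximum
#' VIF exceeds `vif_threshold`, recomputing the diagnosis after each removal.
#' Ties on the maximum VIF are broken alphabetically.
#'
#' @param x Wide trait matrix/data frame.
#' @param vif_threshold Exclusion threshold; must exceed 1. Default 10.
#' @return A `collinearity_report` for the retained traits, with attribute
#'   `excluded` giving the removal order.
#' @export
drop_collinear <- function(x, vif_threshold = 10) {
  if (vif_threshold <= 1) stop("vif_threshold must exceed 1")
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, TRUE)
  keep <- names(x)[num]
  excluded <- character(0)
  repeat {
    rep_ <- collinearity(x[keep])
    worst <- max(rep_$vif)
    if (worst <= vif_threshold) break
    cand <- sort(rep_$trait[rep_$vif == worst])
    drop <- cand[1]
    excluded <- c(excluded, drop)
    keep <- setdiff(keep, drop)
    if (length(keep) < 3) break
  }
  attr(rep_, "excluded") <- excluded
  rep_
}

#' Principal component analysis of the trait correlation matrix
#'
#' Eigendecomposition of the Pearson correlation matrix of the trait columns.
#' Components are ordered by decreasing eigenvalue; each component's sign is
#' fixed so that its largest-magnitude loading is positive; the number of
#' retained components follows the Kaiser rule (eigenvalue > 1). Eigenvalues
#' sum to the number of traits and the explained percentages to 100.
#'
#' @param x Wide trait matrix/data frame (rows are genotype or treatment-cell
#'   means).
#' @return A `pca_result`: list with `eigenvalues`, `explained` (percent),
#'   `loadings` (trait x component), `scores` (row x component, from
#'   standardized data), `retained`.
#' @export
trait_pca <- function(x) {
  m <- .numeric_trait_matrix(x)
  if (ncol(m) < 2) stop("need at least 2 traits")
  if (any(!is.finite(m))) stop("non-finite trait values")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait column: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  R <- stats::cor(m)
  ev <- eigen(R, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  vec <- ev$vectors
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  dimnames(vec) <- list(colnames(m), paste0("PC", seq_len(ncol(vec))))
  structure(
    list(eigenvalues = vals,
         explained = 100 * vals / sum(vals),
         loadings = vec,
         scores = scale(m) %*% vec,
         retained = sum(vals > 1)),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(6, length(x$eigenvalues))
  cat("Correlation-matrix PCA: ", length(x$eigenvalues), " traits, ",
      x$retained, " components with eigenvalue > 1\n", sep = "")
  print(round(rbind(eigenvalue = x$eigenvalues[1:k],
                    `explained %` = x$explained[1:k],
                    `cumulative %` = cumsum(x$explained)[1:k]), 3))
  invisible(x)
}

#' Select traits loading on the leading components
#'
#' Returns the traits whose absolute loading exceeds `loading_threshold` on
#' any of the first `components` axes. Absolute values are used because
#' traits loading negatively (e.g. canopy temperature against yield) are as
#' informative as positive loaders.
#'
#' @param pca A [trait_pca()] result.
#' @param loading_threshold Absolute loading cutoff; default 0.27.
#' @param components Number of leading components searched; default 2.
#' @return Character vector of selected trait names.
#' @export
select_traits <- function(pca, loading_threshold = 0.27, components = 2) {
  stopifnot(inherits(pca, "pca_result"))
  if (components > ncol(pca$loadings)) {
    stop("components exceeds the number of available axes")
  }
  if (components > pca$retained) {
    warning("components exceeds the number of retained (eigenvalue > 1) axes")
  }
  L <- abs(pca$loadings[, seq_len(components), drop = FALSE])
  rownames(pca$loadings)[apply(L > loading_threshold, 1, any)]
}
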