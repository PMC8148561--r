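#' Forward stepwise regression of yield on screened traits
#'
#' Classical p-value-driven stepwise multiple linear regression: at each step
#' the candidate whose partial-F p-value is smallest enters if it is below
#' `alpha_enter`; after every entry, any entered trait whose p-value in the
#' current model exceeds `alpha_remove` is removed (largest first). The
#' procedure stops when no entry or removal changes the model. Partial R2 is
#' reported as the sequential R2 increment in entry order.
#'
#' @param x Data frame/matrix of candidate trait columns (rows are
#'   genotype x season x regime cell means).
#' @param y Yield vector, same length as `nrow(x)`.
#' @param alpha_enter Entry significance level, default 0.05.
#' @param alpha_remove Removal significance level, default 0.10. A value
#'   below `alpha_enter` triggers a warning (cycling risk).
#' @return A `stepwise_result`: list with `entered` (order of entry),
#'   `coefficients`, `intercept`, `p_values` (final model), `partial_r2`,
#'   `cumulative_r2`, `r2`, and the final `model` ([stats::lm] fit).
#' @export
stepwise_yield <- function(x, y, alpha_enter = 0.05, alpha_remove = 0.10) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, TRUE)
  x <- x[num]
  if (!all(is.finite(y))) stop("yield values must be finite")
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (nrow(x) <= ncol(x) + 1) {
    stop("need more rows than candidate traits + 1")
  }
  if (alpha_enter > alpha_remove) {
    warning("alpha_enter exceeds alpha_remove; selection may cycle")
  }
  dat <- data.frame(.y = y, x, check.names = FALSE)
  entered <- character(0)
  coef_p <- function(vars) {
    f <- stats::reformulate(vars, response = ".y")
    fit <- stats::lm(f, data = dat)
    if (anyNA(stats::coef(fit))) {
      stop("perfect collinearity among entered traits: ",
           paste(vars, collapse = ", "))
    }
    fit
  }
  repeat {
    changed <- FALSE
    cand <- setdiff(names(x), entered)
    if (length(cand)) {
      pv <- vapply(cand, function(v) {
        fit <- stats::lm(stats::reformulate(c(entered, v), response = ".y"),
                         data = dat)
        cf <- summary(fit)$coefficients
        if (!(v %in% rownames(cf))) return(1)  # aliased candidate
        pv <- cf[v, "Pr(>|t|)"]
        if (is.nan(pv)) 0 else pv  # zero-residual fit: perfect explanation
      }, 0)
      if (min(pv) < alpha_enter) {
        entered <- c(entered, cand[which.min(pv)])
        changed <- TRUE
      }
    }
    while (length(entered)) {
      fit <- coef_p(entered)
      cf <- summary(fit)$coefficients
      pv <- cf[entered, "Pr(>|t|)"]
      pv[is.nan(pv)] <- 0
      if (max(pv) > alpha_remove) {
        entered <- setdiff(entered, entered[which.max(pv)])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (!length(entered)) {
    stop("no trait met the entry criterion at alpha_enter = ", alpha_enter)
  }
  fit <- coef_p(entered)
  sm <- summary(fit)
  # sequential R2 in entry order
  cum <- vapply(seq_along(entered), function(k) {
    summary(coef_p(entered[seq_len(k)]))$r.squared
  }, 0)
  structure(
    list(entered = entered,
         coefficients = stats::coef(fit)[entered],
         intercept = unname(stats::coef(fit)[1]),
         p_values = stats::setNames(sm$coefficients[entered, "Pr(>|t|)"],
                                    entered),
         partial_r2 = stats::setNames(diff(c(0, cum)), entered),
         cumulative_r2 = stats::setNames(cum, entered),
         r2 = sm$r.squared,
         alpha_enter = alpha_enter, alpha_remove = alpha_remove,
         model = fit),
    class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("Stepwise regression (alpha_enter = ", x$alpha_enter,
      ", alpha_remove = ", x$alpha_remove, ")\n", sep = "")
  tab <- data.frame(trait = x$entered,
                    coefficient = unname(x$coefficients),
                    partial_r2 = unname(x$partial_r2),
                    cumulative_r2 = unname(x$cumulative_r2))
  print.data.frame(format(tab, digits = 4), row.names = FALSE)
  cat(sprintf("Model R2 = %.3f (intercept %.4g)\n", x$r2, x$intercept))
  invisible(x)
}

#' Path-coefficient decomposition of trait-yield correlations
#'
#' Standardizes the chosen traits and yield, then solves the normal equations
#' `R_x p = r_xy` for the direct effects (standardized path coefficients).
#' Each trait's correlation with yield splits exactly into its direct effect
#' plus the indirect effects transmitted through correlated traits:
#' `r_iy = p_i + sum_{j != i} r_ij p_j`. The total determination is
#' `R2 = sum_i p_i r_iy`, partitioned into a direct part `sum_i p_i^2` and
#' the indirect remainder; the residual (noise) effect is `sqrt(1 - R2)`.
#'
#' @param x Data frame/matrix of the chosen trait columns.
#' @param y Yield vector.
#' @return A `path_decomposition`: data frame with one row per trait
#'   (`direct`, `indirect`, `correlation`, `direct_r2`) and attributes
#'   `r2_total`, `r2_direct`, `r2_indirect`, `residual_effect`.
#' @export
path_analysis <- function(x, y) {
  m <- .numeric_trait_matrix(as.data.frame(x))
  if (nrow(m) != length(y)) stop("x and y sizes differ")
  Rx <- stats::cor(m)
  rxy <- drop(stats::cor(m, y))
  if (rcond(Rx) < 1e-12) {
    stop("correlation matrix of the chosen traits is singular")
  }
  p <- drop(solve(Rx, rxy))
  r2 <- sum(p * rxy)
  if (r2 > 1) {
    warning("total determination exceeded 1 numerically; clamped")
    r2 <- 1
  }
  out <- data.frame(trait = colnames(m),
                    direct = p,
                    indirect = rxy - p,
                    correlation = rxy,
                    direct_r2 = p^2,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("path_decomposition", "data.frame"),
            r2_total = r2,
            r2_direct = sum(p^2),
            r2_indirect = r2 - sum(p^2),
            residual_effect = sqrt(max(1 - r2, 0)))
}

#' @export
print.path_decomposition <- function(x, ...) {
  cat("Path-coefficient decomposition\n")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  cat(sprintf("R2 = %.3f (direct %.3f, indirect %.3f); residual effect %.3f\n",
              attr(x, "r2_total"), attr(x, "r2_direct"),
              attr(x, "r2_indirect"), attr(x, "residual_effect")))
  invisible(x)
}
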