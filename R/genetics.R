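#' Combined split-plot analysis of variance for one trait
#'
#' Partitions the total sum of squares of a balanced two-season split-plot
#' trial into the classical source list: season (S), replicates within season
#' rep(S), irrigation regime (I), S x I, replicates within season x regime
#' rep(I x S), genotype (G), S x G, I x G, S x I x G, and the subplot Error.
#' Fitting uses [stats::aov()] on the orthogonal balanced layout; the
#' decomposition is exact (source sums of squares add to the total).
#'
#' @param observations Long plot table with columns genotype, season, regime,
#'   rep, trait, value (see [read_plot_table()]).
#' @param trait Trait label to analyse.
#' @return An `anova_table`: data frame with columns `source`, `df`, `ss`,
#'   `ms` in the order above.
#' @export
combined_anova <- function(observations, trait) {
  obs <- observations[observations$trait == trait, , drop = FALSE]
  if (!nrow(obs)) stop("no observations for trait '", trait, "'")
  counts <- table(obs$genotype, obs$season, obs$regime, obs$rep)
  if (any(counts != 1L)) {
    stop("unbalanced data for trait '", trait,
         "': every genotype x season x regime x rep cell must occur exactly once")
  }
  d <- data.frame(S = factor(obs$season), I = factor(obs$regime),
                  G = factor(obs$genotype), R = factor(obs$rep),
                  y = obs$value)
  fit <- stats::aov(y ~ S + S:R + I + S:I + S:I:R + G + S:G + I:G + S:I:G,
                    data = d)
  tab <- summary(fit)[[1]]
  term <- trimws(rownames(tab))
  want <- c("S", "S:R", "I", "S:I", "S:R:I", "G", "S:G", "I:G", "S:I:G",
            "Residuals")
  idx <- match(want, term)
  if (anyNA(idx)) stop("ANOVA term missing: ", paste(want[is.na(idx)],
                                                     collapse = ", "))
  out <- data.frame(
    source = c("S", "rep(S)", "I", "SxI", "rep(IxS)", "G", "SxG", "IxG",
               "SxIxG", "Error"),
    df = tab$Df[idx],
    ss = tab$`Sum Sq`[idx],
    ms = tab$`Mean Sq`[idx],
    stringsAsFactors = FALSE)
  structure(out, class = c("anova_table", "data.frame"),
            trait = trait)
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Combined split-plot ANOVA",
      if (!is.null(attr(x, "trait"))) paste0(" (", attr(x, "trait"), ")"),
      "\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = 5), row.names = FALSE)
  invisible(x)
}

#' ANOVA-based variance components
#'
#' Moment estimators from the combined ANOVA mean squares:
#' `sigma2_g = (MS_G - MS_GxE) / (r e)`,
#' `sigma2_gxe = (MS_GxE - MS_Error) / r`, and `sigma2_re = MS_Error`.
#' The genotype-by-environment mean square is taken from the chosen
#' interaction under `convention`: `"pooled"` (default) uses the df-weighted
#' mean of the S x G, I x G and S x I x G mean squares; `"sxg"`, `"ixg"` and
#' `"sxixg"` use a single interaction. Negative moment estimates are
#' truncated to zero and flagged.
#'
#' @param anova An [combined_anova()] table, or any list with elements
#'   `ms_g`, `ms_gxe`, `ms_error`.
#' @param r Number of replicates.
#' @param e Number of environments.
#' @param convention Which interaction mean square estimates G x E.
#' @return A `variance_components` object with fields `sigma2_g`,
#'   `sigma2_gxe`, `sigma2_re`, `r`, `e`, `convention`, `truncated`.
#' @export
variance_components <- function(anova, r, e,
                                convention = c("pooled", "sxg", "ixg",
                                               "sxixg")) {
  convention <- match.arg(convention)
  if (r * e == 0) stop("r and e must be positive")
  if (inherits(anova, "anova_table") || is.data.frame(anova)) {
    ms <- stats::setNames(anova$ms, anova$source)
    df <- stats::setNames(anova$df, anova$source)
    ms_g <- ms[["G"]]
    ms_err <- ms[["Error"]]
    ms_gxe <- switch(convention,
      pooled = stats::weighted.mean(ms[c("SxG", "IxG", "SxIxG")],
                                    df[c("SxG", "IxG", "SxIxG")]),
      sxg = ms[["SxG"]],
      ixg = ms[["IxG"]],
      sxixg = ms[["SxIxG"]])
  } else {
    ms_g <- anova$ms_g; ms_gxe <- anova$ms_gxe; ms_err <- anova$ms_error
  }
  raw_g <- (ms_g - ms_gxe) / (r * e)
  raw_gxe <- (ms_gxe - ms_err) / r
  truncated <- character(0)
  if (raw_g < 0) truncated <- c(truncated, "sigma2_g")
  if (raw_gxe < 0) truncated <- c(truncated, "sigma2_gxe")
  structure(
    list(sigma2_g = max(raw_g, 0), sigma2_gxe = max(raw_gxe, 0),
         sigma2_re = ms_err, r = r, e = e,
         convention = convention, truncated = truncated),
    class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (", x$convention, " G x E mean square; r = ", x$r,
      ", e = ", x$e, ")\n", sep = "")
  cat(sprintf("  sigma2_g = %.5g  sigma2_gxe = %.5g  sigma2_re = %.5g\n",
              x$sigma2_g, x$sigma2_gxe, x$sigma2_re))
  if (length(x$truncated)) {
    cat("  truncated to zero:", paste(x$truncated, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Genetic parameters from variance components
#'
#' Computes the quantitative-genetic summary used to compare traits for
#' indirect selection. With phenotypic variance on a genotype-mean basis,
#' `sigma2_p = sigma2_g + sigma2_gxe/e + sigma2_re/(r e)`:
#' broad-sense heritability `h2 = 100 sigma2_g / sigma2_p` (percent);
#' genotypic and phenotypic coefficients of variation
#' `GCV = 100 sqrt(sigma2_g) / mean` and `PCV = 100 sqrt(sigma2_p) / mean`;
#' genetic advance under truncation selection
#' `GA = k (sigma2_g / sigma2_p) sqrt(sigma2_p)`; and genetic gain
#' `GG = 100 GA / mean`. By construction `h2 = 100 (GCV/PCV)^2`.
#'
#' @param vc A [variance_components()] object.
#' @param grand_mean Trait grand mean (nonzero), the unweighted mean of all
#'   plot observations.
#' @param k Standardized selection differential; 2.06 at 5% selection
#'   intensity.
#' @return A `genetic_parameters` object: list with `h2`, `gcv`, `pcv`, `ga`,
#'   `gg`, `k`, `grand_mean` and the input components.
#' @export
genetic_parameters <- function(vc, grand_mean, k = 2.06) {
  stopifnot(inherits(vc, "variance_components"))
  if (!is.finite(grand_mean) || grand_mean == 0) {
    stop("grand_mean must be nonzero")
  }
  s2p <- vc$sigma2_g + vc$sigma2_gxe / vc$e + vc$sigma2_re / (vc$r * vc$e)
  if (s2p <= 0) stop("phenotypic variance is zero; heritability undefined")
  h2 <- vc$sigma2_g / s2p
  ga <- k * h2 * sqrt(s2p)
  structure(
    list(h2 = 100 * h2,
         gcv = 100 * sqrt(vc$sigma2_g) / abs(grand_mean),
         pcv = 100 * sqrt(s2p) / abs(grand_mean),
         ga = ga,
         gg = genetic_gain(ga, grand_mean),
         k = k, grand_mean = grand_mean,
         sigma2_p = s2p, components = vc),
    class = "genetic_parameters")
}

#' Genetic gain as a percentage of the trait mean
#'
#' @param ga Genetic advance, in trait units.
#' @param grand_mean Trait grand mean (nonzero).
#' @return `100 * ga / grand_mean`.
#' @export
genetic_gain <- function(ga, grand_mean) {
  if (any(grand_mean == 0)) stop("grand_mean must be nonzero")
  100 * ga / grand_mean
}

#' @export
print.genetic_parameters <- function(x, ...) {
  cat(sprintf(
    "Genetic parameters: h2 = %.2f%%  GCV = %.2f  PCV = %.2f  GA = %.3g  GG = %.2f%%\n",
    x$h2, x$gcv, x$pcv, x$ga, x$gg))
  invisible(x)
}

#' Per-trait genetic parameter table for a trial
#'
#' Runs [combined_anova()], [variance_components()] and
#' [genetic_parameters()] for every trait in a long plot table.
#'
#' @param observations Long plot table.
#' @param traits Traits to summarise; default all.
#' @param e Number of environments; default seasons x regimes present in the
#'   data.
#' @param convention Passed to [variance_components()].
#' @param k Passed to [genetic_parameters()].
#' @return Data frame with one row per trait: grand_mean, sigma2_g,
#'   sigma2_gxe, sigma2_re, h2, gcv, pcv, ga, gg.
#' @export
genetic_summary <- function(observations, traits = NULL, e = NULL,
                            convention = "pooled", k = 2.06) {
  if (is.null(traits)) traits <- unique(observations$trait)
  r <- length(unique(observations$rep))
  if (is.null(e)) {
    e <- length(unique(observations$season)) *
      length(unique(observations$regime))
  }
  rows <- lapply(traits, function(tr) {
    at <- combined_anova(observations, tr)
    vc <- variance_components(at, r = r, e = e, convention = convention)
    gm <- mean(observations$value[observations$trait == tr])
    gp <- genetic_parameters(vc, gm, k = k)
    data.frame(trait = tr, grand_mean = gm,
               sigma2_g = vc$sigma2_g, sigma2_gxe = vc$sigma2_gxe,
               sigma2_re = vc$sigma2_re,
               h2 = gp$h2, gcv = gp$gcv, pcv = gp$pcv, ga = gp$ga, gg = gp$gg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "r") <- r
  attr(out, "e") <- e
  attr(out, "convention") <- convention
  out
}
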