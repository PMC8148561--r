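#' Specify one simulated trait
#'
#' A trait specification carries the simulation truth for a single phenotype:
#' its grand mean, the three variance components of the additive trial model
#' (genotypic, genotype-by-environment, plot residual), the direction and size
#' of the irrigation-stress effect, and its target genetic correlation with the
#' designated yield trait.
#'
#' @param name Trait label (e.g. `"GY"`, `"CT"`).
#' @param grand_mean Trait grand mean, in trait units.
#' @param sigma2_g Genotypic variance (>= 0).
#' @param sigma2_gxe Genotype-by-environment interaction variance (>= 0).
#' @param sigma2_e Plot residual variance (>= 0).
#' @param stress_direction `"decreases"` if the trait drops under limited
#'   irrigation (most traits), `"increases"` if it rises (canopy temperature,
#'   water-use efficiencies, stomatal limitation).
#' @param stress_shift Absolute difference between the full- and
#'   limited-irrigation trait means, in trait units (>= 0).
#' @param yield_correlation Target genetic correlation with the yield trait,
#'   in \[-1, 1\].
#'
#' @return A `trait_spec` object (named list).
#' @export
trait_spec <- function(name, grand_mean, sigma2_g, sigma2_gxe, sigma2_e,
                       stress_direction = c("decreases", "increases"),
                       stress_shift = 0, yield_correlation = 0) {
  stress_direction <- match.arg(stress_direction)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  vars <- c(sigma2_g = sigma2_g, sigma2_gxe = sigma2_gxe, sigma2_e = sigma2_e)
  if (any(!is.finite(vars)) || any(vars < 0)) {
    stop("negative or non-finite variance component for trait '", name, "'")
  }
  if (!is.finite(stress_shift) || stress_shift < 0) {
    stop("stress_shift must be a nonnegative magnitude for trait '", name, "'")
  }
  if (!is.finite(yield_correlation) || abs(yield_correlation) > 1) {
    stop("yield_correlation must lie in [-1, 1] for trait '", name, "'")
  }
  structure(
    list(name = name, grand_mean = grand_mean,
         sigma2_g = sigma2_g, sigma2_gxe = sigma2_gxe, sigma2_e = sigma2_e,
         stress_direction = stress_direction, stress_shift = stress_shift,
         yield_correlation = yield_correlation),
    class = "trait_spec")
}

#' Define a split-plot trial design
#'
#' Describes a balanced multi-environment split-plot layout: irrigation
#' regimes on main plots, genotypes on subplots, replicated blocks within
#' each season. The generated table has one row per
#' genotype x season x regime x replicate x trait, with no missing cells.
#'
#' @param n_genotypes Number of genotypes (>= 2). Default 25.
#' @param seasons Season labels; at least one. Default `c("S1", "S2")`.
#' @param n_reps Replicates per season x regime (>= 2). Default 3.
#' @param traits List of [trait_spec()] objects; defaults to
#'   [default_trait_panel()].
#' @param yield_trait Name of the trait treated as yield when completing the
#'   genetic correlation matrix. Default `"GY"`.
#' @param e_convention How the number of environments `e` entering the
#'   phenotypic variance is counted: `"cells"` (seasons x regimes, the
#'   default) or `"seasons"`.
#' @param season_sd_frac,rep_sd_frac Standard deviations of the random season
#'   and replicate (block) effects, expressed as fractions of each trait's
#'   residual standard deviation. Defaults 0.5 and 0.25.
#' @param nonnegative Censor simulated plot values at zero (default `TRUE`):
#'   all default panel traits are physically nonnegative, and for the few
#'   high-variability traits the normal model would otherwise produce
#'   impossible negative plots in its far tail.
#'
#' @return A `trial_design` object.
#' @seealso [simulate_trial()]
#' @export
trial_design <- function(n_genotypes = 25, seasons = c("S1", "S2"),
                         n_reps = 3, traits = default_trait_panel(),
                         yield_trait = "GY",
                         e_convention = c("cells", "seasons"),
                         season_sd_frac = 0.5, rep_sd_frac = 0.25,
                         nonnegative = TRUE) {
  e_convention <- match.arg(e_convention)
  if (!is.numeric(n_genotypes) || n_genotypes < 2) {
    stop("need at least 2 genotypes")
  }
  if (!is.numeric(n_reps) || n_reps < 2) stop("need at least 2 replicates")
  if (length(seasons) < 1) stop("need at least one season")
  if (anyDuplicated(seasons)) stop("duplicated season labels")
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  if (!length(traits) || !all(vapply(traits, inherits, TRUE, "trait_spec"))) {
    stop("traits must be a list of trait_spec objects")
  }
  nm <- vapply(traits, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicated trait names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(traits) <- nm
  structure(
    list(n_genotypes = as.integer(n_genotypes),
         seasons = as.character(seasons),
         regimes = c("full", "limited"),
         n_reps = as.integer(n_reps),
         traits = traits,
         yield_trait = yield_trait,
         e_convention = e_convention,
         season_sd_frac = season_sd_frac,
         rep_sd_frac = rep_sd_frac,
         nonnegative = isTRUE(nonnegative)),
    class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Split-plot trial design\n")
  cat("  genotypes: ", x$n_genotypes,
      "   seasons: ", length(x$seasons),
      "   regimes: 2 (full/limited)",
      "   reps: ", x$n_reps, "\n", sep = "")
  cat("  traits (", length(x$traits), "): ",
      paste(utils::head(names(x$traits), 8), collapse = ", "),
      if (length(x$traits) > 8) ", ..." else "", "\n", sep = "")
  cat("  environments counted as: ", n_environments(x), " (", x$e_convention,
      ")\n", sep = "")
  invisible(x)
}

#' Number of environments implied by a design
#'
#' Under the default `"cells"` convention each season x regime combination is
#' one environment; under `"seasons"` only seasons count.
#'
#' @param design A [trial_design()].
#' @return Integer count of environments `e`.
#' @export
n_environments <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  if (design$e_convention == "cells") {
    length(design$seasons) * length(design$regimes)
  } else {
    length(design$seasons)
  }
}

# Grand means, coefficients of variation and stress shifts for the default
# 28-trait panel. Magnitudes are calibrated to a realistic two-season bread
# wheat drought trial (water-status, gas-exchange, morphological, phenological
# and yield-component traits); CT, WUE, WUEi and Ls increase under limited
# irrigation, all other traits decrease.
.default_panel_table <- function() {
  tab <- read.table(header = TRUE, text = "
name   mean    gcv   pcv   shift   dir rho
LWC    73.55   2.76  4.60   3.810  dec 0.25
RWC    81.01  10.73 11.55   6.980  dec 0.39
CT     18.51  10.33 10.99   2.620  inc -0.63
LEWT    0.022 26.71 28.42   0.0035 dec 0.35
Pn     10.93  11.73 13.05   0.200  dec 0.35
Gs      0.16   8.53 15.48   0.050  dec 0.31
Ci    302.0    3.82  6.13  41.000  dec 0.30
E       2.85   7.48 11.99   0.635  dec 0.30
WUE     3.81   9.52 12.80   0.645  inc -0.30
WUEi   69.21   7.54 13.78  15.470  inc -0.30
Ls      0.32   9.80 15.24   0.080  inc -0.35
GLN    35.27   7.40  9.05   4.560  dec 0.30
FLA    21.76  17.23 18.30   3.040  dec 0.40
GLA    77.24  15.39 17.97  24.740  dec 0.45
LAI     2.96  18.90 23.87   1.415  dec 0.49
DSW     7.97  24.43 25.13   0.735  dec 0.40
DLW     0.95  20.72 22.31   0.100  dec 0.40
TDW     8.92  22.83 23.51   0.835  dec 0.45
DH     74.88   4.91  4.96   1.340  dec 0.20
DM    119.59   2.91  2.98   4.270  dec 0.20
GFD    44.61   3.69  4.08   2.865  dec 0.25
NS    465.55  11.65 14.39 110.900  dec 0.45
PH     79.25   6.75  7.65   5.625  dec 0.30
SL      9.04   7.06 11.23   0.605  dec 0.25
NSS    14.88   4.39  8.40   0.915  dec 0.30
NKS    35.27  11.12 12.40   4.560  dec 0.40
HKW    45.53  10.08 11.24   4.670  dec 0.40
GY      4.68  10.80 14.24   1.110  dec 1.00
")
  tab
}

#' Default 28-trait panel for the synthetic wheat trial
#'
#' Returns trait specifications emulating a 25-genotype, two-season, two-regime
#' bread wheat drought trial: 28 correlated agro-physiological traits with
#' realistic grand means, genotypic and phenotypic coefficients of variation,
#' and irrigation-stress shifts. Variance components are derived from the
#' coefficients of variation at the default design scale (3 replicates, 4
#' environments): the genotypic variance is `(gcv * mean / 100)^2`; the
#' non-genotypic phenotypic variance is split so that the interaction and
#' residual terms contribute equally to the phenotypic variance, which makes
#' the simulation-truth heritability equal `(gcv/pcv)^2`.
#'
#' @param traits Optional character vector restricting the panel to a subset
#'   of trait names.
#' @return A named list of [trait_spec()] objects.
#' @export
default_trait_panel <- function(traits = NULL) {
  tab <- .default_panel_table()
  if (!is.null(traits)) {
    bad <- setdiff(traits, tab$name)
    if (length(bad)) stop("unknown trait(s): ", paste(bad, collapse = ", "))
    tab <- tab[match(traits, tab$name), ]
  }
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    s2g <- (row$gcv * row$mean / 100)^2
    s2p <- (row$pcv * row$mean / 100)^2
    delta <- max(s2p - s2g, 0)
    # sigma2_gxe/e and sigma2_e/(r*e) each contribute delta/2 at r = 3, e = 4
    trait_spec(row$name, row$mean,
               sigma2_g = s2g, sigma2_gxe = 2 * delta, sigma2_e = 6 * delta,
               stress_direction = if (row$dir == "inc") "increases" else "decreases",
               stress_shift = row$shift,
               yield_correlation = row$rho)
  })
  names(specs) <- tab$name
  specs
}

#' Assemble the genetic correlation matrix for a trait panel
#'
#' Only trait-to-yield correlations are user-specified; every other pair is
#' completed by the product rule `rho_ij = rho_iy * rho_jy`, which yields the
#' rank-one-plus-diagonal matrix `rho rho' + diag(1 - rho^2)` and is positive
#' semi-definite by construction. Should a user-modified matrix fail positive
#' semi-definiteness, it is projected to the nearest correlation matrix by
#' eigenvalue clipping.
#'
#' @param design A [trial_design()].
#' @return A trait x trait correlation matrix.
#' @export
genetic_correlation <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  rho <- vapply(design$traits, `[[`, 0, "yield_correlation")
  if (design$yield_trait %in% names(rho)) rho[design$yield_trait] <- 1
  R <- tcrossprod(rho)
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    off <- which(R == min(R), arr.ind = TRUE)[1, ]
    warning("correlation target not positive semi-definite (worst pair: ",
            rownames(R)[off[1]], "/", colnames(R)[off[2]],
            "); projecting to nearest valid matrix")
    vals <- pmax(ev$values, 0)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
  }
  dimnames(R) <- list(names(rho), names(rho))
  R
}
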