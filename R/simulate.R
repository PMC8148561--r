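#' Simulate a balanced split-plot drought trial
#'
#' Generates plot-level observations under the additive model
#' \deqn{y = \mu_t + season + regime + rep(season) + rep(season \times regime)
#'       + G + G{\times}E + \epsilon}
#' where genotypic effects `G` are drawn from a multivariate normal whose
#' correlation across traits follows [genetic_correlation()], the
#' genotype-by-environment effects are independent normals with variance
#' `sigma2_gxe` per season x regime cell, and plot residuals have variance
#' `sigma2_e`. The regime effect shifts the limited-irrigation mean by
#' `stress_shift`, downward for stress-decreasing traits and upward for
#' stress-increasing ones. Season and replicate effects are drawn once per
#' level from zero-mean normals scaled to each trait's residual standard
#' deviation. When the design declares traits nonnegative (the default),
#' plot values are censored at zero, mirroring physical measurement limits.
#'
#' Identical `(design, seed)` pairs give identical tables.
#'
#' @param design A [trial_design()].
#' @param seed Integer seed for the single RNG stream.
#' @return A list of class `drought_trial` with elements
#'   \describe{
#'     \item{observations}{long data frame: genotype, season, regime, rep,
#'       trait, value.}
#'     \item{truth}{the truth manifest, see [trial_truth()].}
#'   }
#' @examples
#' trial <- simulate_trial(trial_design(n_genotypes = 5,
#'   traits = default_trait_panel(c("GY", "CT"))), seed = 1)
#' head(trial$observations)
#' @export
simulate_trial <- function(design, seed = 1) {
  stopifnot(inherits(design, "trial_design"))
  set.seed(as.integer(seed))
  g <- design$n_genotypes
  seasons <- design$seasons
  regimes <- design$regimes
  r <- design$n_reps
  traits <- design$traits
  p <- length(traits)
  genos <- sprintf("G%02d", seq_len(g))

  R <- genetic_correlation(design)
  # eigen square root: robust to the exactly singular rank-one completion
  ev <- eigen(R, symmetric = TRUE)
  Rh <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  Gz <- matrix(stats::rnorm(g * p), g, p) %*% Rh  # correlated N(0,1) per trait
  colnames(Gz) <- names(traits)

  cells <- expand.grid(season = seasons, regime = regimes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_cell <- nrow(cells)

  frame <- expand.grid(rep = seq_len(r), genotype = genos,
                       regime = regimes, season = seasons,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  frame <- frame[, c("genotype", "season", "regime", "rep")]

  out <- vector("list", p)
  for (t in seq_len(p)) {
    sp <- traits[[t]]
    sd_e <- sqrt(sp$sigma2_e)
    season_eff <- stats::rnorm(length(seasons), 0, design$season_sd_frac * sd_e)
    names(season_eff) <- seasons
    rep_s <- matrix(stats::rnorm(length(seasons) * r, 0,
                                 design$rep_sd_frac * sd_e),
                    length(seasons), r, dimnames = list(seasons, NULL))
    rep_si <- array(stats::rnorm(n_cell * r, 0, design$rep_sd_frac * sd_e),
                    c(n_cell, r))
    ge <- matrix(stats::rnorm(g * n_cell, 0, sqrt(sp$sigma2_gxe)), g, n_cell)
    eps <- stats::rnorm(nrow(frame), 0, sd_e)

    half <- sp$stress_shift / 2
    regime_eff <- if (sp$stress_direction == "decreases") {
      c(full = half, limited = -half)
    } else {
      c(full = -half, limited = half)
    }
    gi <- match(frame$genotype, genos)
    ci <- match(paste(frame$season, frame$regime),
                paste(cells$season, cells$regime))
    value <- sp$grand_mean +
      season_eff[frame$season] +
      regime_eff[frame$regime] +
      rep_s[cbind(match(frame$season, seasons), frame$rep)] +
      rep_si[cbind(ci, frame$rep)] +
      sqrt(sp$sigma2_g) * Gz[cbind(gi, t)] +
      ge[cbind(gi, ci)] +
      eps
    if (isTRUE(design$nonnegative)) value <- pmax(value, 0)
    out[[t]] <- data.frame(frame, trait = sp$name, value = unname(value),
                           stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, out)
  rownames(obs) <- NULL
  structure(list(observations = obs,
                 truth = trial_truth(design, seed)),
            class = "drought_trial")
}

#' @export
print.drought_trial <- function(x, ...) {
  cat("Simulated drought trial: ", nrow(x$observations), " plot records, ",
      nrow(x$truth$traits), " traits (seed ", x$truth$seed, ")\n", sep = "")
  invisible(x)
}

#' Truth manifest for a simulated trial
#'
#' Records the simulation truth per trait: the variance components and the
#' broad-sense heritability they imply at the design's replicate and
#' environment counts,
#' `h2 = sigma2_g / (sigma2_g + sigma2_gxe/e + sigma2_e/(r e))`.
#'
#' @param design A [trial_design()].
#' @param seed Seed used for generation.
#' @return A list with `seed`, `r`, `e`, `e_convention`, and a per-trait
#'   data frame `traits`.
#' @export
trial_truth <- function(design, seed) {
  stopifnot(inherits(design, "trial_design"))
  r <- design$n_reps
  e <- n_environments(design)
  tr <- design$traits
  df <- data.frame(
    trait = names(tr),
    grand_mean = vapply(tr, `[[`, 0, "grand_mean"),
    sigma2_g = vapply(tr, `[[`, 0, "sigma2_g"),
    sigma2_gxe = vapply(tr, `[[`, 0, "sigma2_gxe"),
    sigma2_e = vapply(tr, `[[`, 0, "sigma2_e"),
    stress_direction = vapply(tr, `[[`, "", "stress_direction"),
    stress_shift = vapply(tr, `[[`, 0, "stress_shift"),
    yield_correlation = vapply(tr, `[[`, 0, "yield_correlation"),
    row.names = NULL, stringsAsFactors = FALSE)
  s2p <- df$sigma2_g + df$sigma2_gxe / e + df$sigma2_e / (r * e)
  df$h2_truth <- ifelse(s2p > 0, df$sigma2_g / s2p, NA_real_)
  list(seed = as.integer(seed), r = r, e = e,
       e_convention = design$e_convention,
       n_genotypes = design$n_genotypes,
       seasons = design$seasons,
       traits = df)
}

#' Write / read a truth manifest
#'
#' The manifest is stored as plain text: `key: value` header lines followed by
#' a CSV block with full (17 significant digit) precision, so that
#' `read_truth_manifest(write_truth_manifest(x, f))` reproduces `x` exactly.
#'
#' @param truth A manifest from [trial_truth()].
#' @param path File path.
#' @return `write_truth_manifest` returns `path` invisibly;
#'   `read_truth_manifest` returns the manifest list.
#' @export
write_truth_manifest <- function(truth, path) {
  hdr <- c(paste0("# seed: ", truth$seed),
           paste0("# r: ", truth$r),
           paste0("# e: ", truth$e),
           paste0("# e_convention: ", truth$e_convention),
           paste0("# n_genotypes: ", truth$n_genotypes),
           paste0("# seasons: ", paste(truth$seasons, collapse = ",")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- truth$traits
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(z) format(z, digits = 17))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- sub("^# ([^:]+): (.*)$", "\\1\t\\2", hdr)
  keys <- vapply(strsplit(kv, "\t"), `[`, "", 1)
  vals <- vapply(strsplit(kv, "\t"), `[`, "", 2)
  df <- utils::read.csv(text = lines[!grepl("^# ", lines)],
                        stringsAsFactors = FALSE)
  list(seed = as.integer(vals[keys == "seed"]),
       r = as.integer(vals[keys == "r"]),
       e = as.integer(vals[keys == "e"]),
       e_convention = vals[keys == "e_convention"],
       n_genotypes = as.integer(vals[keys == "n_genotypes"]),
       seasons = strsplit(vals[keys == "seasons"], ",")[[1]],
       traits = df)
}

# ---- derived-trait helpers ---------------------------------------------
# Standard water-status, gas-exchange and canopy formulas used to give the
# simulated panel its real-world meaning.

#' Derived-trait helpers
#'
#' Water-status, gas-exchange and leaf-area formulas used by the simulated
#' trait panel: leaf water content `LWC = 100 (FW - DW)/FW`, relative water
#' content `RWC = 100 (FW - DW)/(TW - DW)`, leaf equivalent water thickness
#' `LEWT = (FW - DW)/A`, instantaneous water-use efficiency `WUE = Pn/E`,
#' intrinsic water-use efficiency `WUEi = Pn/Gs`, stomatal limitation
#' `Ls = 1 - Ci/Ca`, and leaf area index `LAI = (A B)/(C D)` from green leaf
#' area `A`, plants per metre of row `B`, plants sampled `C` and row spacing
#' `D` (cm).
#'
#' @param fw,tw,dw Fresh, turgid and dry leaf weights (`tw > dw`,
#'   `fw >= dw`).
#' @param area Flag leaf area (for `LEWT`), > 0.
#' @param pn Net photosynthesis rate.
#' @param e Transpiration rate, > 0.
#' @param gs Stomatal conductance, > 0.
#' @param ci,ca Intercellular and ambient CO2 concentration (`ca > 0`).
#' @param a,b,c,d Leaf area, plants per metre, plants sampled, row spacing.
#' @return Numeric vector of derived values.
#' @name derived_traits
NULL

#' @rdname derived_traits
#' @export
leaf_water_content <- function(fw, dw) {
  if (any(fw <= 0)) stop("fresh weight must be positive")
  if (any(fw < dw)) stop("fresh weight below dry weight")
  100 * (fw - dw) / fw
}

#' @rdname derived_traits
#' @export
relative_water_content <- function(fw, tw, dw) {
  if (any(tw <= dw)) stop("turgid weight must exceed dry weight")
  if (any(fw < dw)) stop("fresh weight below dry weight")
  100 * (fw - dw) / (tw - dw)
}

#' @rdname derived_traits
#' @export
leaf_equivalent_water_thickness <- function(fw, dw, area) {
  if (any(area <= 0)) stop("leaf area must be positive")
  if (any(fw < dw)) stop("fresh weight below dry weight")
  (fw - dw) / area
}

#' @rdname derived_traits
#' @export
water_use_efficiency <- function(pn, e) {
  if (any(e <= 0)) stop("transpiration rate must be positive")
  pn / e
}

#' @rdname derived_traits
#' @export
intrinsic_water_use_efficiency <- function(pn, gs) {
  if (any(gs <= 0)) stop("stomatal conductance must be positive")
  pn / gs
}

#' @rdname derived_traits
#' @export
stomatal_limitation <- function(ci, ca) {
  if (any(ca <= 0)) stop("ambient CO2 concentration must be positive")
  1 - ci / ca
}

#' @rdname derived_traits
#' @export
leaf_area_index <- function(a, b, c = 5, d = 17) {
  if (any(c * d == 0)) stop("zero denominator in leaf area index")
  (a * b) / (c * d)
}
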