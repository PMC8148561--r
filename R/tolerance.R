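#' Stress/control trait ratios per genotype and season
#'
#' Aggregates plot observations to genotype x season x regime means and forms
#' the limited/full irrigation ratio per genotype, season and trait. For
#' stress-increasing traits (canopy temperature here) the orientation is
#' inverted to full/limited so that a larger ratio always means a more
#' tolerant genotype: tolerant lines keep canopy temperature low under
#' stress, so the raw limited/full ratio would rank them backwards.
#'
#' @param observations Long plot table.
#' @param traits Traits to use; default all present.
#' @param invert Traits whose ratio orientation is inverted. Either a
#'   character vector of trait names or `"auto"` (default): invert every
#'   trait whose mean value rises under the limited regime (regime-contrast
#'   sign).
#' @return Long data frame genotype, season, trait, ratio, with attribute
#'   `inverted` listing the inverted traits.
#' @export
stress_ratio <- function(observations, traits = NULL, invert = "auto") {
  if (is.null(traits)) traits <- unique(observations$trait)
  obs <- observations[observations$trait %in% traits, , drop = FALSE]
  if (!all(c("full", "limited") %in% unique(obs$regime))) {
    stop("observations must contain both 'full' and 'limited' regimes")
  }
  agg <- stats::aggregate(value ~ genotype + season + regime + trait,
                          data = obs, FUN = mean)
  if (any(agg$value < 0)) {
    stop("negative trait means for trait(s): ",
         paste(unique(agg$trait[agg$value < 0]), collapse = ", "),
         "; ratios undefined")
  }
  wide <- stats::reshape(agg, idvar = c("genotype", "season", "trait"),
                         timevar = "regime", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  if (identical(invert, "auto")) {
    by_tr <- tapply(wide$limited - wide$full, wide$trait, mean)
    invert <- names(by_tr)[by_tr > 0]
  }
  inv <- wide$trait %in% invert
  den <- ifelse(inv, wide$limited, wide$full)
  if (any(den == 0)) {
    stop("zero denominator in stress ratio for trait(s): ",
         paste(unique(wide$trait[den == 0]), collapse = ", "))
  }
  ratio <- ifelse(inv, wide$full / wide$limited, wide$limited / wide$full)
  out <- data.frame(genotype = wide$genotype, season = wide$season,
                    trait = wide$trait, ratio = ratio,
                    stringsAsFactors = FALSE)
  out <- out[order(out$trait, out$season, out$genotype), ]
  rownames(out) <- NULL
  attr(out, "inverted") <- intersect(traits, invert)
  out
}

#' Membership index: min-max rescaling of stress ratios
#'
#' Within each trait x season slice, rescales the stress ratios across
#' genotypes to \[0, 1\]:
#' `F_ij = (x_ij - x_min) / (x_max - x_min)`,
#' so the best-maintaining genotype scores 1 and the worst 0. The index is
#' invariant to affine transformations of the ratios. A degenerate slice
#' (all ratios equal) gets the uninformative value `tie_value` with a
#' warning.
#'
#' @param ratios Long ratio table from [stress_ratio()] (columns genotype,
#'   season, trait, ratio).
#' @param tie_value Value assigned when a slice has zero range; default 0.5.
#' @return Long data frame genotype, season, trait, fij.
#' @export
membership_index <- function(ratios, tie_value = 0.5) {
  key <- interaction(ratios$trait, ratios$season, drop = TRUE)
  fij <- rep(NA_real_, nrow(ratios))
  for (k in levels(key)) {
    i <- key == k
    if (sum(i) < 2) stop("need at least 2 genotypes per trait x season slice")
    x <- ratios$ratio[i]
    rng <- range(x)
    if (rng[1] == rng[2]) {
      warning("zero range in slice ", k, "; assigning ", tie_value)
      fij[i] <- tie_value
    } else {
      fij[i] <- (x - rng[1]) / (rng[2] - rng[1])
    }
  }
  data.frame(genotype = ratios$genotype, season = ratios$season,
             trait = ratios$trait, fij = fij, stringsAsFactors = FALSE)
}

#' Five-rank tolerance classification scheme
#'
#' Threshold scheme mapping the overall membership score to the tolerance
#' ranks: highly tolerant (HT, `Fi >= 0.8`), tolerant (T, `0.6 <= Fi < 0.8`),
#' intermediate (I, `0.4 <= Fi < 0.6`), sensitive (S, `0.2 <= Fi < 0.4`) and
#' highly sensitive (HS, `Fi < 0.2`). The 0.8 boundary is assigned to HT so
#' the five classes partition \[0, 1\] without gaps.
#'
#' @param thresholds Strictly decreasing lower bounds of the four upper
#'   classes.
#' @param labels Class labels, most tolerant first; one more label than
#'   thresholds.
#' @return A `rank_scheme` object.
#' @export
rank_scheme <- function(thresholds = c(0.8, 0.6, 0.4, 0.2),
                        labels = c("HT", "T", "I", "S", "HS")) {
  if (any(diff(thresholds) >= 0)) stop("thresholds must strictly decrease")
  if (length(labels) != length(thresholds) + 1) {
    stop("need one more label than thresholds")
  }
  structure(list(thresholds = thresholds, labels = labels),
            class = "rank_scheme")
}

#' Classify overall membership scores
#'
#' @param fi Numeric vector of overall membership scores.
#' @param scheme A [rank_scheme()].
#' @return Character vector of class labels.
#' @export
classify_fi <- function(fi, scheme = rank_scheme()) {
  stopifnot(inherits(scheme, "rank_scheme"))
  idx <- length(scheme$thresholds) + 1 -
    findInterval(fi, rev(scheme$thresholds))
  scheme$labels[idx]
}

#' Per-genotype membership profile and tolerance class
#'
#' Averages the membership scores into the per-season index (mean over
#' traits within each season), the combined index (mean over all
#' trait x season scores) and the tolerance class of each. Classification
#' uses the unrounded scores; the reported scores are rounded half-up to 3
#' decimals for display parity with published membership tables.
#'
#' @param fij Long membership table from [membership_index()].
#' @param scheme A [rank_scheme()].
#' @return A `membership_profile`: data frame with one row per genotype,
#'   columns `<trait>_<season>` scores, `Fi_<season>`, `class_<season>`,
#'   `Fi_combined`, `class_combined`. Attribute `scheme` stores the scheme.
#' @export
tolerance_score <- function(fij, scheme = rank_scheme()) {
  if (!nrow(fij)) stop("empty trait panel")
  seasons <- sort(unique(fij$season))
  genos <- unique(fij$genotype)
  wide <- stats::reshape(
    transform(fij, key = paste(trait, season, sep = "_"))[
      c("genotype", "key", "fij")],
    idvar = "genotype", timevar = "key", direction = "wide")
  names(wide) <- sub("^fij\\.", "", names(wide))
  wide <- wide[match(genos, wide$genotype), ]
  for (s in seasons) {
    sub <- fij[fij$season == s, ]
    fi <- as.vector(tapply(sub$fij, sub$genotype, mean)[genos])
    wide[[paste0("Fi_", s)]] <- fi
    wide[[paste0("class_", s)]] <- classify_fi(fi, scheme)
  }
  fi_comb <- as.vector(tapply(fij$fij, fij$genotype, mean)[genos])
  wide$Fi_combined <- fi_comb
  wide$class_combined <- classify_fi(fi_comb, scheme)
  rownames(wide) <- NULL
  structure(wide, class = c("membership_profile", "data.frame"),
            scheme = scheme, seasons = seasons)
}

#' @export
print.membership_profile <- function(x, digits = 3, ...) {
  cat("Membership profile (", nrow(x), " genotypes)\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round_half_up, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Round half away from zero
#'
#' Published membership tables round 0.0005 up; R's [round()] rounds to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 3) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Drought-tolerance profile straight from plot observations
#'
#' Convenience wrapper running [stress_ratio()], [membership_index()] and
#' [tolerance_score()] on a chosen trait panel.
#'
#' @param observations Long plot table.
#' @param traits Trait panel; default the four-trait screening panel
#'   `c("GLA", "LAI", "RWC", "CT")` intersected with the traits present.
#' @param invert Passed to [stress_ratio()].
#' @param scheme Passed to [tolerance_score()].
#' @return A `membership_profile`.
#' @export
tolerance_profile <- function(observations,
                              traits = c("GLA", "LAI", "RWC", "CT"),
                              invert = "auto", scheme = rank_scheme()) {
  traits <- intersect(traits, unique(observations$trait))
  if (!length(traits)) stop("empty trait panel")
  ratios <- stress_ratio(observations, traits = traits, invert = invert)
  prof <- tolerance_score(membership_index(ratios), scheme = scheme)
  attr(prof, "inverted") <- attr(ratios, "inverted")
  prof
}

#' Class counts and cross-season agreement
#'
#' Summarizes a membership profile: how many genotypes fall in each
#' tolerance class (combined scores) and how many genotypes receive the same
#' class in every season.
#'
#' @param profile A [tolerance_score()] profile.
#' @return List with `counts` (named integer vector over all classes of the
#'   scheme) and `season_agreement` (count of genotypes whose per-season
#'   classes all coincide).
#' @export
classify_panel <- function(profile) {
  stopifnot(inherits(profile, "membership_profile"))
  scheme <- attr(profile, "scheme")
  counts <- table(factor(profile$class_combined, levels = scheme$labels))
  seasons <- attr(profile, "seasons")
  cls <- profile[paste0("class_", seasons)]
  agree <- sum(apply(as.matrix(cls), 1, function(z) length(unique(z)) == 1))
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       season_agreement = agree)
}
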