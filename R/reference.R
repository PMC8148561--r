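#' Reference tables from a published wheat drought-screening trial
#'
#' Small digitized tables from a published two-season, two-regime screening
#' trial of 25 bread wheat genotypes, shipped so the package's worked
#' examples and tests run offline:
#' \describe{
#'   \item{`reference_membership_scores()`}{per-genotype membership scores
#'     for the four-trait panel (GLA, LAI, RWC, CT) in each season, with the
#'     per-season and combined overall indices and tolerance classes.}
#'   \item{`reference_path_coefficients()`}{stepwise-regression and
#'     path-coefficient table for grain yield on five screened traits;
#'     attributes `intercept`, `r2_total`, `r2_direct`, `r2_indirect`,
#'     `residual_effect` carry the model-level values.}
#'   \item{`reference_collinearity()`}{tolerance and VIF per trait before
#'     and after excluding the days-to-maturity trait.}
#'   \item{`reference_genetic_parameters()`}{heritability, GCV, PCV, genetic
#'     advance and genetic gain per trait.}
#'   \item{`reference_cell_means()`}{season x regime means of the
#'     days-to-heading trait.}
#' }
#'
#' @return A data frame (see above).
#' @name reference_tables
NULL

.extdata <- function(name) {
  system.file("extdata", name, package = "droughtscreen", mustWork = TRUE)
}

#' @rdname reference_tables
#' @export
reference_membership_scores <- function() {
  utils::read.csv(.extdata("membership_scores.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_path_coefficients <- function() {
  path <- .extdata("path_coefficients.csv")
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  df <- utils::read.csv(text = lines[!grepl("^# ", lines)],
                        stringsAsFactors = FALSE)
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), ": ")[[1]]
    attr(df, kv[1]) <- as.numeric(kv[2])
  }
  df
}

#' @rdname reference_tables
#' @export
reference_collinearity <- function() {
  utils::read.csv(.extdata("collinearity_reference.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_genetic_parameters <- function() {
  utils::read.csv(.extdata("genetic_parameters_reference.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_cell_means <- function() {
  utils::read.csv(.extdata("heading_date_means.csv"),
                  stringsAsFactors = FALSE)
}

#' Long membership scores from the reference table
#'
#' Reshapes the `<trait>_<season>` score columns of
#' [reference_membership_scores()] into the long genotype/season/trait/fij
#' layout accepted by [tolerance_score()].
#'
#' @return Long data frame with columns genotype, season, trait, fij.
#' @export
reference_membership_long <- function() {
  wide <- reference_membership_scores()
  score_cols <- grep("^(GLA|LAI|RWC|CT)_S[0-9]+$", names(wide), value = TRUE)
  parts <- strsplit(score_cols, "_")
  out <- do.call(rbind, lapply(seq_along(score_cols), function(i) {
    data.frame(genotype = wide$genotype,
               season = parts[[i]][2],
               trait = parts[[i]][1],
               fij = wide[[score_cols[i]]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
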