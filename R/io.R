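#' Read a long-format plot table
#'
#' Reads and validates a CSV of plot-level observations: columns `genotype`,
#' `season`, `regime`, `rep`, `trait`, `value`, one row per plot x trait.
#' Non-numeric values and duplicated keys are rejected with the offending
#' row/key in the message.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_plot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_plot_table(df)
}

#' @rdname read_plot_table
#' @param observations A data frame to validate in place.
#' @export
validate_plot_table <- function(observations) {
  need <- c("genotype", "season", "regime", "rep", "trait", "value")
  miss <- setdiff(need, names(observations))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(observations$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(observations$value))))
    stop("non-numeric value at row ", bad[1])
  }
  if (anyNA(observations$value)) {
    stop("non-numeric value at row ", which(is.na(observations$value))[1])
  }
  key <- do.call(paste, c(observations[c("genotype", "season", "regime",
                                         "rep", "trait")], sep = "/"))
  if (anyDuplicated(key)) {
    stop("duplicated plot record: ", key[duplicated(key)][1])
  }
  observations[c(need, setdiff(names(observations), need))]
}

#' Write a long-format plot table
#'
#' @param observations Long plot table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects and validates every stage parameter of [run_pipeline()].
#' Unknown argument names are rejected.
#'
#' @param input Optional path to a long plot CSV; when `NULL` a trial is
#'   simulated from `design` and `seed`.
#' @param design A [trial_design()] used when simulating.
#' @param seed RNG seed for simulation and permutation tests.
#' @param e_convention `"cells"` or `"seasons"` (environments entering the
#'   genetic parameters).
#' @param gxe_convention Interaction mean square choice, see
#'   [variance_components()].
#' @param k Selection differential, default 2.06.
#' @param vif_threshold,loading_threshold,n_components Screening stage
#'   parameters.
#' @param yield_trait Yield column name, default `"GY"`.
#' @param alpha_enter,alpha_remove Stepwise stage parameters.
#' @param panel Trait panel for the membership index; default
#'   `c("GLA", "LAI", "RWC", "CT")`.
#' @param invert Ratio inversion rule, see [stress_ratio()].
#' @param linkage,n_groups Validation stage parameters.
#' @param n_perm Mantel permutations.
#' @param out_dir Optional directory for CSV reports.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, design = trial_design(), seed = 1,
                            e_convention = c("cells", "seasons"),
                            gxe_convention = c("pooled", "sxg", "ixg",
                                               "sxixg"),
                            k = 2.06, vif_threshold = 10,
                            loading_threshold = 0.27, n_components = 2,
                            yield_trait = "GY",
                            alpha_enter = 0.05, alpha_remove = 0.10,
                            panel = c("GLA", "LAI", "RWC", "CT"),
                            invert = "auto",
                            linkage = c("ward", "upgma"), n_groups = 5,
                            n_perm = 999, out_dir = NULL) {
  cfg <- list(input = input, design = design, seed = seed,
              e_convention = match.arg(e_convention),
              gxe_convention = match.arg(gxe_convention),
              k = k, vif_threshold = vif_threshold,
              loading_threshold = loading_threshold,
              n_components = n_components,
              yield_trait = yield_trait,
              alpha_enter = alpha_enter, alpha_remove = alpha_remove,
              panel = panel, invert = invert,
              linkage = match.arg(linkage), n_groups = n_groups,
              n_perm = n_perm, out_dir = out_dir)
  structure(cfg, class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Executes the stages in analysis order: data ingest/simulation, per-trait
#' genetic parameters, collinearity screening and PCA trait selection,
#' stepwise yield modelling with path decomposition, membership-index
#' tolerance classification, and multivariate group validation. Every
#' data-driven choice (excluded traits, inverted ratios, truncated variance
#' components, classifier gate) is recorded in the run log.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with one element per stage plus
#'   `log` (character vector).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  obs <- if (is.null(config$input)) {
    note("simulated trial with seed ", config$seed)
    simulate_trial(config$design, seed = config$seed)$observations
  } else {
    note("read observations from ", config$input)
    read_plot_table(config$input)
  }

  e <- switch(config$e_convention,
              cells = length(unique(obs$season)) *
                length(unique(obs$regime)),
              seasons = length(unique(obs$season)))
  genetics <- genetic_summary(obs, e = e, convention = config$gxe_convention,
                              k = config$k)
  note("genetic parameters with e = ", e, " (", config$e_convention,
       "), G x E mean square: ", config$gxe_convention)

  cells <- trait_means(obs, by = c("genotype", "season", "regime"))
  col_rep <- drop_collinear(cells, vif_threshold = config$vif_threshold)
  exc <- attr(col_rep, "excluded")
  note("collinearity exclusions: ",
       if (length(exc)) paste(exc, collapse = ", ") else "none")
  kept <- col_rep$trait
  pca <- trait_pca(cells[kept])
  selected <- select_traits(pca, config$loading_threshold,
                            config$n_components)
  note("PCA retained ", pca$retained, " components; selected traits: ",
       paste(selected, collapse = ", "))

  predictors <- setdiff(selected, config$yield_trait)
  if (!length(predictors)) stop("yield_model: no predictor traits selected")
  if (!config$yield_trait %in% names(cells)) {
    stop("yield_model: yield trait '", config$yield_trait,
         "' absent from data")
  }
  sw <- stepwise_yield(cells[predictors], cells[[config$yield_trait]],
                       config$alpha_enter, config$alpha_remove)
  path <- path_analysis(cells[sw$entered], cells[[config$yield_trait]])
  note("stepwise entered: ", paste(sw$entered, collapse = ", "),
       " (R2 = ", round(sw$r2, 3), ")")

  panel <- intersect(config$panel, unique(obs$trait))
  if (!length(panel)) panel <- sw$entered
  profile <- tolerance_profile(obs, traits = panel, invert = config$invert)
  note("membership panel: ", paste(panel, collapse = ", "),
       "; inverted ratios: ",
       paste(attr(profile, "inverted"), collapse = ", "))

  validation <- validate_groups(profile, linkage = config$linkage,
                                k = config$n_groups, n_perm = config$n_perm,
                                seed = config$seed)
  note("classifier: ", validation$classification$classifier,
       if (validation$classification$pooled_fallback)
         " (pooled fallback)" else "")

  res <- structure(
    list(observations = obs, genetics = genetics,
         collinearity = col_rep, pca = pca, selected = selected,
         stepwise = sw, path = path, profile = profile,
         validation = validation, log = log, config = config),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_reports(res, config$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Drought-screening pipeline run\n")
  for (l in x$log) cat("  - ", l, "\n", sep = "")
  invisible(x)
}

#' Write pipeline stage reports as CSV
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_reports <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  w(result$genetics, "genetic_parameters.csv")
  w(as.data.frame(result$collinearity), "collinearity.csv")
  w(data.frame(component = seq_along(result$pca$eigenvalues),
               eigenvalue = result$pca$eigenvalues,
               explained = result$pca$explained),
    "pca_eigenvalues.csv")
  w(data.frame(trait = rownames(result$pca$loadings),
               round(result$pca$loadings, 5)), "pca_loadings.csv")
  w(data.frame(trait = result$stepwise$entered,
               coefficient = unname(result$stepwise$coefficients),
               p_value = unname(result$stepwise$p_values),
               partial_r2 = unname(result$stepwise$partial_r2),
               cumulative_r2 = unname(result$stepwise$cumulative_r2)),
    "stepwise.csv")
  w(as.data.frame(result$path), "path_decomposition.csv")
  w(as.data.frame(result$profile), "membership_profile.csv")
  writeLines(cluster_newick(result$validation$clustering),
             file.path(dir, "dendrogram.newick"))
  writeLines(result$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
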