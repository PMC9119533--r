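#' Pipeline configuration
#'
#' Bundles paths, outcome roles and tuning constants for the end-to-end
#' run. Input data may come from files (coverage / outcome CSVs, optional
#' polygon GeoJSON layers) or from the synthetic generator via
#' `simulate`. Cross-validation outcomes and validation outcomes must be
#' disjoint: the validation comparison is performed on outcomes never
#' seen during the scheme search.
#'
#' @param out_dir Output directory (created if missing).
#' @param coverages_path,outcomes_path CSV inputs (ignored when
#'   `simulate` is given or polygon layers are supplied).
#' @param tracts_path,holc_path,mask_path Optional GeoJSON polygon layers;
#'   when given, coverages are computed by overlay.
#' @param simulate Optional [sim_config()]; when given, coverages and
#'   outcomes are generated synthetically.
#' @param cv_outcomes,validation_outcomes Character vectors of outcome
#'   column names used in the cross-validation grid and in the validation
#'   comparison.
#' @param sign_flips Integer indices (within `cv_outcomes`) of outcomes
#'   where higher is worse, negated before compositing.
#' @param thresholds Minimum rated coverage percentages for the grid.
#' @param tolerance Relative tolerance for the parsimonious selection.
#' @param seed Integer seed governing all pipeline randomness.
#' @return A list of class `holc_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            coverages_path = NULL, outcomes_path = NULL,
                            tracts_path = NULL, holc_path = NULL,
                            mask_path = NULL, simulate = NULL,
                            cv_outcomes = paste0("y", 1:6),
                            validation_outcomes = character(0),
                            sign_flips = c(2L, 3L),
                            thresholds = c(1, 5, 10, 15, 25, 33, 50),
                            tolerance = 0.005, seed = 1L) {
  if (length(intersect(cv_outcomes, validation_outcomes)) > 0) {
    stop("cv_outcomes and validation_outcomes must be disjoint",
         call. = FALSE)
  }
  if (any(thresholds < 0 | thresholds > 100)) {
    stop("thresholds must lie in [0, 100]", call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, coverages_path = coverages_path,
         outcomes_path = outcomes_path, tracts_path = tracts_path,
         holc_path = holc_path, mask_path = mask_path, simulate = simulate,
         cv_outcomes = cv_outcomes,
         validation_outcomes = validation_outcomes,
         sign_flips = as.integer(sign_flips), thresholds = thresholds,
         tolerance = tolerance, seed = as.integer(seed)),
    class = "holc_pipeline_config"
  )
}

#' Run the end-to-end classification pipeline
#'
#' Sequences the full analysis: coverage acquisition (overlay, file or
#' synthetic generation), scheme enumeration, the cross-validation grid,
#' meta-regression and scheme selection, collapse and class profiles, and
#' the validation comparison on held-out outcomes. All intermediate
#' tables are written as CSV under `config$out_dir`, together with a
#' machine-readable `summary.json` and a `pipeline.log` recording the
#' seed and per-stage row counts. Reruns with the same configuration are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with the main artifacts: `coverages`,
#'   `cv_results`, `scheme_summary`, `selection`, `profile`, `validation`
#'   and `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "holc_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("R version: %s", getRversion()))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    coverages <- stage("simulate", simulate_coverages(config$simulate))
    outcomes <- stage("simulate", simulate_outcomes(coverages,
                                                    config$simulate))
  } else if (!is.null(config$tracts_path)) {
    tracts <- stage("overlay", read_geojson_layer(config$tracts_path))
    holc <- stage("overlay", read_geojson_layer(config$holc_path))
    mask <- if (is.null(config$mask_path)) NULL else {
      stage("overlay", read_geojson_layer(config$mask_path))
    }
    coverages <- stage("overlay", compute_coverage(tracts, holc, mask))
    outcomes <- stage("read", read_outcome_csv(config$outcomes_path))
  } else {
    coverages <- stage("read", read_coverage_csv(config$coverages_path))
    outcomes <- stage("read", read_outcome_csv(config$outcomes_path))
  }
  cv_oc <- intersect(config$cv_outcomes, names(outcomes))
  if (length(cv_oc) == 0) stop("no cv outcomes present in outcome table",
                               call. = FALSE)
  write_coverage_csv(coverages, file.path(config$out_dir, "coverages.csv"))
  write_outcome_csv(outcomes, file.path(config$out_dir, "outcomes.csv"))
  log_lines <- c(log_lines, sprintf("tracts: %d", nrow(coverages)),
                 sprintf("outcomes: %d cv + %d validation", length(cv_oc),
                         length(intersect(config$validation_outcomes,
                                          names(outcomes)))))

  # --- scheme search ------------------------------------------------------
  schemes <- enumerate_schemes()
  cv_results <- stage("cv", run_grid(
    coverages, outcomes[, c("tract_id", cv_oc)], schemes = schemes,
    thresholds = config$thresholds, seed = config$seed))
  write.csv(cv_results, file.path(config$out_dir, "cv_results.csv"),
            row.names = FALSE)
  log_lines <- c(log_lines, sprintf("schemes: %d", nrow(schemes)),
                 sprintf("cv cells: %d", nrow(cv_results)))

  rows <- meta_features(cv_results)
  meta_tabs <- stage("meta", meta_regression_tables(rows))
  for (nm in names(meta_tabs)) {
    write.csv(meta_tabs[[nm]],
              file.path(config$out_dir, paste0("meta_", nm, ".csv")),
              row.names = FALSE)
  }
  summaries <- summarize_schemes(cv_results)
  write.csv(summaries, file.path(config$out_dir, "scheme_summary.csv"),
            row.names = FALSE)
  optimal <- select_optimal(summaries)
  parsimonious <- select_parsimonious(summaries,
                                      tolerance = config$tolerance)
  ggplot2::ggsave(file.path(config$out_dir, "mse_vs_df.png"),
                  plot_mse_vs_df(summaries, tolerance = config$tolerance),
                  width = 7, height = 5, dpi = 150)

  # --- collapse + profile (5% threshold universe) -------------------------
  cov5 <- filter_by_threshold(coverages, 5)
  det <- assign_labels(cov5, scheme(6, 2, FALSE))
  col10 <- collapse_labels(det)
  z <- vapply(cv_oc, function(oc) {
    standardize(outcomes[[oc]][match(cov5$tract_id, outcomes$tract_id)])
  }, numeric(nrow(cov5)))
  comp <- composite_outcome(z, config$sign_flips)
  alpha <- cronbach_alpha(sweep(z, 2, ifelse(
    seq_along(cv_oc) %in% config$sign_flips, -1, 1), `*`))
  profile <- dplyr::bind_rows(
    dplyr::mutate(class_profile(det, comp$composite),
                  classification = "detailed16"),
    dplyr::mutate(class_profile(col10, comp$composite),
                  classification = "collapsed10"))
  write.csv(profile, file.path(config$out_dir, "class_profile.csv"),
            row.names = FALSE)

  # --- validation comparison ----------------------------------------------
  validation <- NULL
  ratio <- NULL
  val_oc <- intersect(config$validation_outcomes, names(outcomes))
  if (length(val_oc) > 0) {
    validation <- stage("compare", r2_table(
      coverages, outcomes[, c("tract_id", val_oc)],
      outcome_groups = list(validation = val_oc)))
    write.csv(validation$cells,
              file.path(config$out_dir, "validation_r2.csv"),
              row.names = FALSE)
    avg <- validation$averages
    ratio <- performance_ratio(
      avg$mean_r_squared[avg$kind == "collapsed10"],
      avg$mean_r_squared[avg$kind == "optimal40"])
  }

  summary <- list(
    seed = config$seed,
    n_tracts = nrow(coverages),
    n_schemes = nrow(schemes),
    n_cv_cells = nrow(cv_results),
    cells_per_scheme = nrow(cv_results) / nrow(schemes),
    optimal_scheme = optimal,
    parsimonious_scheme = parsimonious,
    n_detailed_classes = length(unique(det)),
    n_collapsed_classes = length(unique(col10)),
    cronbach_alpha = alpha,
    performance_ratio_pct = if (is.null(ratio)) NULL else ratio$percent
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(log_lines,
                 sprintf("optimal: %s", optimal),
                 sprintf("parsimonious: %s", parsimonious),
                 sprintf("collapsed classes: %d", length(unique(col10))))
  writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))

  invisible(list(coverages = coverages, cv_results = cv_results,
                 scheme_summary = summaries,
                 selection = list(optimal = optimal,
                                  parsimonious = parsimonious),
                 profile = profile, validation = validation,
                 summary = summary))
}
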