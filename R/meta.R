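#' Build the meta-regression feature table from CV results
#'
#' One row per cross-validation cell, with the experiment features coded
#' as factors at the stated reference levels: ratings count (reference 2),
#' set (reference set 6, rank-ordered), unrated inclusion (reference
#' exclude), outcome (reference configurable) and threshold (reference
#' 5 percent).
#'
#' @param cv_results Output of [run_grid()].
#' @param outcome_ref Reference outcome level; defaults to the first
#'   outcome id.
#' @return A tibble with `mse` and factor columns `ratings_count`,
#'   `set_cat`, `include_u`, `outcome_cat`, `threshold_cat`.
#' @export
meta_features <- function(cv_results, outcome_ref = NULL) {
  stopifnot(nrow(cv_results) > 0)
  ocs <- unique(cv_results$outcome_id)
  if (is.null(outcome_ref)) outcome_ref <- ocs[1]
  stopifnot(outcome_ref %in% ocs)
  tibble::tibble(
    mse = cv_results$mse,
    ratings_count = stats::relevel(factor(cv_results$n_ratings), ref = "2"),
    set_cat = stats::relevel(factor(paste0("set", cv_results$set_id)),
                             ref = "set6"),
    include_u = stats::relevel(
      factor(ifelse(cv_results$include_unrated, "include", "exclude")),
      ref = "exclude"),
    outcome_cat = stats::relevel(factor(cv_results$outcome_id),
                                 ref = outcome_ref),
    threshold_cat = stats::relevel(factor(cv_results$threshold), ref = "5")
  )
}

META_FEATURES <- c("ratings_count", "set_cat", "include_u", "outcome_cat",
                   "threshold_cat")

#' Regress cross-validated MSEs on experiment features
#'
#' Ordinary least squares of the cell MSEs on dummy-coded experiment
#' features, either one feature group at a time or all simultaneously.
#' Because the grid is a (near) balanced factorial, one-at-a-time and
#' all-features coefficients coincide up to numerical error.
#'
#' @param rows A feature table from [meta_features()].
#' @param feature_subset Character vector of feature names (subset of
#'   `ratings_count`, `set_cat`, `include_u`, `outcome_cat`,
#'   `threshold_cat`), or `"all"`. An empty subset fits the intercept-only
#'   model.
#' @return A tibble of coefficients (`term`, `estimate`, `se`, `p`) with
#'   attributes `r_squared` and `n`.
#' @export
regress_mse_on_features <- function(rows, feature_subset = "all") {
  stopifnot(nrow(rows) > 0)
  feats <- if (identical(feature_subset, "all")) META_FEATURES
           else feature_subset
  stopifnot(all(feats %in% META_FEATURES))
  for (f in feats) {
    if (nlevels(droplevels(rows[[f]])) < 2) {
      stop("feature ", f, " has a single level", call. = FALSE)
    }
  }
  rhs <- if (length(feats) == 0) "1" else paste(feats, collapse = " + ")
  fit <- lm(stats::as.formula(paste("mse ~", rhs)), data = rows)
  sm <- summary(fit)
  co <- sm$coefficients
  out <- tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    se = unname(co[, "Std. Error"]),
    p = unname(co[, "Pr(>|t|)"])
  )
  attr(out, "r_squared") <- sm$r.squared
  attr(out, "n") <- length(fit$residuals)
  attr(out, "fit") <- fit
  out
}

#' One-at-a-time and all-features meta-regression tables
#'
#' Runs [regress_mse_on_features()] once per feature group and once with
#' all groups, mirroring the columns of a feature-effects table.
#'
#' @inheritParams regress_mse_on_features
#' @return A named list of coefficient tibbles (`ratings_count`, ...,
#'   `all`).
#' @export
meta_regression_tables <- function(rows) {
  out <- lapply(META_FEATURES, function(f) {
    regress_mse_on_features(rows, f)
  })
  names(out) <- META_FEATURES
  out$all <- regress_mse_on_features(rows, "all")
  out
}

#' Per-outcome stratified meta-regressions
#'
#' Reruns the all-features meta-regression separately for each outcome,
#' with the outcome dummies dropped.
#'
#' @param cv_results Output of [run_grid()].
#' @return A named list of coefficient tibbles, one per outcome.
#' @export
stratified_regressions <- function(cv_results) {
  ocs <- unique(cv_results$outcome_id)
  if (length(ocs) < 2) stop("need at least two outcomes to stratify",
                            call. = FALSE)
  out <- lapply(ocs, function(oc) {
    rows <- meta_features(cv_results[cv_results$outcome_id == oc, ])
    regress_mse_on_features(
      rows, setdiff(META_FEATURES, "outcome_cat"))
  })
  names(out) <- ocs
  out
}

#' Summarize per-scheme cross-validation performance
#'
#' Aggregates the grid over each scheme's cells (42 cells under the
#' default 6-outcome, 7-threshold grid): mean and median MSE, and the
#' median degrees of freedom actually used (distinct observed classes
#' minus one, which can fall below the feasible class count when not all
#' classes occur).
#'
#' @param cv_results Output of [run_grid()].
#' @return A tibble `scheme_id`, `set_id`, `n_ratings`, `include_unrated`,
#'   `mean_mse`, `median_mse`, `median_df`, `n_cells`.
#' @export
summarize_schemes <- function(cv_results) {
  out <- cv_results |>
    dplyr::group_by(.data$scheme_id, .data$set_id, .data$n_ratings,
                    .data$include_unrated) |>
    dplyr::summarise(mean_mse = mean(.data$mse),
                     median_mse = median(.data$mse),
                     median_df = median(.data$df),
                     n_cells = dplyr::n(), .groups = "drop")
  if (length(unique(out$n_cells)) > 1) {
    warning("incomplete grid: per-scheme cell counts range ",
            min(out$n_cells), "-", max(out$n_cells))
  }
  out
}

#' Select the predictively optimal scheme
#'
#' The scheme with the lowest average test MSE across its cells; exact
#' ties go to the scheme with fewer degrees of freedom.
#'
#' @param summaries Output of [summarize_schemes()].
#' @param use `"mean"` (default) or `"median"`: which MSE summary drives
#'   selection.
#' @return The selected `scheme_id`.
#' @export
select_optimal <- function(summaries, use = c("mean", "median")) {
  use <- match.arg(use)
  m <- if (use == "mean") summaries$mean_mse else summaries$median_mse
  ord <- order(m, summaries$median_df)
  summaries$scheme_id[ord[1]]
}

#' Select the parsimonious scheme
#'
#' Among schemes whose average MSE is within a relative tolerance of the
#' minimum, the one using the fewest degrees of freedom.
#'
#' @inheritParams select_optimal
#' @param tolerance Relative tolerance (default 0.005, i.e. within 0.5
#'   percent of the minimum average MSE).
#' @return The selected `scheme_id`.
#' @export
select_parsimonious <- function(summaries, tolerance = 0.005,
                                use = c("mean", "median")) {
  use <- match.arg(use)
  stopifnot(tolerance >= 0)
  m <- if (use == "mean") summaries$mean_mse else summaries$median_mse
  near <- m <= (1 + tolerance) * min(m)
  cand <- summaries[near, ]
  mc <- if (use == "mean") cand$mean_mse else cand$median_mse
  ord <- order(cand$median_df, mc)
  cand$scheme_id[ord[1]]
}

#' Scatter of scheme MSE against degrees of freedom
#'
#' Plots each scheme's summarized MSE against its median degrees of
#' freedom, with a horizontal line at the minimum and the optimal and
#' parsimonious schemes highlighted -- the overfitting-curve view of the
#' scheme search.
#'
#' @inheritParams select_optimal
#' @param tolerance Passed to [select_parsimonious()].
#' @return A ggplot object.
#' @export
plot_mse_vs_df <- function(summaries, use = c("mean", "median"),
                           tolerance = 0.005) {
  use <- match.arg(use)
  ycol <- if (use == "mean") "mean_mse" else "median_mse"
  opt <- select_optimal(summaries, use = use)
  par <- select_parsimonious(summaries, tolerance = tolerance, use = use)
  summaries$highlight <- dplyr::case_when(
    summaries$scheme_id == opt ~ "optimal",
    summaries$scheme_id == par ~ "parsimonious",
    TRUE ~ "other"
  )
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$median_df, y = .data[[ycol]],
                               colour = .data$highlight)) +
    ggplot2::geom_hline(yintercept = min(summaries[[ycol]]),
                        colour = "goldenrod") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(
      values = c(optimal = "goldenrod", parsimonious = "blue",
                 other = "grey30")) +
    ggplot2::labs(x = "Median degrees of freedom",
                  y = paste(if (use == "mean") "Mean" else "Median",
                            "cross-validated MSE"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
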