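PREDICTOR_KINDS <- c("proportions", "one_rating", "collapsed10",
                     "detailed16", "optimal40", "centroid")

#' Build predictor columns for a classification approach
#'
#' Constructs the design of each comparison approach from a coverage
#' table: `proportions` (continuous shares of rated area covered by B, C
#' and D, with A omitted for identification), `one_rating` (largest-
#' coverage grade), `detailed16` / `optimal40` (rank-ordered two- and
#' three-rating labels, unrated excluded), `collapsed10` (the ten-class
#' collapse of the detailed labels) and `centroid` (grade at the tract's
#' interior point, supplied via `centroid`). Classification kinds use the
#' rated-area denominator.
#'
#' @param coverages A coverage table.
#' @param kind One of `"proportions"`, `"one_rating"`, `"collapsed10"`,
#'   `"detailed16"`, `"optimal40"`, `"centroid"`.
#' @param centroid For `kind = "centroid"`: a tibble `tract_id`, `grade`
#'   as returned by [centroid_grade()].
#' @return A tibble with `tract_id` and either a `class` column (factor
#'   kinds) or `prop_b`, `prop_c`, `prop_d` columns.
#' @export
build_predictors <- function(coverages, kind, centroid = NULL) {
  kind <- match.arg(kind, PREDICTOR_KINDS)
  coverages <- as_coverage(coverages)
  id <- tibble::tibble(tract_id = coverages$tract_id)
  if (kind == "proportions") {
    re <- rebase_excluding_unrated(coverages)
    return(dplyr::bind_cols(id, tibble::tibble(
      prop_b = re$pct_b / 100, prop_c = re$pct_c / 100,
      prop_d = re$pct_d / 100)))
  }
  if (kind == "centroid") {
    if (is.null(centroid)) {
      stop("centroid kind requires a centroid grade table", call. = FALSE)
    }
    cls <- centroid$grade[match(coverages$tract_id, centroid$tract_id)]
    return(dplyr::bind_cols(id, tibble::tibble(class = cls)))
  }
  cls <- switch(kind,
    one_rating = assign_labels(coverages, scheme(6, 1, FALSE)),
    detailed16 = assign_labels(coverages, scheme(6, 2, FALSE)),
    collapsed10 = collapse_labels(
      assign_labels(coverages, scheme(6, 2, FALSE))),
    optimal40 = assign_labels(coverages, scheme(6, 3, FALSE))
  )
  dplyr::bind_cols(id, tibble::tibble(class = cls))
}

fit_predictor_model <- function(pred, y) {
  if ("class" %in% names(pred)) {
    keep <- !is.na(y) & !is.na(pred$class)
    df <- data.frame(y = y[keep], class = factor(pred$class[keep]))
    fit <- lm(y ~ class, data = df)
  } else {
    keep <- !is.na(y)
    df <- data.frame(y = y[keep], pred[keep, c("prop_b", "prop_c", "prop_d")])
    fit <- lm(y ~ prop_b + prop_c + prop_d, data = df)
  }
  fit
}

#' R-squared comparison table across classification approaches
#'
#' For each (outcome, approach) pair, fits OLS of the standardized outcome
#' on the approach's predictors and records R-squared, adjusted R-squared,
#' RMSE (root mean squared residual), degrees of freedom used (non-
#' intercept parameters) and n. Tracts below the minimum rated coverage
#' are excluded and outcomes are standardized on the analysis sample.
#' Per-approach averages over designated outcome groups are returned
#' alongside.
#'
#' @param coverages A coverage table.
#' @param outcomes Outcome table (`tract_id` plus numeric columns).
#' @param kinds Approaches to compare (default all except `centroid`).
#' @param outcome_groups Optional named list of outcome-id vectors (e.g.
#'   `list(health = ..., economic = ...)`) over which per-approach average
#'   R-squared values are computed.
#' @param min_rated_pct Minimum rated coverage (default 5 percent).
#' @param centroid Passed to [build_predictors()] when `"centroid"` is in
#'   `kinds`.
#' @return A list with `cells` (per outcome and approach) and `averages`
#'   (per group and approach; `NULL` without groups).
#' @export
r2_table <- function(coverages, outcomes,
                     kinds = setdiff(PREDICTOR_KINDS, "centroid"),
                     outcome_groups = NULL, min_rated_pct = 5,
                     centroid = NULL) {
  coverages <- filter_by_threshold(as_coverage(coverages), min_rated_pct)
  outcomes <- validate_outcomes(outcomes)
  outcome_ids <- setdiff(names(outcomes), "tract_id")
  preds <- lapply(kinds, function(k) {
    build_predictors(coverages, k, centroid = centroid)
  })
  names(preds) <- kinds

  cells <- list()
  for (oc in outcome_ids) {
    y_raw <- outcomes[[oc]][match(coverages$tract_id, outcomes$tract_id)]
    if (all(is.na(y_raw))) next
    y <- rep(NA_real_, length(y_raw))
    y[!is.na(y_raw)] <- standardize(y_raw[!is.na(y_raw)])
    for (k in kinds) {
      fit <- fit_predictor_model(preds[[k]], y)
      sm <- summary(fit)
      cells[[length(cells) + 1L]] <- tibble::tibble(
        outcome_id = oc, kind = k,
        r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
        rmse = sqrt(mean(fit$residuals^2)),
        df = fit$rank - 1L, n = length(fit$residuals)
      )
    }
  }
  cells <- dplyr::bind_rows(cells)

  averages <- NULL
  if (!is.null(outcome_groups)) {
    averages <- dplyr::bind_rows(lapply(names(outcome_groups), function(g) {
      sub <- cells[cells$outcome_id %in% outcome_groups[[g]], ]
      sub |>
        dplyr::group_by(.data$kind) |>
        dplyr::summarise(group = g, mean_r_squared = mean(.data$r_squared),
                         .groups = "drop")
    }))
  }
  list(cells = cells, averages = averages)
}

#' Coefficient table against a reference class
#'
#' OLS of an outcome on class indicators with a stated reference class:
#' the intercept is the reference-class mean and each coefficient the
#' difference between that class's mean and the reference mean.
#' Significance stars use two-sided t-tests with conventional standard
#' errors (0.05 / 0.01 / 0.001).
#'
#' @param labels Character vector of class labels.
#' @param y Numeric outcome aligned with `labels`.
#' @param reference_class The reference class label (must be present).
#' @return A tibble `term`, `estimate`, `se`, `p`, `stars`, with
#'   attributes `r_squared`, `rmse`, `n` and `intercept` (reference-class
#'   mean with its own se row included as term `"(Intercept)"`).
#' @export
coefficient_table <- function(labels, y, reference_class) {
  keep <- !is.na(labels) & !is.na(y)
  labels <- as.character(labels[keep]); y <- y[keep]
  if (!reference_class %in% labels) {
    stop("reference class not present: ", reference_class, call. = FALSE)
  }
  f <- stats::relevel(factor(labels), ref = reference_class)
  fit <- lm(y ~ f)
  sm <- summary(fit)
  co <- sm$coefficients
  term <- rownames(co)
  term <- ifelse(term == "(Intercept)", term, sub("^f", "", term))
  stars <- cut(co[, "Pr(>|t|)"], c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  out <- tibble::tibble(term = unname(term),
                        estimate = unname(co[, "Estimate"]),
                        se = unname(co[, "Std. Error"]),
                        p = unname(co[, "Pr(>|t|)"]),
                        stars = as.character(stars))
  attr(out, "r_squared") <- sm$r.squared
  attr(out, "rmse") <- sqrt(mean(fit$residuals^2))
  attr(out, "n") <- length(fit$residuals)
  out
}

#' Predictive-performance ratio
#'
#' The percentage of one approach's average explained variance achieved by
#' another: `100 * numerator / denominator`, reported unrounded and to the
#' nearest integer percent.
#'
#' @param numerator_avg_r2 Average R-squared of the simpler approach (in
#'   percent or as a fraction, consistently with the denominator).
#' @param denominator_avg_r2 Average R-squared of the reference approach;
#'   must be positive.
#' @return A list with `percent` (unrounded) and `percent_rounded`.
#' @export
performance_ratio <- function(numerator_avg_r2, denominator_avg_r2) {
  if (denominator_avg_r2 <= 0) {
    stop("denominator must be positive", call. = FALSE)
  }
  pct <- 100 * numerator_avg_r2 / denominator_avg_r2
  list(percent = pct, percent_rounded = round(pct))
}
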