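#' Standardize an outcome to z-scores
#'
#' Subtracts the mean and divides by the standard deviation (n - 1
#' denominator), computed on the full supplied vector. In the
#' cross-validation grid this is done per (outcome, threshold) dataset
#' before fold splitting, following the stated step order of the
#' evaluation procedure.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Numeric vector with mean 0 and sd 1.
#' @export
standardize <- function(values) {
  stopifnot(is.numeric(values))
  values <- as.numeric(values)
  if (length(unique(values[!is.na(values)])) < 2) {
    stop("cannot standardize a constant vector", call. = FALSE)
  }
  (values - mean(values, na.rm = TRUE)) / sd(values, na.rm = TRUE)
}

#' Random fold assignment
#'
#' Divides `n` observations into `k` folds whose sizes differ by at most
#' one, reproducibly from `seed`.
#'
#' @param n Number of observations.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`.
#' @export
make_folds <- function(n, k = 5, seed) {
  stopifnot(n >= k)
  withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

#' Cross-validated test MSE of a class-label regression
#'
#' For each fold, fits least squares of the outcome on class indicators
#' (intercept plus one indicator per non-reference class) in the training
#' folds and predicts the held-out fold; the fold MSE is the mean squared
#' prediction error in the test fold. Because the design is a saturated
#' dummy coding, the least-squares fit is computed in closed form as the
#' per-class training means; classes unseen in training predict the
#' training grand mean. Returns the unweighted mean of the fold MSEs.
#'
#' @param labels Character or factor class labels.
#' @param y_std Numeric outcome (typically standardized), aligned with
#'   `labels`.
#' @param folds Integer fold assignment from [make_folds()].
#' @return A list with `mse` (mean over folds) and `per_fold`.
#' @export
cv_mse <- function(labels, y_std, folds) {
  stopifnot(length(labels) == length(y_std),
            length(folds) == length(y_std))
  labels <- as.character(labels)
  ks <- sort(unique(folds))
  per_fold <- vapply(ks, function(k) {
    train <- folds != k
    if (!any(train)) stop("fold ", k, " has no training rows", call. = FALSE)
    mu <- tapply(y_std[train], labels[train], mean)
    grand <- mean(y_std[train])
    pred <- mu[labels[!train]]
    pred[is.na(pred)] <- grand
    mean((y_std[!train] - pred)^2)
  }, numeric(1))
  list(mse = mean(per_fold), per_fold = unname(per_fold))
}

#' Run the full cross-validation grid
#'
#' Scores every (scheme, outcome, threshold) cell by averaged five-fold
#' cross-validated test MSE. For each threshold, tracts below the minimum
#' rated coverage are dropped; for each outcome, rows with missing values
#' are dropped, the outcome is standardized on the resulting dataset, and
#' one fold assignment is drawn and shared by all schemes evaluated on
#' that dataset. Schemes excluding the unrated pseudo-grade are evaluated
#' on rebased compositions. With the default 54 schemes, 6 outcomes and 7
#' thresholds the grid has 2,268 cells.
#'
#' @param coverages A coverage table.
#' @param outcomes An outcome table (`tract_id` plus numeric columns).
#' @param schemes A tibble as returned by [enumerate_schemes()] (default),
#'   or a subset of it.
#' @param thresholds Minimum rated coverage percentages; default
#'   `c(1, 5, 10, 15, 25, 33, 50)`.
#' @param seed Integer seed for the fold assignments.
#' @param n_folds Number of folds (default 5).
#' @return A tibble with one row per cell: `scheme_id`, `set_id`,
#'   `n_ratings`, `include_unrated`, `outcome_id`, `threshold`, `mse`,
#'   `df` (distinct labels in the threshold dataset minus one) and
#'   `n_tracts`.
#' @export
run_grid <- function(coverages, outcomes,
                     schemes = enumerate_schemes(),
                     thresholds = c(1, 5, 10, 15, 25, 33, 50),
                     seed = 1L, n_folds = 5) {
  coverages <- as_coverage(coverages)
  outcomes <- validate_outcomes(outcomes)
  outcome_ids <- setdiff(names(outcomes), "tract_id")
  if (length(outcome_ids) < 1) stop("no outcome columns", call. = FALSE)
  scheme_objs <- lapply(seq_len(nrow(schemes)), function(i) {
    scheme_from_row(schemes[i, ])
  })

  results <- vector("list", 0)
  for (ti in seq_along(thresholds)) {
    th <- thresholds[ti]
    cov_t <- filter_by_threshold(coverages, th)
    if (nrow(cov_t) == 0) {
      stop("threshold ", th, "% eliminates all tracts", call. = FALSE)
    }
    # shared label machinery per threshold dataset: one grade ordering per
    # denominator variant, reused across all schemes
    variants <- prepare_label_variants(cov_t)
    labels_by_scheme <- lapply(scheme_objs, function(sc) {
      v <- variants[[if (sc$include_unrated) "withU" else "noU"]]
      label_from_order(v$p, v$ord, sc)
    })

    for (oi in seq_along(outcome_ids)) {
      oc <- outcome_ids[oi]
      y_all <- outcomes[[oc]][match(cov_t$tract_id, outcomes$tract_id)]
      keep <- !is.na(y_all)
      if (sum(keep) < n_folds) {
        stop("threshold ", th, "% leaves too few tracts with outcome ", oc,
             call. = FALSE)
      }
      y <- standardize(y_all[keep])
      fold_seed <- (seed + 7919L * ti + 104729L * oi) %% .Machine$integer.max
      folds <- make_folds(length(y), k = n_folds, seed = fold_seed)

      cells <- lapply(seq_along(scheme_objs), function(si) {
        lab <- labels_by_scheme[[si]][keep]
        fit <- cv_mse(lab, y, folds)
        tibble::tibble(
          scheme_id = scheme_objs[[si]]$scheme_id,
          set_id = scheme_objs[[si]]$set_id,
          n_ratings = scheme_objs[[si]]$n_ratings,
          include_unrated = scheme_objs[[si]]$include_unrated,
          outcome_id = oc, threshold = th, mse = fit$mse,
          df = length(unique(lab)) - 1L, n_tracts = length(y)
        )
      })
      results[[length(results) + 1L]] <- dplyr::bind_rows(cells)
    }
  }
  dplyr::bind_rows(results)
}

prepare_label_variants <- function(cov_t) {
  p_with <- as.matrix(cov_t[, pct_col(ALL_GRADES)])
  colnames(p_with) <- ALL_GRADES
  cov_re <- rebase_excluding_unrated(cov_t)
  p_no <- as.matrix(cov_re[, pct_col(HOLC_GRADES)])
  colnames(p_no) <- HOLC_GRADES
  list(withU = list(p = p_with, ord = order_grades(p_with)),
       noU = list(p = p_no, ord = order_grades(p_no)))
}
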