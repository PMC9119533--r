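#' @importFrom rlang .data
#' @importFrom stats lm coef predict rnorm rgamma rbeta runif sd var median
#'   setNames complete.cases pt
#' @importFrom utils head read.csv write.csv
NULL

# Rated HOLC grades, best to worst, plus the unrated pseudo-grade.
HOLC_GRADES <- c("A", "B", "C", "D")
ALL_GRADES <- c(HOLC_GRADES, "U")

# Tie-break preference when two grades cover exactly the same area:
# worst grade first, unrated last.
TIE_ORDER <- c("D", "C", "B", "A", "U")

COVERAGE_COLS <- c("tract_id", "pct_a", "pct_b", "pct_c", "pct_d", "pct_u")

pct_col <- function(grade) paste0("pct_", tolower(grade))

#' Construct and validate a tract coverage table
#'
#' A coverage table holds, for each census tract, the percentage of tract
#' (land) area covered by each HOLC grade (A best ... D worst) and by
#' unrated space (U). The five percentages are a composition: nonnegative
#' and summing to 100.
#'
#' @param x A data frame with columns `tract_id`, `pct_a`, `pct_b`, `pct_c`,
#'   `pct_d`, `pct_u`.
#' @param tol Numeric tolerance for the sum-to-100 check.
#' @return A validated tibble with the coverage columns.
#' @export
as_coverage <- function(x, tol = 1e-6) {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(COVERAGE_COLS, names(x))
  if (length(missing_cols) > 0) {
    stop("coverage table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, c(COVERAGE_COLS, setdiff(names(x), COVERAGE_COLS))]
  if (anyDuplicated(x$tract_id)) {
    dup <- unique(x$tract_id[duplicated(x$tract_id)])
    stop("duplicated tract_id: ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  p <- as.matrix(x[, pct_col(ALL_GRADES)])
  bad <- which(rowSums(p < -tol | p > 100 + tol) > 0)
  if (length(bad) > 0) {
    stop("coverage percentages outside [0, 100] in row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  s <- rowSums(p)
  off <- which(abs(s - 100) > tol)
  if (length(off) > 0) {
    stop("coverage composition does not sum to 100 in row(s): ",
         paste(head(off, 5), collapse = ", "), call. = FALSE)
  }
  x
}

#' Rebase a coverage table to the rated-area denominator
#'
#' Removes unrated area (U) from the composition and re-expresses the rated
#' grade percentages relative to the rated tract area, so that A + B + C + D
#' sums to 100. This is the denominator used by classification schemes that
#' exclude the unrated pseudo-grade.
#'
#' @param coverages A coverage table (see [as_coverage()]).
#' @return A coverage table with `pct_u = 0` and rated percentages scaled by
#'   `100 / (100 - pct_u)`.
#' @export
rebase_excluding_unrated <- function(coverages) {
  coverages <- as_coverage(coverages)
  rated <- 100 - coverages$pct_u
  if (any(rated <= 0)) {
    bad <- coverages$tract_id[rated <= 0]
    stop("cannot rebase fully unrated tract(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  for (g in HOLC_GRADES) {
    coverages[[pct_col(g)]] <- coverages[[pct_col(g)]] * 100 / rated
  }
  coverages$pct_u <- 0
  coverages
}

#' Filter tracts by minimum rated coverage
#'
#' Keeps tracts whose total rated coverage (100 - `pct_u`) is at least
#' `min_rated_pct` percent. The comparison is closed: a tract rated exactly
#' at the threshold is kept. Raising the threshold never increases the
#' number of surviving tracts.
#'
#' @param coverages A coverage table.
#' @param min_rated_pct Minimum percent of tract area that must be covered
#'   by rated (A--D) HOLC polygons, in `[0, 100]`.
#' @return The subset of `coverages` meeting the threshold.
#' @export
filter_by_threshold <- function(coverages, min_rated_pct) {
  stopifnot(is.numeric(min_rated_pct), length(min_rated_pct) == 1)
  if (min_rated_pct < 0 || min_rated_pct > 100) {
    stop("min_rated_pct must be in [0, 100]", call. = FALSE)
  }
  coverages[100 - coverages$pct_u >= min_rated_pct, , drop = FALSE]
}

#' Read / write coverage and outcome tables
#'
#' CSV dialect: UTF-8, header row, `.` decimal separator. Coverage tables
#' have columns `tract_id, pct_a, pct_b, pct_c, pct_d, pct_u`; outcome
#' tables have `tract_id` plus one numeric column per outcome. Validation
#' errors cite the offending rows.
#'
#' @param path File path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_coverage_csv <- function(path) {
  as_coverage(read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(tract_id = "character")))
}

#' @rdname table_io
#' @param coverages A coverage table.
#' @export
write_coverage_csv <- function(coverages, path) {
  write.csv(as_coverage(coverages), path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_outcome_csv <- function(path) {
  x <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                  colClasses = c(tract_id = "character")))
  validate_outcomes(x)
}

#' @rdname table_io
#' @param outcomes An outcome table (`tract_id` plus numeric columns).
#' @export
write_outcome_csv <- function(outcomes, path) {
  write.csv(validate_outcomes(outcomes), path, row.names = FALSE)
  invisible(path)
}

validate_outcomes <- function(outcomes) {
  outcomes <- tibble::as_tibble(outcomes)
  if (!"tract_id" %in% names(outcomes)) {
    stop("outcome table must have a tract_id column", call. = FALSE)
  }
  if (ncol(outcomes) < 2) {
    stop("outcome table must have at least one outcome column", call. = FALSE)
  }
  if (anyDuplicated(outcomes$tract_id)) {
    dup <- unique(outcomes$tract_id[duplicated(outcomes$tract_id)])
    stop("duplicated tract_id: ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  for (nm in setdiff(names(outcomes), "tract_id")) {
    if (!is.numeric(outcomes[[nm]])) {
      stop("outcome column ", nm, " is not numeric", call. = FALSE)
    }
  }
  outcomes
}
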