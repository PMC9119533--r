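# Coverage-percentage bin edges per classification set. Sets 1-5 coarsen
# each grade's coverage percentage into bins of decreasing resolution
# (10, 20, 25, 33.3 and 50 percentage points); set 6 discards magnitudes
# and keeps only the rank order of the grades.
SET_BREAKS <- list(
  `1` = seq(0, 100, 10),
  `2` = seq(0, 100, 20),
  `3` = seq(0, 100, 25),
  `4` = c(0, 33.3, 66.6, 100),
  `5` = c(0, 50, 100)
)

#' Define a single classification scheme
#'
#' A scheme is one recipe for turning a tract's coverage composition into a
#' categorical class label: a set (binning resolution, or rank-order for
#' set 6), the number of most-important ratings considered (1--5), and
#' whether unrated area (U) is included as a pseudo-grade. When U is
#' excluded, at most four ratings exist and coverages are rebased to the
#' rated-area denominator before labeling.
#'
#' @param set_id Integer 1--6. Sets 1--5 bin the coverage percentage
#'   (10, 20, 25, 33.3, 50 percentage-point bins respectively); set 6 is
#'   rank-ordered.
#' @param n_ratings Integer 1--5: how many of the largest-coverage grades
#'   the label retains.
#' @param include_unrated Logical; include U as its own grade?
#' @return A list of class `holc_scheme` with a `scheme_id` string such as
#'   `"set6_r2_noU"`.
#' @export
scheme <- function(set_id, n_ratings, include_unrated) {
  set_id <- as.integer(set_id)
  n_ratings <- as.integer(n_ratings)
  stopifnot(set_id %in% 1:6, n_ratings %in% 1:5, is.logical(include_unrated))
  if (!include_unrated && n_ratings > 4) {
    stop("without the unrated pseudo-grade only four ratings exist",
         call. = FALSE)
  }
  structure(
    list(scheme_id = sprintf("set%d_r%d_%s", set_id, n_ratings,
                             if (include_unrated) "withU" else "noU"),
         set_id = set_id, n_ratings = n_ratings,
         include_unrated = isTRUE(include_unrated)),
    class = "holc_scheme"
  )
}

#' Enumerate all 54 candidate classification schemes
#'
#' Six sets crossed with 1--4 ratings excluding unrated area (24 schemes)
#' and 1--5 ratings including it (30 schemes).
#'
#' @return A tibble with columns `scheme_id`, `set_id`, `n_ratings`,
#'   `include_unrated`.
#' @export
enumerate_schemes <- function() {
  grid <- rbind(
    expand.grid(set_id = 1:6, n_ratings = 1:4, include_unrated = FALSE),
    expand.grid(set_id = 1:6, n_ratings = 1:5, include_unrated = TRUE)
  )
  grid <- grid[order(grid$set_id, grid$include_unrated, grid$n_ratings), ]
  tibble::tibble(
    scheme_id = sprintf("set%d_r%d_%s", grid$set_id, grid$n_ratings,
                        ifelse(grid$include_unrated, "withU", "noU")),
    set_id = as.integer(grid$set_id),
    n_ratings = as.integer(grid$n_ratings),
    include_unrated = grid$include_unrated
  )
}

scheme_from_row <- function(row) {
  scheme(row$set_id, row$n_ratings, row$include_unrated)
}

#' Bin a coverage percentage
#'
#' Bins are half-open on the right, `[lo, hi)`, except the top bin which is
#' closed at 100. Indices are 1-based: for set 1 (10-point bins), 75
#' percent falls in bin 8. Set 4 uses the printed 33.3 / 66.6 boundaries,
#' with a boundary value belonging to the upper bin.
#'
#' @param pct Numeric vector of percentages in `[0, 100]`.
#' @param set_id Integer 1--5 (set 6 has no bins).
#' @return Integer vector of 1-based bin indices; set 1 has 10 bins, sets
#'   2--5 have 5, 4, 3 and 2.
#' @export
bin_percentage <- function(pct, set_id) {
  stopifnot(set_id %in% 1:5)
  if (any(pct < -1e-9 | pct > 100 + 1e-9)) {
    stop("percentage outside [0, 100]", call. = FALSE)
  }
  pct <- pmin(pmax(pct, 0), 100)
  breaks <- SET_BREAKS[[as.character(set_id)]]
  findInterval(pct, breaks[-length(breaks)])
}

#' Assign class labels to tracts under a scheme
#'
#' Candidate grades are the rated grades with positive coverage, plus U
#' when the scheme includes it and `pct_u > 0`. Candidates are sorted by
#' coverage, largest first, with exact ties broken worst grade first
#' (D, C, B, A, U), and truncated to the scheme's `n_ratings`. For binned
#' sets each retained grade carries its coverage bin (e.g. `"A8-B3"`); for
#' set 6 only the grade order remains (e.g. `"D-B"`). Tracts with fewer
#' present grades than `n_ratings` get shorter labels. Schemes excluding U
#' rebase the composition to the rated-area denominator first (idempotent
#' if already rebased).
#'
#' @param coverages A coverage table.
#' @param scheme A [scheme()].
#' @param bin_base 1 (default) or 0: base used when rendering bin indices,
#'   for comparability with outputs that label bins from zero.
#' @return Character vector of labels, one per tract.
#' @export
assign_labels <- function(coverages, scheme, bin_base = 1) {
  stopifnot(inherits(scheme, "holc_scheme"))
  coverages <- as_coverage(coverages)
  if (!scheme$include_unrated) {
    coverages <- rebase_excluding_unrated(coverages)
  }
  grades <- if (scheme$include_unrated) ALL_GRADES else HOLC_GRADES
  p <- as.matrix(coverages[, pct_col(grades)])
  colnames(p) <- grades
  ord <- order_grades(p)
  label_from_order(p, ord, scheme, bin_base = bin_base)
}

# Per-row ordering of grade columns: decreasing coverage, ties broken
# worst grade first.
order_grades <- function(p) {
  tie_rank <- match(colnames(p), TIE_ORDER)
  t(apply(p, 1, function(r) order(-r, tie_rank)))
}

# Vectorized label construction given precomputed orderings. Shared by
# assign_labels() and the cross-validation grid runner (which reuses one
# ordering across many schemes).
label_from_order <- function(p, ord, scheme, bin_base = 1) {
  n <- nrow(p)
  grades <- colnames(p)
  k <- min(scheme$n_ratings, ncol(p))
  if (n == 0) return(character(0))
  rated <- p[, intersect(grades, HOLC_GRADES), drop = FALSE]
  if (any(rowSums(rated > 0) == 0)) {
    stop("tract with no positive rated grade coverage cannot be labeled",
         call. = FALSE)
  }
  label <- NULL
  for (r in seq_len(k)) {
    idx <- cbind(seq_len(n), ord[, r])
    pr <- p[idx]
    part <- grades[ord[, r]]
    if (scheme$set_id <= 5) {
      part <- paste0(part,
                     bin_percentage(pr, scheme$set_id) - (1 - bin_base))
    }
    part[pr <= 0] <- NA_character_
    label <- if (is.null(label)) {
      part
    } else {
      ifelse(is.na(part), label, paste(label, part, sep = "-"))
    }
  }
  label
}

#' Enumerate the feasible labels of a scheme
#'
#' Returns every label string that some valid coverage composition could
#' produce under the scheme. For set 6 these are ordered arrangements of
#' distinct grades (4, 16, 40 and 64 labels for 1--4 ratings excluding U).
#' For binned sets, candidate grade/bin strings are screened by a
#' constraint check: there must exist percentages within the bins, ordered
#' largest first, that close to a 100-percent composition (allowing
#' unlisted-grade mass only when the label is truncated at `n_ratings`).
#' A label consisting only of U is infeasible whenever a rated grade would
#' necessarily accompany it.
#'
#' @param scheme A [scheme()].
#' @param bin_base As in [assign_labels()].
#' @return Character vector of feasible labels.
#' @export
enumerate_feasible_labels <- function(scheme, bin_base = 1) {
  stopifnot(inherits(scheme, "holc_scheme"))
  grades <- if (scheme$include_unrated) ALL_GRADES else HOLC_GRADES
  ng <- length(grades)
  nbins <- if (scheme$set_id <= 5) {
    length(SET_BREAKS[[as.character(scheme$set_id)]]) - 1L
  } else 1L
  eps <- 1e-9
  labels <- character(0)

  for (m in seq_len(min(scheme$n_ratings, ng))) {
    perms <- Filter(function(a) length(a) == m, rank_combinations(grades, m))
    for (perm in perms) {
      has_rated <- any(perm %in% HOLC_GRADES)
      truncated <- m == scheme$n_ratings && m < ng
      if (!has_rated && !truncated) next  # all-U label needs hidden rated mass
      for (bins in bin_vectors(m, nbins)) {
        if (label_feasible(perm, bins, scheme$set_id, ng, truncated,
                           has_rated, eps)) {
          lab <- if (scheme$set_id <= 5) {
            paste(paste0(perm, bins - (1 - bin_base)), collapse = "-")
          } else {
            paste(perm, collapse = "-")
          }
          labels <- c(labels, lab)
        }
      }
    }
  }
  labels
}

# All non-increasing bin index vectors of length m over 1..nbins
# (a later, smaller coverage can never sit in a strictly higher bin).
bin_vectors <- function(m, nbins) {
  out <- list()
  recurse <- function(prefix, maxbin) {
    if (length(prefix) == m) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (b in seq_len(maxbin)) recurse(c(prefix, b), b)
  }
  recurse(integer(0), nbins)
  out
}

label_feasible <- function(perm, bins, set_id, ng, truncated, has_rated,
                           eps) {
  m <- length(perm)
  if (set_id <= 5) {
    breaks <- SET_BREAKS[[as.character(set_id)]]
    lo <- breaks[bins]
    hi <- breaks[bins + 1]
    up <- ifelse(bins == length(breaks) - 1, hi, hi - eps)
  } else {
    lo <- rep(0, m)
    up <- rep(100, m)
  }
  lo[m] <- max(lo[m], eps)  # last listed grade must be strictly positive
  # impose the ordering p1 >= p2 >= ... >= pm on the interval bounds
  for (i in seq_len(m)[-1]) up[i] <- min(up[i], up[i - 1])
  for (i in rev(seq_len(m))[-1]) lo[i] <- max(lo[i], lo[i + 1])
  if (any(lo > up)) return(FALSE)
  extra_max <- if (truncated) (ng - m) * up[m] else 0
  extra_min <- if (truncated && !has_rated) eps else 0
  sum(lo) + extra_min <= 100 && 100 <= sum(up) + extra_max
}
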