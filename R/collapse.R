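# Canonical collapsed class names, in display order.
COLLAPSED_ORDER <- c(
  "Only or mainly A", "Only B", "Mainly B, some A",
  "Mainly B, some C or D", "Only C", "Mainly C, some D", "Only D",
  "Mainly D, some C", "Mainly C or D, some A", "Mainly C or D, some B"
)

#' The 16-class to 10-class collapse map
#'
#' Maps every detailed rank-ordered two-rating label (grades only, unrated
#' excluded) to one of ten collapsed classes: the four only-or-mainly-A
#' classes merge; mainly-C-or-D classes with a secondary A merge, as do
#' those with a secondary B; mainly-B classes with secondary C or D merge;
#' the remaining six classes map to themselves. The map is total over the
#' 16 feasible detailed labels and surjective onto the 10 collapsed
#' classes.
#'
#' @return A tibble with columns `detailed` and `collapsed`.
#' @export
collapse_map <- function() {
  tibble::tribble(
    ~detailed, ~collapsed,
    "A",   "Only or mainly A",
    "A-B", "Only or mainly A",
    "A-C", "Only or mainly A",
    "A-D", "Only or mainly A",
    "B",   "Only B",
    "B-A", "Mainly B, some A",
    "B-C", "Mainly B, some C or D",
    "B-D", "Mainly B, some C or D",
    "C",   "Only C",
    "C-A", "Mainly C or D, some A",
    "C-B", "Mainly C or D, some B",
    "C-D", "Mainly C, some D",
    "D",   "Only D",
    "D-A", "Mainly C or D, some A",
    "D-B", "Mainly C or D, some B",
    "D-C", "Mainly D, some C"
  )
}

#' Collapse detailed two-rating labels to the 10-class scheme
#'
#' @param labels16 Character vector of detailed labels (from
#'   [assign_labels()] with the rank-ordered two-rating scheme excluding
#'   unrated area).
#' @return Character vector of collapsed class names.
#' @export
collapse_labels <- function(labels16) {
  map <- collapse_map()
  idx <- match(labels16, map$detailed)
  if (anyNA(idx)) {
    bad <- unique(labels16[is.na(idx)])
    stop("unknown detailed label(s): ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  map$collapsed[idx]
}

#' Composite standardized outcome
#'
#' Averages standardized outcomes into a single per-tract composite after
#' aligning signs so that higher always means better (outcomes in
#' `sign_flips` are multiplied by -1). Missing values are averaged over
#' the non-missing outcomes, with the count reported.
#'
#' @param outcome_matrix Numeric matrix or data frame of standardized
#'   (z-scored) outcomes, one column per outcome.
#' @param sign_flips Integer column indices to negate.
#' @return A tibble `composite`, `n_outcomes_used`.
#' @export
composite_outcome <- function(outcome_matrix, sign_flips = integer(0)) {
  m <- as.matrix(outcome_matrix)
  stopifnot(is.numeric(m))
  for (j in sign_flips) m[, j] <- -m[, j]
  tibble::tibble(
    composite = rowMeans(m, na.rm = TRUE),
    n_outcomes_used = rowSums(!is.na(m))
  )
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = K/(K-1) * (1 - sum(item variances) / var(row sums))`, with
#' n - 1 variance denominators. Used to justify averaging a sign-aligned
#' outcome battery into one composite. For two standardized items with
#' correlation rho the closed form is `2 * rho / (1 + rho)`.
#'
#' @param outcome_matrix Numeric matrix with at least 2 columns and 3
#'   rows; columns should be sign-aligned first.
#' @return Alpha as a single number.
#' @export
cronbach_alpha <- function(outcome_matrix) {
  m <- as.matrix(outcome_matrix)
  stopifnot(ncol(m) >= 2, nrow(m) >= 3)
  m <- m[complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  total_var <- var(rowSums(m))
  if (total_var <= 0) stop("zero total variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Per-class descriptive profile
#'
#' Counts and mean composite outcome per class, sorted in the canonical
#' collapsed-class order when applicable (otherwise alphabetically).
#'
#' @param labels Character vector of class labels.
#' @param composite Numeric per-tract composite outcome, aligned with
#'   `labels`.
#' @return A tibble `class`, `n_tracts`, `mean_composite`.
#' @export
class_profile <- function(labels, composite) {
  stopifnot(length(labels) == length(composite))
  out <- tibble::tibble(class = as.character(labels),
                        composite = composite) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n_tracts = dplyr::n(),
                     mean_composite = mean(.data$composite, na.rm = TRUE),
                     .groups = "drop")
  pos <- match(out$class, COLLAPSED_ORDER)
  out[order(is.na(pos), pos, out$class), ]
}

#' Exploratory class-merge suggestions
#'
#' Utility for exploring alternative collapses: flags classes that are
#' both small and close in mean composite outcome to another class. The
#' canonical pipeline uses the fixed [collapse_map()] instead; this helper
#' exists only to examine how that map generalizes to other data.
#'
#' @param profile Output of [class_profile()].
#' @param min_n Classes with fewer tracts are merge candidates.
#' @param max_gap Maximum absolute difference in mean composite for a
#'   suggested partner.
#' @return A tibble `class`, `partner`, `gap` of suggested merges (empty
#'   when none qualify).
#' @export
suggest_merges <- function(profile, min_n = 250, max_gap = 0.1) {
  small <- profile[profile$n_tracts < min_n, ]
  if (nrow(small) == 0) return(tibble::tibble(class = character(0),
                                              partner = character(0),
                                              gap = numeric(0)))
  rows <- lapply(seq_len(nrow(small)), function(i) {
    others <- profile[profile$class != small$class[i], ]
    gap <- abs(others$mean_composite - small$mean_composite[i])
    j <- which.min(gap)
    if (gap[j] <= max_gap) {
      tibble::tibble(class = small$class[i], partner = others$class[j],
                     gap = gap[j])
    }
  })
  dplyr::bind_rows(rows)
}
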