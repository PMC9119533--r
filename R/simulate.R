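#' Configuration for the synthetic tract generator
#'
#' Bundles the parameters of the synthetic study universe: compositional
#' grade coverages per tract and multiple mutually correlated continuous
#' outcomes driven by a monotone grade-effect gradient (A best, D worst)
#' plus noise. Defaults are chosen to emulate the conditions of the real
#' tract universe this package targets: most tracts intersect more than one
#' grade, roughly a third of tract area is unrated on average, and the
#' sign-aligned outcome battery has internal consistency (Cronbach alpha)
#' in the low-0.9 range.
#'
#' @param n_tracts Number of tracts to generate.
#' @param grade_weights Named numeric vector of latent effects per rated
#'   grade. The default `c(A = 1, B = 0.5, C = 0, D = -0.5)` encodes the
#'   monotone A > B > C > D gradient; magnitudes are arbitrary.
#' @param rank_weights Numeric weights for the first to fourth
#'   largest-coverage rated grades in the latent gradient (renormalized
#'   over the grades actually present). The default `c(0.6, 0.3, 0.1, 0)`
#'   makes tract outcomes depend on the composition through the rank order
#'   of the dominant grades -- the regime where relative, not absolute,
#'   coverage carries the signal and unrated area is missing at random.
#' @param noise_sd Standard deviation of the total outcome noise
#'   (shared + idiosyncratic), on the latent outcome scale.
#' @param n_outcomes Number of outcome columns to generate.
#' @param shared_signal_frac Fraction of the noise variance shared across
#'   outcomes, in `[0, 1]`; controls inter-outcome correlation beyond the
#'   common grade gradient.
#' @param sign_flips Integer indices of outcomes whose sign is inverted,
#'   emulating outcomes where higher values are worse (e.g. disease
#'   prevalence). The default `NULL` flips outcomes 2 and 3 when present
#'   (mirroring a battery with two ill-health measures); pass `integer(0)`
#'   for no flips.
#' @param ensure_all_combinations If `TRUE`, every ordered rank combination
#'   of 1--4 rated grades, each both with and without a nonzero unrated
#'   share, is planted in at least one tract with strictly decreasing
#'   coverages.
#' @param forced Optional data frame of coverage rows (columns
#'   `pct_a ... pct_u`) to include verbatim before random tracts.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `holc_sim_config`.
#' @export
sim_config <- function(n_tracts = 1500,
                       grade_weights = c(A = 1, B = 0.5, C = 0, D = -0.5),
                       rank_weights = c(0.6, 0.3, 0.1, 0),
                       noise_sd = 0.45,
                       n_outcomes = 6,
                       shared_signal_frac = 0.5,
                       sign_flips = NULL,
                       ensure_all_combinations = TRUE,
                       forced = NULL,
                       seed = 1L) {
  stopifnot(n_tracts >= 1, n_outcomes >= 1, noise_sd >= 0,
            shared_signal_frac >= 0, shared_signal_frac <= 1)
  if (!all(HOLC_GRADES %in% names(grade_weights))) {
    stop("grade_weights must name all of A, B, C, D", call. = FALSE)
  }
  if (is.null(sign_flips)) {
    sign_flips <- intersect(c(2L, 3L), seq_len(n_outcomes))
  }
  sign_flips <- as.integer(sign_flips)
  if (length(sign_flips) > 0 &&
      (any(sign_flips < 1) || any(sign_flips > n_outcomes))) {
    stop("sign_flips must index outcomes in 1..n_outcomes", call. = FALSE)
  }
  structure(
    list(n_tracts = as.integer(n_tracts),
         grade_weights = grade_weights[HOLC_GRADES],
         rank_weights = rank_weights,
         noise_sd = noise_sd,
         n_outcomes = as.integer(n_outcomes),
         shared_signal_frac = shared_signal_frac,
         sign_flips = sign_flips,
         ensure_all_combinations = isTRUE(ensure_all_combinations),
         forced = forced,
         seed = as.integer(seed)),
    class = "holc_sim_config"
  )
}

# All ordered arrangements of 1..max_len distinct elements of `items`.
# Returns a list of character vectors.
rank_combinations <- function(items = HOLC_GRADES, max_len = length(items)) {
  out <- list()
  recurse <- function(prefix, remaining) {
    for (g in remaining) {
      arr <- c(prefix, g)
      out[[length(out) + 1L]] <<- arr
      if (length(arr) < max_len) recurse(arr, setdiff(remaining, g))
    }
  }
  recurse(character(0), items)
  out
}

#' Generate synthetic tract coverage compositions
#'
#' Draws one `{A, B, C, D, U}` composition per tract. The set and order of
#' present grades is sampled first; their shares are a Dirichlet draw
#' sorted in decreasing order and assigned to the ordered grades, which
#' guarantees a strict rank order (no ties). The unrated share is drawn
#' independently and the rated shares renormalized; fully unrated tracts
#' are never emitted because the study universe is tracts with at least
#' some rated coverage.
#'
#' @param config A [sim_config()].
#' @return A coverage table (see [as_coverage()]).
#' @export
simulate_coverages <- function(config) {
  stopifnot(inherits(config, "holc_sim_config"))
  withr::with_seed(config$seed, simulate_coverages_impl(config))
}

simulate_coverages_impl <- function(config) {
  rows <- list()

  if (!is.null(config$forced)) {
    forced <- tibble::as_tibble(config$forced)
    for (g in ALL_GRADES) {
      if (!pct_col(g) %in% names(forced)) forced[[pct_col(g)]] <- 0
    }
    rows <- lapply(seq_len(nrow(forced)), function(i) {
      as.numeric(forced[i, pct_col(ALL_GRADES)])
    })
  }

  if (config$ensure_all_combinations) {
    combos <- rank_combinations(HOLC_GRADES, 4L)
    n_enforced <- 2L * length(combos)  # each combo with and without U
    n_free <- config$n_tracts - length(rows) - n_enforced
    if (n_free < 0) {
      stop("n_tracts too small to host all enforced rank combinations: ",
           "need ", n_enforced + length(rows), ", have ", config$n_tracts,
           " (deficit ", -n_free, ")", call. = FALSE)
    }
    for (combo in combos) {
      rows[[length(rows) + 1L]] <- compose_row(combo, u = 0)
      rows[[length(rows) + 1L]] <- compose_row(combo, u = runif(1, 5, 60))
    }
  } else {
    n_free <- config$n_tracts - length(rows)
    if (n_free < 0) {
      stop("n_tracts smaller than the number of forced rows (deficit ",
           -n_free, ")", call. = FALSE)
    }
  }

  for (i in seq_len(n_free)) {
    m <- sample(1:4, 1, prob = c(0.4, 0.3, 0.2, 0.1))
    combo <- sample(HOLC_GRADES, m)
    u <- if (runif(1) < 0.2) 0 else min(100 * rbeta(1, 1.5, 3), 99)
    rows[[length(rows) + 1L]] <- compose_row(combo, u = u)
  }

  p <- do.call(rbind, rows)
  out <- tibble::tibble(
    tract_id = sprintf("t%05d", seq_len(nrow(p))),
    pct_a = p[, 1], pct_b = p[, 2], pct_c = p[, 3], pct_d = p[, 4],
    pct_u = p[, 5]
  )
  as_coverage(out, tol = 1e-9)
}

# One composition row: `combo` grades get strictly decreasing shares of the
# rated mass (Dirichlet draw, sorted), unrated gets u percent.
compose_row <- function(combo, u) {
  shares <- sort(rgamma(length(combo), shape = 1), decreasing = TRUE)
  shares <- shares / sum(shares) * (100 - u)
  p <- setNames(numeric(5), ALL_GRADES)
  p[combo] <- shares
  p["U"] <- u
  # close the composition exactly; the residual (float dust) goes to the
  # largest rated share so a planted zero unrated share stays exactly zero
  p[combo[1]] <- p[combo[1]] + (100 - sum(p))
  unname(p)
}

#' Generate correlated synthetic tract outcomes
#'
#' Each outcome is `intercept + slope * L + shared signal + noise`, where
#' the latent gradient `L` is the rank-weighted mean of the rated grade
#' weights (see [latent_gradient()]): the grade covering the largest share
#' of the rated tract area contributes most, the second-largest less, and
#' so on, with rank weights renormalized over the grades present. A tract
#' covered only by grade g has `L = w_g` exactly. Unrated area does not
#' enter `L`: it behaves as missing at random. The shared signal (common
#' to all outcomes of a tract) makes the outcome battery intercorrelated
#' beyond what the gradient alone induces. Outcomes listed in
#' `sign_flips` are negated.
#'
#' @param coverages A coverage table.
#' @param config A [sim_config()].
#' @param slopes,intercepts Optional numeric vectors (length `n_outcomes`)
#'   of per-outcome gradient slopes and intercepts; default slope 1,
#'   intercept 0.
#' @return A tibble `tract_id, y1, ..., yK`.
#' @export
simulate_outcomes <- function(coverages, config, slopes = NULL,
                              intercepts = NULL) {
  stopifnot(inherits(config, "holc_sim_config"))
  coverages <- as_coverage(coverages)
  if (nrow(coverages) == 0) stop("empty coverage table", call. = FALSE)
  k <- config$n_outcomes
  if (is.null(slopes)) slopes <- rep(1, k)
  if (is.null(intercepts)) intercepts <- rep(0, k)
  stopifnot(length(slopes) == k, length(intercepts) == k)

  l <- latent_gradient(coverages, config$grade_weights,
                       config$rank_weights)
  n <- nrow(coverages)
  sd_shared <- config$noise_sd * sqrt(config$shared_signal_frac)
  sd_idio <- config$noise_sd * sqrt(1 - config$shared_signal_frac)

  y <- withr::with_seed(config$seed + 1L, {
    shared <- rnorm(n, 0, sd_shared)
    vapply(seq_len(k), function(j) {
      intercepts[j] + slopes[j] * l + shared + rnorm(n, 0, sd_idio)
    }, numeric(n))
  })
  if (n == 1) y <- matrix(y, nrow = 1)
  for (j in config$sign_flips) y[, j] <- -y[, j]
  colnames(y) <- paste0("y", seq_len(k))
  dplyr::bind_cols(tibble::tibble(tract_id = coverages$tract_id),
                   tibble::as_tibble(y))
}

#' Latent grade gradient of a coverage table
#'
#' The generator's structural signal: rated grades are ranked by their
#' share of the rated tract area (largest first, ties broken worst grade
#' first) and their weights combined with rank weights renormalized over
#' the grades present,
#' `L = sum_r rw_r * w(grade_r) / sum_r rw_r` over ranks `r` with
#' positive coverage. The composition therefore drives outcomes through
#' the rank order of its dominant grades rather than through fine-grained
#' area fractions, and the unrated share carries no signal.
#'
#' @param coverages A coverage table.
#' @param grade_weights Named weights for the rated grades.
#' @param rank_weights Weights for coverage ranks 1--4.
#' @return Numeric vector, one latent value per tract.
#' @export
latent_gradient <- function(coverages,
                            grade_weights = c(A = 1, B = 0.5, C = 0,
                                              D = -0.5),
                            rank_weights = c(0.6, 0.3, 0.1, 0)) {
  p <- as.matrix(coverages[, pct_col(HOLC_GRADES)])
  colnames(p) <- HOLC_GRADES
  w <- grade_weights[HOLC_GRADES]
  tie_rank <- match(HOLC_GRADES, TIE_ORDER)
  apply(p, 1, function(r) {
    pres <- which(r > 0)
    if (length(pres) == 0) return(NA_real_)
    ord <- pres[order(-r[pres], tie_rank[pres])]
    rw <- rank_weights[seq_along(ord)]
    if (sum(rw) == 0) rw <- rw + 1  # degenerate rank weights: plain mean
    sum(rw * w[ord]) / sum(rw)
  })
}

#' Rectangular polygon fixture with analytically known overlap areas
#'
#' Builds a small planar test bed of rectangular tracts and rectangular
#' graded HOLC areas whose pairwise intersection areas are exact rectangle
#' arithmetic. The default fixture contains a tract fully inside one grade,
#' a tract split across two grades, a partially unrated tract (40% D, 25%
#' B), a tract untouched by any graded area, and a tract whose interior
#' point falls in a grade that is not the largest-area grade.
#'
#' @param rects Optional data frame describing the fixture, with columns
#'   `id`, `layer` (`"tract"` or `"holc"`), `grade` (`NA` for tracts),
#'   `xmin`, `xmax`, `ymin`, `ymax`. Defaults to the standard fixture.
#' @return A list with `tracts` and `holc` polygon layers (see
#'   [polygon_layer()]) and `expected`, the analytic coverage table for the
#'   default fixture (`NULL` for custom `rects`).
#' @export
polygon_fixture <- function(rects = NULL) {
  default <- is.null(rects)
  if (default) rects <- default_fixture_rects()
  rects <- tibble::as_tibble(rects)
  stopifnot(all(c("id", "layer", "grade", "xmin", "xmax", "ymin", "ymax")
                %in% names(rects)))
  if (any(rects$xmax <= rects$xmin | rects$ymax <= rects$ymin)) {
    bad <- rects$id[rects$xmax <= rects$xmin | rects$ymax <= rects$ymin]
    stop("degenerate (zero-area) rectangle(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  geom <- lapply(seq_len(nrow(rects)), function(i) {
    rect_poly(rects$xmin[i], rects$xmax[i], rects$ymin[i], rects$ymax[i])
  })
  tr <- rects$layer == "tract"
  tracts <- polygon_layer(id = rects$id[tr], geometry = geom[tr])
  holc <- polygon_layer(id = rects$id[!tr], geometry = geom[!tr],
                        grade = rects$grade[!tr])
  expected <- if (default) default_fixture_expected() else NULL
  list(tracts = tracts, holc = holc, expected = expected)
}

default_fixture_rects <- function() {
  tibble::tribble(
    ~id,   ~layer,  ~grade, ~xmin, ~xmax, ~ymin, ~ymax,
    "t1",  "tract", NA,     0,     1,     0,     1,    # fully inside A
    "t2",  "tract", NA,     2,     3,     0,     1,    # left half B
    "t3",  "tract", NA,     4,     5,     0,     1,    # 40% D, 25% B
    "t4",  "tract", NA,     6,     7,     0,     1,    # untouched
    "t5",  "tract", NA,     8,     9,     0,     1,    # 47% B, 44% D, interior point in D
    "h1",  "holc",  "A",    -0.5,  1.5,   -0.5,  1.5,
    "h2",  "holc",  "B",    2,     2.5,   0,     1,
    "h3",  "holc",  "D",    4,     4.4,   0,     1,
    "h4",  "holc",  "B",    4.6,   4.85,  0,     1,
    "h5a", "holc",  "B",    8,     8.27,  0,     1,
    "h5b", "holc",  "B",    8.8,   9,     0,     1,
    "h6",  "holc",  "D",    8.36,  8.8,   0,     1
  )
}

default_fixture_expected <- function() {
  tibble::tribble(
    ~tract_id, ~pct_a, ~pct_b, ~pct_c, ~pct_d, ~pct_u,
    "t1",      100,    0,      0,      0,      0,
    "t2",      0,      50,     0,      0,      50,
    "t3",      0,      25,     0,      40,     35,
    "t4",      0,      0,      0,      0,      100,
    "t5",      0,      47,     0,      44,     9
  )
}
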