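# Fully crossed artificial grid of CV cells with additive planted effects.
planted_cells <- function(u_effect = 0.1, set_effects = rep(0, 6),
                          outcome_effects = c(0, 0),
                          outcomes = c("y1", "y2")) {
  g <- expand.grid(set_id = 1:6, n_ratings = 1:4,
                   include_unrated = c(FALSE, TRUE),
                   outcome_id = outcomes, threshold = c(1, 5, 10),
                   stringsAsFactors = FALSE)
  g$scheme_id <- sprintf("set%d_r%d_%s", g$set_id, g$n_ratings,
                         ifelse(g$include_unrated, "withU", "noU"))
  g$mse <- 0.8 + u_effect * g$include_unrated +
    set_effects[g$set_id] +
    outcome_effects[match(g$outcome_id, outcomes)]
  g$df <- g$n_ratings * 10L
  g$n_tracts <- 1000L
  tibble::as_tibble(g)
}

test_that("a planted unrated effect is recovered exactly", {
  rows <- meta_features(planted_cells(u_effect = 0.1))
  tab <- suppressWarnings(regress_mse_on_features(rows, "include_u"))
  est <- tab$estimate[tab$term == "include_uinclude"]
  expect_equal(est, 0.1, tolerance = 1e-10)
  expect_equal(attr(tab, "r_squared"), 1, tolerance = 1e-10)
})

test_that("one-at-a-time equals all-features on a balanced factorial", {
  cells <- planted_cells(u_effect = 0.07,
                         set_effects = c(0.05, 0.02, 0.02, 0.01, 0.004, 0),
                         outcome_effects = c(0, 0.03))
  rows <- meta_features(cells)
  tabs <- suppressWarnings(meta_regression_tables(rows))
  for (f in c("ratings_count", "set_cat", "include_u", "outcome_cat",
              "threshold_cat")) {
    uni <- tabs[[f]]
    multi <- tabs$all
    shared <- setdiff(uni$term, "(Intercept)")
    expect_equal(uni$estimate[match(shared, uni$term)],
                 multi$estimate[match(shared, multi$term)],
                 tolerance = 1e-8)
  }
})

test_that("the intercept-only meta-regression returns the mean MSE", {
  rows <- meta_features(planted_cells())
  tab <- regress_mse_on_features(rows, character(0))
  expect_equal(tab$estimate[tab$term == "(Intercept)"], mean(rows$mse))
})

test_that("single-level features are rejected by name", {
  cells <- planted_cells()
  cells <- cells[cells$outcome_id == "y1", ]
  rows <- meta_features(cells)
  expect_error(regress_mse_on_features(rows, "outcome_cat"), "outcome_cat")
})

test_that("stratified regressions isolate outcome-specific effects", {
  # same planted effect in both outcomes: stratified equals pooled
  cells <- planted_cells(u_effect = 0.05)
  strat <- suppressWarnings(stratified_regressions(cells))
  expect_length(strat, 2)
  pooled <- suppressWarnings(regress_mse_on_features(
    meta_features(cells), c("ratings_count", "set_cat", "include_u",
                            "threshold_cat")))
  for (tab in strat) {
    expect_equal(tab$estimate[tab$term == "include_uinclude"],
                 pooled$estimate[pooled$term == "include_uinclude"],
                 tolerance = 1e-8)
  }
  # effect planted only in outcome y1: stratified tables differ
  cells2 <- planted_cells(u_effect = 0)
  cells2$mse <- cells2$mse +
    0.2 * cells2$include_unrated * (cells2$outcome_id == "y1")
  strat2 <- suppressWarnings(stratified_regressions(cells2))
  e1 <- strat2$y1$estimate[strat2$y1$term == "include_uinclude"]
  e2 <- strat2$y2$estimate[strat2$y2$term == "include_uinclude"]
  expect_equal(e1, 0.2, tolerance = 1e-8)
  expect_equal(e2, 0, tolerance = 1e-8)
})

test_that("meta-regression residuals are orthogonal to the design", {
  cells <- planted_cells(u_effect = 0.03)
  cells$mse <- cells$mse + rep_len(c(0.01, -0.01, 0.005), nrow(cells))
  rows <- meta_features(cells)
  tab <- suppressWarnings(regress_mse_on_features(rows, "all"))
  fit <- attr(tab, "fit")
  mm <- stats::model.matrix(fit)
  expect_lt(max(abs(crossprod(mm, fit$residuals))), 1e-8)
})

test_that("scheme summaries match an independent group-by oracle", {
  d <- gradient_data(n = 300, seed = 14, n_outcomes = 2)
  g <- run_grid(d$coverages, d$outcomes,
                schemes = enumerate_schemes()[c(4, 22, 40), ],
                thresholds = c(1, 10), seed = 14)
  s <- summarize_schemes(g)
  expect_equal(unique(s$n_cells), 4L)
  for (i in seq_len(nrow(s))) {
    cells <- g[g$scheme_id == s$scheme_id[i], ]
    expect_equal(s$mean_mse[i], sum(cells$mse) / length(cells$mse))
    expect_equal(s$median_mse[i], median(cells$mse))
    expect_equal(s$median_df[i], median(cells$df))
  }
  # single-cell grid: summary equals the cell
  g1 <- g[1, ]
  s1 <- summarize_schemes(g1)
  expect_equal(s1$mean_mse, g1$mse)
  expect_equal(s1$median_df, as.numeric(g1$df))
})

test_that("selection rules: argmin, tie-breaks and tolerance band", {
  summaries <- tibble::tibble(
    scheme_id = c("s_big", "s_small", "s_worse"),
    set_id = 6L, n_ratings = 2L, include_unrated = FALSE,
    mean_mse = c(0.5, 0.5, 0.9),
    median_mse = c(0.5, 0.5, 0.9),
    median_df = c(39, 15, 3), n_cells = 42L)
  # equal mse: fewer df wins both selections
  expect_equal(select_optimal(summaries), "s_small")
  expect_equal(select_parsimonious(summaries, tolerance = 0), "s_small")
  # dominated scheme never selected
  expect_false(select_optimal(summaries) == "s_worse")
  # widening the band admits cheaper schemes
  summaries2 <- tibble::tibble(
    scheme_id = c("opt", "near"), set_id = 6L, n_ratings = 2:3,
    include_unrated = FALSE, mean_mse = c(0.500, 0.502),
    median_mse = c(0.500, 0.502), median_df = c(39, 15), n_cells = 42L)
  expect_equal(select_optimal(summaries2), "opt")
  expect_equal(select_parsimonious(summaries2, tolerance = 0.005), "near")
  expect_equal(select_parsimonious(summaries2, tolerance = 0), "opt")
})

test_that("the MSE-vs-df plot is a valid ggplot with highlights", {
  summaries <- summarize_schemes(run_grid(
    gradient_data(n = 300, seed = 15, n_outcomes = 2)$coverages,
    gradient_data(n = 300, seed = 15, n_outcomes = 2)$outcomes,
    schemes = enumerate_schemes()[c(1, 10, 40), ],
    thresholds = 5, seed = 15))
  p <- plot_mse_vs_df(summaries)
  expect_s3_class(p, "ggplot")
})
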