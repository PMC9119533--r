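test_that("predictor construction matches the stated designs", {
  cov <- rbind(cov_row(a = 100, id = "tA"),
               cov_row(b = 40, d = 40, u = 20, id = "tBD"))
  props <- build_predictors(cov, "proportions")
  expect_equal(unlist(props[1, c("prop_b", "prop_c", "prop_d")]),
               c(prop_b = 0, prop_c = 0, prop_d = 0))
  expect_equal(unlist(props[2, c("prop_b", "prop_c", "prop_d")]),
               c(prop_b = 0.5, prop_c = 0, prop_d = 0.5))
  expect_equal(build_predictors(cov, "one_rating")$class, c("A", "D"))
  expect_equal(build_predictors(cov, "detailed16")$class, c("A", "D-B"))
  expect_equal(build_predictors(cov, "collapsed10")$class,
               c("Only or mainly A", "Mainly C or D, some B"))
  expect_error(build_predictors(cov, "centroid"), "centroid")
  cg <- tibble::tibble(tract_id = c("tA", "tBD"), grade = c("A", NA))
  expect_equal(build_predictors(cov, "centroid", centroid = cg)$class,
               c("A", NA))
})

test_that("each approach consumes its stated degrees of freedom", {
  cov <- simulate_coverages(sim_config(n_tracts = 300, seed = 25))
  cfg <- sim_config(n_tracts = 300, seed = 25)
  y <- simulate_outcomes(cov, cfg)
  tab <- r2_table(cov, y[, c("tract_id", "y1")], min_rated_pct = 5)
  dfs <- setNames(tab$cells$df, tab$cells$kind)
  expect_equal(dfs[["proportions"]], 3)
  expect_equal(dfs[["one_rating"]], 3)
  expect_equal(dfs[["collapsed10"]], 9)
  expect_equal(dfs[["detailed16"]], 15)
  expect_equal(dfs[["optimal40"]], 39)
})

test_that("R-squared is monotone over nested classifications", {
  for (seed in c(31, 32, 33)) {
    d <- gradient_data(n = 800, seed = seed, n_outcomes = 2)
    tab <- r2_table(d$coverages, d$outcomes[, c("tract_id", "y1")],
                    kinds = c("one_rating", "collapsed10", "detailed16",
                              "optimal40"))
    r2 <- setNames(tab$cells$r_squared, tab$cells$kind)
    expect_gte(r2[["detailed16"]], r2[["collapsed10"]] - 1e-12)
    expect_gte(r2[["collapsed10"]], r2[["one_rating"]] - 1e-12)
    expect_gte(r2[["optimal40"]], r2[["detailed16"]] - 1e-12)
  }
})

test_that("a class-mean outcome is fit perfectly; pure noise is not fit at all", {
  cov <- simulate_coverages(sim_config(n_tracts = 400, seed = 35))
  cov5 <- filter_by_threshold(cov, 5)
  det <- assign_labels(cov5, scheme(6, 2, FALSE))
  mu <- setNames(seq_along(unique(det)), unique(det))
  y_perfect <- tibble::tibble(tract_id = cov5$tract_id,
                              y1 = unname(mu[det]))
  tab <- suppressWarnings(r2_table(cov5, y_perfect, kinds = "detailed16",
                                  min_rated_pct = 5))
  expect_equal(tab$cells$r_squared, 1, tolerance = 1e-12)

  set.seed(36)
  big <- simulate_coverages(sim_config(n_tracts = 10000, seed = 36))
  y_noise <- tibble::tibble(tract_id = big$tract_id, y1 = rnorm(10000))
  tab2 <- r2_table(big, y_noise, min_rated_pct = 5)
  expect_true(all(tab2$cells$r_squared < 0.01))
})

test_that("group averages summarize the R-squared cells", {
  d <- gradient_data(n = 500, seed = 37, n_outcomes = 4)
  tab <- r2_table(d$coverages, d$outcomes,
                  kinds = c("one_rating", "detailed16"),
                  outcome_groups = list(health = c("y1", "y2"),
                                        economic = c("y3", "y4")))
  expect_equal(nrow(tab$averages), 4)
  cell_avg <- mean(tab$cells$r_squared[
    tab$cells$kind == "detailed16" & tab$cells$outcome_id %in%
      c("y1", "y2")])
  got <- tab$averages$mean_r_squared[
    tab$averages$kind == "detailed16" & tab$averages$group == "health"]
  expect_equal(got, cell_avg)
})

test_that("coefficients are class-mean differences from the reference", {
  set.seed(41)
  lab <- sample(c("Only or mainly A", "Only B", "Only D"), 200,
                replace = TRUE)
  y <- rnorm(200) + c("Only or mainly A" = 1, "Only B" = 0.4,
                      "Only D" = -0.6)[lab]
  tab <- coefficient_table(lab, y, "Only or mainly A")
  means <- tapply(y, lab, mean)
  expect_equal(tab$estimate[tab$term == "(Intercept)"],
               unname(means["Only or mainly A"]), tolerance = 1e-8)
  expect_equal(tab$estimate[tab$term == "Only B"],
               unname(means["Only B"] - means["Only or mainly A"]),
               tolerance = 1e-8)
  expect_equal(tab$estimate[tab$term == "Only D"],
               unname(means["Only D"] - means["Only or mainly A"]),
               tolerance = 1e-8)
  expect_error(coefficient_table(lab, y, "Only C"), "not present")
})

test_that("one-rating coefficients decline monotonically with grade", {
  d <- gradient_data(n = 2000, seed = 43)
  cov5 <- filter_by_threshold(d$coverages, 5)
  one <- build_predictors(cov5, "one_rating")$class
  y <- standardize(d$outcomes$y1[match(cov5$tract_id,
                                       d$outcomes$tract_id)])
  tab <- coefficient_table(one, y, "A")
  est <- setNames(tab$estimate, tab$term)
  expect_lt(est[["B"]], 0)
  expect_lt(est[["C"]], est[["B"]])
  expect_lt(est[["D"]], est[["C"]])
})

test_that("the performance ratio reports unrounded and integer percent", {
  r <- performance_ratio(8.3, 9.2)
  expect_equal(r$percent_rounded, 90)
  expect_equal(r$percent, 100 * 8.3 / 9.2)
  expect_equal(performance_ratio(4, 4)$percent, 100)
  expect_equal(performance_ratio(0, 4)$percent, 0)
  expect_error(performance_ratio(1, 0), "positive")
})
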