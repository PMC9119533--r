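test_that("exactly 54 schemes are enumerated, with the right structure", {
  s <- enumerate_schemes()
  expect_equal(nrow(s), 54)
  expect_equal(anyDuplicated(s$scheme_id), 0)
  # no five-rating scheme without the unrated pseudo-grade
  expect_equal(sum(!s$include_unrated & s$n_ratings == 5), 0)
  expect_equal(sum(!s$include_unrated), 24)
  expect_equal(sum(s$include_unrated), 30)
  per_set <- table(s$set_id)
  expect_true(all(per_set == 9))
  expect_error(scheme(6, 5, FALSE), "four ratings")
})

test_that("rebasing rescales to the rated-area denominator", {
  expect_equal(rebase_excluding_unrated(cov_row(a = 50, u = 50))$pct_a, 100)
  re <- rebase_excluding_unrated(cov_row(b = 30, d = 30, u = 40))
  expect_equal(c(re$pct_b, re$pct_d, re$pct_u), c(50, 50, 0))
  re2 <- rebase_excluding_unrated(
    cov_row(a = 10, b = 20, c = 30, d = 20, u = 20))
  expect_equal(c(re2$pct_a, re2$pct_b, re2$pct_c, re2$pct_d),
               c(12.5, 25, 37.5, 25))
  expect_error(rebase_excluding_unrated(cov_row(u = 100)),
               "fully unrated")
})

test_that("percentage bins follow the set definitions", {
  expect_equal(bin_percentage(75, 1), 8)
  expect_equal(bin_percentage(100, 5), 2)   # top bin closed at 100
  expect_equal(bin_percentage(33.3, 4), 2)  # boundary joins the upper bin
  expect_equal(bin_percentage(0, 1), 1)
  expect_equal(bin_percentage(c(9.99, 10), 1), c(1, 2))  # half-open bins
  # bin counts per set: 10, 5, 4, 3, 2
  expect_equal(vapply(1:5, function(s) bin_percentage(100, s), numeric(1)),
               c(10, 5, 4, 3, 2))
  expect_error(bin_percentage(101, 1), "outside")
})

test_that("labels are assigned by coverage order with bins where required", {
  expect_equal(assign_labels(cov_row(a = 100), scheme(6, 2, FALSE)), "A")
  # mainly D, some B (rebased shares ~81.6 / 18.4)
  d_b <- cov_row(b = 19 / 103 * 100, d = 84 / 103 * 100, u = 0)
  expect_equal(assign_labels(d_b, scheme(6, 2, FALSE)), "D-B")
  # U covers the most area and is a first-class grade when included
  expect_equal(assign_labels(cov_row(c = 47, u = 53), scheme(6, 2, TRUE)),
               "U-C")
  expect_equal(assign_labels(cov_row(a = 75, b = 25), scheme(1, 2, FALSE)),
               "A8-B3")
  # zero-coverage grades never appear; short labels when few grades present
  expect_equal(assign_labels(cov_row(b = 60, c = 40), scheme(6, 4, FALSE)),
               "B-C")
  # 0-based rendering option
  expect_equal(assign_labels(cov_row(a = 75, b = 25), scheme(1, 2, FALSE),
                             bin_base = 0), "A7-B2")
  expect_error(assign_labels(cov_row(u = 100), scheme(6, 2, TRUE)),
               "no positive rated")
})

test_that("feasible label counts match the brute-force arrangement oracle", {
  counts <- vapply(1:4, function(r) {
    length(enumerate_feasible_labels(scheme(6, r, FALSE)))
  }, numeric(1))
  expect_equal(counts, c(4, 16, 40, 64))
  oracle <- vapply(1:4, function(m) {
    length(oracle_arrangements(c("A", "B", "C", "D"), m))
  }, numeric(1))
  expect_equal(counts, oracle)
  expect_setequal(enumerate_feasible_labels(scheme(6, 2, FALSE)),
                  oracle_arrangements(c("A", "B", "C", "D"), 2))
  # with U: the all-U label exists only for single-rating schemes
  expect_length(enumerate_feasible_labels(scheme(6, 1, TRUE)), 5)
  expect_length(enumerate_feasible_labels(scheme(6, 2, TRUE)), 24)
  expect_length(enumerate_feasible_labels(scheme(6, 3, TRUE)), 84)
  expect_false("U" %in% enumerate_feasible_labels(scheme(6, 2, TRUE)))
  # binned feasibility: an untruncated label must close to 100 exactly
  s5 <- enumerate_feasible_labels(scheme(5, 3, FALSE))
  expect_false("A1-B1" %in% s5)  # both below 50 cannot sum to 100 alone
  expect_true("A2-B1" %in% s5)   # e.g. 75 + 25
  # under truncation a third, unlisted grade can absorb the remainder
  expect_true("A1-B1" %in% enumerate_feasible_labels(scheme(5, 2, FALSE)))
})

test_that("every assigned label is feasible (closure property)", {
  cov <- simulate_coverages(sim_config(n_tracts = 300, seed = 8))
  for (sc in list(scheme(6, 2, FALSE), scheme(6, 3, FALSE),
                  scheme(6, 2, TRUE), scheme(1, 2, FALSE),
                  scheme(4, 2, FALSE), scheme(5, 3, TRUE),
                  scheme(2, 1, TRUE))) {
    lab <- assign_labels(cov, sc)
    feas <- enumerate_feasible_labels(sc)
    expect_true(all(lab %in% feas),
                label = paste("labels feasible for", sc$scheme_id))
  }
})

test_that("truncating the rating count only coarsens labels", {
  cov <- simulate_coverages(sim_config(n_tracts = 300, seed = 9))
  for (set_id in c(1, 6)) {
    for (k in 1:3) {
      fine <- assign_labels(cov, scheme(set_id, k + 1, FALSE))
      coarse <- assign_labels(cov, scheme(set_id, k, FALSE))
      groups <- split(coarse, fine)
      expect_true(all(vapply(groups, function(g) {
        length(unique(g)) == 1
      }, logical(1))))
    }
  }
})

test_that("label assignment is deterministic and total on valid coverages", {
  cov <- simulate_coverages(sim_config(n_tracts = 200, seed = 10))
  sc <- scheme(3, 2, TRUE)
  l1 <- assign_labels(cov, sc)
  expect_identical(l1, assign_labels(cov, sc))
  expect_false(anyNA(l1))
  expect_equal(length(l1), nrow(cov))
})
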