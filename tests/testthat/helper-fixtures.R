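# Shared fixtures, built in code at test time.

# A single-row coverage table.
cov_row <- function(a = 0, b = 0, c = 0, d = 0, u = NULL, id = "t1") {
  if (is.null(u)) u <- 100 - (a + b + c + d)
  tibble::tibble(tract_id = id, pct_a = a, pct_b = b, pct_c = c,
                 pct_d = d, pct_u = u)
}

# Synthetic gradient universe: coverages plus correlated outcomes.
gradient_data <- function(n = 1500, seed = 1, ...) {
  cfg <- sim_config(n_tracts = n, seed = seed, ...)
  cov <- simulate_coverages(cfg)
  list(config = cfg, coverages = cov,
       outcomes = simulate_outcomes(cov, cfg))
}

# Independent brute-force enumeration of ordered arrangements of up to
# max_len distinct grades, used as the oracle for rank-combination counts.
oracle_arrangements <- function(grades, max_len) {
  out <- character(0)
  for (m in seq_len(max_len)) {
    idx <- seq_along(grades)
    perm_rows <- function(prefix, rest) {
      if (length(prefix) == m) {
        out <<- c(out, paste(grades[prefix], collapse = "-"))
        return()
      }
      for (i in rest) perm_rows(c(prefix, i), setdiff(rest, i))
    }
    perm_rows(integer(0), idx)
  }
  out
}
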