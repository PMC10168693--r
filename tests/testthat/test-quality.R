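flags <- function(v) stats::setNames(as.list(v), quality_flag_cols)

test_that("total_score sums the five flags and validates them", {
  expect_equal(total_score(flags(c(0, 0, 0, 0, 0))), 0L)
  expect_equal(total_score(flags(c(1, 1, 1, 1, 1))), 5L)
  expect_equal(total_score(flags(c(1, 0, 1, 1, 0))), 3L)
  df <- as.data.frame(rbind(c(1, 0, 1, 1, 0), c(1, 1, 1, 1, 1)))
  names(df) <- quality_flag_cols
  expect_equal(total_score(df), c(3L, 5L))
  expect_error(total_score(flags(c(1, 0, 1, 1, 2))), "0 or 1")
  expect_error(total_score(list(randomized = 1)), "missing quality flag")
})

test_that("mann_whitney matches the exact enumeration example and handles ties", {
  sep <- mann_whitney(c(3, 4, 5), c(1, 2))
  expect_equal(sep$u, 6) # n_a * n_b, complete separation
  expect_equal(sep$p_value, 0.2)
  expect_true(sep$exact)

  tied <- mann_whitney(c(1, 1), c(1, 1))
  expect_equal(tied$u, 2) # n_a * n_b / 2 under complete ties
  expect_false(tied$exact)

  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("mann_whitney agrees with full permutation enumeration for small tie-free inputs", {
  cases <- withr::with_seed(31, lapply(1:30, function(i) {
    n_a <- sample(2:5, 1)
    n_b <- sample(2:5, 1)
    vals <- sample(1:100, n_a + n_b) # distinct -> tie-free
    list(a = vals[seq_len(n_a)], b = vals[-seq_len(n_a)])
  }))
  for (cs in cases) {
    got <- mann_whitney(cs$a, cs$b)
    want <- oracle_mann_whitney(cs$a, cs$b)
    expect_equal(got$u, want$u)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("mann_whitney invariances: group swap, U complement, shift", {
  cases <- withr::with_seed(13, lapply(1:20, function(i) {
    list(a = sample(0:5, sample(3:8, 1), replace = TRUE),
         b = sample(0:5, sample(3:8, 1), replace = TRUE))
  }))
  for (cs in cases) {
    ab <- mann_whitney(cs$a, cs$b)
    ba <- mann_whitney(cs$b, cs$a)
    expect_equal(ab$u + ba$u, length(cs$a) * length(cs$b))
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
    shifted <- mann_whitney(cs$a + 7, cs$b + 7)
    expect_equal(shifted$u, ab$u)
    expect_equal(shifted$p_value, ab$p_value, tolerance = 1e-12)
  }
})

test_that("proportion_at_least covers the corner and published cases", {
  expect_equal(proportion_at_least(c(3, 3, 3)), 1)
  expect_equal(proportion_at_least(c(0, 1, 2)), 0)
  # 11 of 16 multilab studies scored >= 3
  scores <- c(rep(3, 7), rep(4, 3), 5, rep(2, 3), 1, 1)
  expect_equal(proportion_at_least(scores), 11 / 16)
  expect_equal(round(100 * proportion_at_least(scores)), 69)
  expect_error(proportion_at_least(numeric(0)), "no scores")
  expect_error(proportion_at_least(c(3, 7)), "0-5")
})

test_that("compare_quality summarizes designs and runs the U test", {
  studies <- withr::with_seed(4, {
    n_m <- 16
    n_s <- 100
    df <- data.frame(design = rep(c("multilab", "single"), c(n_m, n_s)))
    probs <- list(multilab = c(0.94, 0.19, 0.69, 0.75, 0.38),
                  single = c(0.57, 0.07, 0.24, 0.53, 0.38))
    for (i in seq_along(quality_flag_cols)) {
      df[[quality_flag_cols[i]]] <- c(rbinom(n_m, 1, probs$multilab[i]),
                                      rbinom(n_s, 1, probs$single[i]))
    }
    df
  })
  q <- compare_quality(studies)
  expect_equal(sort(unique(c(q$scores_multi, q$scores_single))),
               intersect(0:5, c(q$scores_multi, q$scores_single)))
  expect_gte(q$median_multi, q$range_multi[1])
  expect_lte(q$median_multi, q$range_multi[2])
  expect_lte(q$u_statistic, length(q$scores_multi) * length(q$scores_single))
  expect_gt(q$p_value, 0)
  expect_lte(q$p_value, 1)
  expect_equal(dim(q$practice_pct), c(5L, 3L))
  expect_error(compare_quality(data.frame(design = "multilab",
                                          randomized = 1, rand_method_lowrob = 1,
                                          blind_personnel = 1, blind_assessor = 1,
                                          complete_data = 1)),
               "each design")
})
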