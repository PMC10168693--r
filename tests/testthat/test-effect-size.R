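test_that("pooled_sd matches direct formula evaluation and guards its domain", {
  expect_equal(pooled_sd(1, 10, 1, 10), 1)
  expect_equal(pooled_sd(0, 5, 0, 5), 0)
  expect_equal(pooled_sd(2, 3, 1, 5), sqrt((2 * 4 + 4 * 1) / 6)) # sqrt(2)
  expect_error(pooled_sd(1, 1, 1, 5), "degrees of freedom")
  expect_error(pooled_sd(-1, 5, 1, 5), "nonnegative")
})

test_that("smd reproduces hand-evaluated d and g with their variances", {
  t_arm <- arm_summary(1, 1, 100)
  c_arm <- arm_summary(0, 1, 100)
  d <- smd(t_arm, c_arm, metric = "d")
  expect_equal(d$point, 1)
  expect_equal(d$variance, 200 / (100 * 100) + 1 / (2 * 200))
  g <- smd(t_arm, c_arm, metric = "g")
  j <- 1 - 3 / (4 * 198 - 1)
  expect_equal(g$point, j, tolerance = 1e-10)
  expect_equal(g$point, 0.99621, tolerance = 1e-5)
  expect_equal(g$variance, j^2 * d$variance)
  expect_equal(g$se, sqrt(g$variance))
  expect_equal(g$ci_low, g$point - 1.96 * g$se)

  # null effect and antisymmetry
  expect_equal(smd(arm_summary(2, 1.5, 8), arm_summary(2, 1.5, 8))$point, 0)
  fwd <- smd(arm_summary(3, 2, 9), arm_summary(1, 1, 14))
  rev <- smd(arm_summary(1, 1, 14), arm_summary(3, 2, 9))
  expect_equal(fwd$point, -rev$point)
  expect_equal(fwd$variance, rev$variance)
})

test_that("smd agrees with metafor's escalc for Cohen's d", {
  cases <- withr::with_seed(42, lapply(1:25, function(i) {
    list(m1 = rnorm(1), sd1 = runif(1, 0.5, 3), n1 = sample(4:60, 1),
         m2 = rnorm(1), sd2 = runif(1, 0.5, 3), n2 = sample(4:60, 1))
  }))
  for (cs in cases) {
    mine <- smd(arm_summary(cs$m1, cs$sd1, cs$n1),
                arm_summary(cs$m2, cs$sd2, cs$n2), metric = "d")
    ref <- metafor::escalc(measure = "SMD", m1i = cs$m1, sd1i = cs$sd1,
                           n1i = cs$n1, m2i = cs$m2, sd2i = cs$sd2,
                           n2i = cs$n2, correct = FALSE)
    expect_equal(mine$point, as.numeric(ref$yi), tolerance = 1e-10)
    expect_equal(mine$variance, as.numeric(ref$vi), tolerance = 1e-10)
  }
})

test_that("SE dispersions are converted with SE * sqrt(n)", {
  via_se <- smd(arm_summary(1, 0.2, 25, "SE"), arm_summary(0, 1, 25))
  via_sd <- smd(arm_summary(1, 1, 25), arm_summary(0, 1, 25))
  expect_equal(via_se$point, via_sd$point)
  expect_equal(via_se$variance, via_sd$variance)
})

test_that("degenerate dispersion is an error for unequal means, flagged zero otherwise", {
  expect_error(smd(arm_summary(1, 0, 5), arm_summary(0, 0, 5)), "undefined SMD")
  flat <- smd(arm_summary(1, 0, 5), arm_summary(1, 0, 5))
  expect_equal(flat$point, 0)
  expect_true(flat$degenerate)
  expect_true(is.na(flat$variance))
})

test_that("smd invariants hold: |g| <= |d|, variance monotone in n, scale invariance", {
  cases <- withr::with_seed(7, lapply(1:50, function(i) {
    list(m1 = rnorm(1, 0, 2), sd1 = runif(1, 0.3, 2), n1 = sample(3:40, 1),
         m2 = rnorm(1, 0, 2), sd2 = runif(1, 0.3, 2), n2 = sample(3:40, 1),
         c = runif(1, 0.1, 10))
  }))
  for (cs in cases) {
    d <- smd(arm_summary(cs$m1, cs$sd1, cs$n1), arm_summary(cs$m2, cs$sd2, cs$n2),
             metric = "d")
    g <- smd(arm_summary(cs$m1, cs$sd1, cs$n1), arm_summary(cs$m2, cs$sd2, cs$n2),
             metric = "g")
    expect_lte(abs(g$point), abs(d$point))
    bigger_n <- smd(arm_summary(cs$m1, cs$sd1, cs$n1 + 20),
                    arm_summary(cs$m2, cs$sd2, cs$n2 + 20), metric = "d")
    if (abs(bigger_n$point - d$point) < 1e-12) {
      expect_lt(bigger_n$variance, d$variance)
    }
    scaled <- smd(arm_summary(cs$c * cs$m1, cs$c * cs$sd1, cs$n1),
                  arm_summary(cs$c * cs$m2, cs$c * cs$sd2, cs$n2), metric = "d")
    expect_equal(scaled$point, d$point, tolerance = 1e-12)
    expect_equal(scaled$variance, d$variance, tolerance = 1e-12)
  }
})

test_that("orient flips lower-is-better effects onto the benefit-positive scale", {
  e <- smd(arm_summary(-0.5, 1, 30), arm_summary(0, 1, 30), metric = "d")
  flipped <- orient(e, "lower_is_better")
  expect_equal(flipped$point, -e$point)
  expect_equal(flipped$ci_low, -e$ci_high)
  expect_equal(flipped$ci_high, -e$ci_low)
  expect_equal(flipped$variance, e$variance)
  expect_equal(orient(e, "higher_is_better"), e)
  expect_equal(orient(orient(e, "lower_is_better"), "lower_is_better"), e)
})
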