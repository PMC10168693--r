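pe <- function(point, se) {
  # minimal pooled estimate for contrast arithmetic
  random_pool(point, se^2)
}

test_that("dsmd matches the hand-evaluated contrast and is antisymmetric", {
  r <- dsmd(pe(1.0, 0.2), pe(0.3, 0.3), "cmp")
  expect_equal(r$dsmd, 0.7)
  expect_equal(r$se, sqrt(0.13), tolerance = 1e-10) # ~0.36056
  expect_equal(r$ci_low, 0.7 - 1.96 * sqrt(0.13), tolerance = 1e-6) # ~ -0.0067
  expect_equal(r$ci_high, 0.7 + 1.96 * sqrt(0.13), tolerance = 1e-6) # ~ 1.4067

  expect_equal(dsmd(pe(0.4, 0.1), pe(0.4, 0.2))$dsmd, 0)

  fwd <- dsmd(pe(0.9, 0.15), pe(0.2, 0.25))
  rev <- dsmd(pe(0.2, 0.25), pe(0.9, 0.15))
  expect_equal(fwd$dsmd, -rev$dsmd)
  expect_equal(fwd$se, rev$se)

  expect_error(dsmd(NULL, pe(0.2, 0.1), "C9"), "C9")
})

test_that("esr is the ratio of pooled points with degenerate flagging", {
  expect_equal(esr(pe(0.4, 0.1), pe(0.4, 0.1))$esr, 1)
  expect_equal(esr(pe(0.8, 0.1), pe(0.2, 0.1))$esr, 4)
  expect_warning(esr(pe(0.5, 0.1), pe(0, 0.1), "Cz"), "degenerate")
  deg <- suppressWarnings(esr(pe(0.5, 0.1), pe(0, 0.1), "Cz"))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$esr))

  # antisymmetry on the ratio scale: swapping designs inverts the ESR
  fwd <- esr(pe(0.9, 0.1), pe(0.3, 0.1))
  rev <- esr(pe(0.3, 0.1), pe(0.9, 0.1))
  expect_equal(fwd$esr, 1 / rev$esr)
})

test_that("median_esr excludes degenerate ratios and direction counts are strict", {
  results <- list(esr(pe(0.8, 0.1), pe(0.2, 0.1), "a"),
                  esr(pe(0.3, 0.1), pe(0.6, 0.1), "b"),
                  suppressWarnings(esr(pe(0.5, 0.1), pe(0, 0.1), "c")))
  m <- suppressMessages(median_esr(results))
  expect_equal(m$n_used, 2)
  expect_equal(m$median, stats::median(c(4, 0.5)))
  expect_gte(m$median, m$range[1])
  expect_lte(m$median, m$range[2])

  dn <- direction_count(list(dsmd(pe(1, .1), pe(.5, .1)),
                             dsmd(pe(.5, .1), pe(1, .1)),
                             dsmd(pe(.5, .1), pe(.5, .1))))
  expect_equal(dn$n_positive, 1)
  expect_equal(dn$n_ties, 1)
  all_neg <- direction_count(list(dsmd(pe(0.4, .1), pe(0.5, .1)),
                                  dsmd(pe(0.1, .1), pe(0.2, .1))))
  expect_equal(all_neg$n_positive, 0)
})

test_that("CI non-overlap counts disjoint intervals only", {
  # multilab CI (0,1) vs single CI (2,3): disjoint
  disjoint <- dsmd(pe(2.5, (3 - 2) / (2 * 1.96)), pe(0.5, (1 - 0) / (2 * 1.96)))
  # multilab CI (0,2) vs single CI (1,3): overlapping
  overlap <- dsmd(pe(2, (3 - 1) / (2 * 1.96)), pe(1, (2 - 0) / (2 * 1.96)))
  # nested intervals intersect, so they do not count
  nested <- dsmd(pe(1, 2), pe(1, 0.1))
  expect_equal(ci_nonoverlap_count(list(disjoint)), 1)
  expect_equal(ci_nonoverlap_count(list(overlap)), 0)
  expect_equal(ci_nonoverlap_count(list(nested)), 0)
  expect_equal(ci_nonoverlap_count(list(disjoint, overlap, nested)), 1)
})

test_that("pool_dsmd shares the random-effects code path and supports equal weights", {
  results <- list(dsmd(pe(1.0, 0.2), pe(0.3, 0.3), "a"),
                  dsmd(pe(0.8, 0.25), pe(0.5, 0.2), "b"),
                  dsmd(pe(1.4, 0.3), pe(0.2, 0.15), "c"))
  yi <- vapply(results, `[[`, numeric(1), "dsmd")
  vi <- vapply(results, `[[`, numeric(1), "se")^2
  pooled <- pool_dsmd(results)
  direct <- random_pool(yi, vi)
  expect_equal(pooled$point, direct$point)
  expect_equal(pooled$se, direct$se)
  expect_equal(pooled$tau2, direct$tau2)

  one <- pool_dsmd(results[1])
  expect_equal(one$point, results[[1]]$dsmd)
  expect_equal(one$se, results[[1]]$se)

  eq <- pool_dsmd(results, weights = "equal")
  expect_equal(eq$point, mean(yi))
  expect_equal(eq$se, sqrt(mean(vi) / 3))

  expect_error(pool_dsmd(list()), "no DSMD")
})

test_that("sign(dsmd) matches sign(log esr) for positive pooled points", {
  cases <- withr::with_seed(9, lapply(1:40, function(i) {
    list(s = runif(1, 0.05, 2), m = runif(1, 0.05, 2))
  }))
  for (cs in cases) {
    d <- dsmd(pe(cs$s, 0.1), pe(cs$m, 0.1))
    r <- esr(pe(cs$s, 0.1), pe(cs$m, 0.1))
    expect_equal(sign(d$dsmd), sign(log(r$esr)))
  }
})

test_that("design_contrast composes the stages on a handcrafted corpus", {
  studies <- toy_corpus()
  rep <- design_contrast(studies)
  expect_equal(rep$n_comparisons, 2)
  expect_s3_class(rep$pooled_dsmd, "pooled_estimate")

  # comparison A recomputed by hand through the package primitives
  eff <- study_effects(studies)
  a <- eff[eff$comparison_id == "A", ]
  d_single <- random_pool(a[a$design == "single", ])
  d_multi <- random_pool(a[a$design == "multilab", ])
  expect_equal(rep$per_comparison$dsmd[rep$per_comparison$comparison_id == "A"],
               d_single$point - d_multi$point)
  expect_equal(rep$per_comparison$esr[rep$per_comparison$comparison_id == "A"],
               d_single$point / d_multi$point)
  # oriented lower-is-better comparison still lands benefit-positive
  expect_true(all(rep$per_comparison$es_single > 0))
  expect_true(all(rep$per_comparison$es_multi > 0))
  expect_true(all(rep$per_comparison$dsmd > 0)) # small singles exceed multilab here
})

test_that("relabeling designs negates every dsmd and inverts every esr", {
  studies <- toy_corpus()
  swapped <- studies
  swapped$design[studies$design == "multilab"] <- "single"
  swapped$design[studies$design == "single"] <- "multilab"
  # swapped corpora have several 'multilab' studies per comparison, so build
  # the contrasts directly from pooled effects instead of design_contrast()
  eff <- study_effects(studies)
  for (cid in unique(eff$comparison_id)) {
    e <- eff[eff$comparison_id == cid, ]
    a <- random_pool(e[e$design == "single", ])
    b <- random_pool(e[e$design == "multilab", ])
    expect_equal(dsmd(a, b)$dsmd, -dsmd(b, a)$dsmd)
    expect_equal(esr(a, b)$esr, 1 / esr(b, a)$esr)
  }
})
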