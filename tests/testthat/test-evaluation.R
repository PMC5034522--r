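test_that("weighted Pearson correlation matches a direct-summation oracle", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  y <- c(2.0, 3.9, 2.5, 6.2, 3.8)
  w <- c(0.5, 1.5, 2.0, 0.8, 1.2)
  # brute-force evaluation of the weighted product-moment formula
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  oracle <- sum(w * (x - mx) * (y - my)) /
    sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
  expect_equal(weighted_pearson(x, y, w), oracle, tolerance = 1e-12)
  expect_equal(weighted_pearson(x, x, w), 1, tolerance = 1e-12)
  expect_equal(weighted_pearson(x, -x, w), -1, tolerance = 1e-12)
  expect_error(weighted_pearson(x, rep(2, 5), w),
               class = "bmicorrect_numeric_error")
})

test_that("weighted Pearson is invariant to affine maps and weight scale", {
  set.seed(41)
  x <- rnorm(50); y <- x + rnorm(50); w <- runif(50, 0.2, 3)
  r <- weighted_pearson(x, y, w)
  expect_equal(weighted_pearson(3 * x - 7, 0.5 * y + 2, w), r, tolerance = 1e-12)
  expect_equal(weighted_pearson(x, y, 100 * w), r, tolerance = 1e-12)
  expect_equal(weighted_pearson(x, y, rep(2, 50)),
               suppressWarnings(cor(x, y)), tolerance = 1e-12)
})

test_that("contingency tables hold weighted percentages in status order", {
  all_same <- contingency(rep(c("UW", "HW", "OW", "OB"), 5),
                          rep(c("UW", "HW", "OW", "OB"), 5))
  expect_equal(sum(diag(all_same$cells)), 100)
  expect_equal(underestimation_rate(all_same), 0)
  expect_equal(overestimation_rate(all_same), 0)
  swap <- contingency(c("HW", "OW"), c("OW", "HW"))
  expect_equal(swap$cells["HW", "OW"], 50)
  expect_equal(swap$cells["OW", "HW"], 50)
  expect_equal(overall_misclassification(swap), 100)
  expect_equal(swap$counts["HW", "OW"], 1L)   # counts kept for unit weights
  # weighted cells
  wtab <- contingency(c("HW", "HW", "OB"), c("HW", "OW", "OB"), w = c(1, 3, 4))
  expect_equal(wtab$cells["HW", "OW"], 37.5)
  expect_null(wtab$counts)
})

test_that("misclassification decomposition sums to 100 and is permutation-invariant", {
  set.seed(42)
  for (i in 1:20) {
    a <- sample(status_levels(), 200, replace = TRUE)
    r <- sample(status_levels(), 200, replace = TRUE)
    w <- runif(200, 0.1, 4)
    tab <- contingency(a, r, w)
    expect_equal(underestimation_rate(tab) + overestimation_rate(tab) +
                   sum(diag(tab$cells)), 100, tolerance = 1e-9)
    expect_equal(overall_misclassification(tab),
                 underestimation_rate(tab) + overestimation_rate(tab),
                 tolerance = 1e-9)
    perm <- sample(200)
    expect_equal(contingency(a[perm], r[perm], w[perm])$cells, tab$cells,
                 tolerance = 1e-12)
  }
})

test_that("re-entered published panels reproduce the printed decompositions", {
  panels <- published_classification_tables()
  expect_equal(underestimation_rate(panels$male), 5.7, tolerance = 1e-9)
  expect_equal(underestimation_rate(panels$female), 5.6, tolerance = 1e-9)
  expect_equal(overall_misclassification(panels$male),
               100 - (1.3 + 64.9 + 8.7 + 11.3), tolerance = 1e-9)
})

test_that("binary diagnostics reproduce direct 2x2 ratios", {
  # constructed 2x2: TP = 8, FN = 2, TN = 90, FP = 0 at threshold 30
  ref <- c(rep(31, 10), rep(22, 90))
  pred <- c(rep(31, 8), rep(22, 2), rep(22, 90))
  d <- binary_diagnostics(pred, ref, 30)
  expect_equal(unname(d$estimates["sensitivity"]), 0.8)
  expect_equal(unname(d$estimates["specificity"]), 1.0)
  expect_equal(unname(d$estimates["ppv"]), 1.0)
  expect_equal(unname(d$estimates["npv"]), 90 / 92)
  perfect <- binary_diagnostics(ref, ref, 30)
  expect_equal(unname(perfect$estimates[c("sensitivity", "specificity")]),
               c(1, 1))
  expect_error(binary_diagnostics(pred, rep(22, 100), 30),
               regexp = "sensitivity", class = "bmicorrect_numeric_error")
})

test_that("PPV from Bayes' rule equals the cell-based PPV", {
  set.seed(43)
  ref <- rnorm(500, 26, 4); pred <- ref + rnorm(500, -0.5, 1.5)
  w <- runif(500, 0.5, 2)
  d <- binary_diagnostics(pred, ref, 25, w)
  sens <- d$estimates[["sensitivity"]]; spec <- d$estimates[["specificity"]]
  prev <- sum(w[ref >= 25]) / sum(w)
  bayes_ppv <- sens * prev / (sens * prev + (1 - spec) * (1 - prev))
  expect_equal(d$estimates[["ppv"]], bayes_ppv, tolerance = 1e-12)
})

test_that("equal weights reduce weighted diagnostics to unweighted", {
  set.seed(44)
  ref <- rnorm(300, 27, 5); pred <- ref + rnorm(300, 0, 2)
  d1 <- binary_diagnostics(pred, ref, 30)
  d2 <- binary_diagnostics(pred, ref, 30, w = rep(3.7, 300))
  expect_equal(d1$estimates, d2$estimates, tolerance = 1e-12)
  expect_equal(d1$ci, d2$ci, tolerance = 1e-12)
})

test_that("confidence intervals contain their point estimates, both methods", {
  set.seed(45)
  ref <- rnorm(400, 26, 4); pred <- ref + rnorm(400, -0.5, 1.5)
  w <- runif(400, 0.3, 3)
  for (method in c("wilson", "exact")) {
    d <- binary_diagnostics(pred, ref, 25, w, ci = method)
    for (m in names(d$estimates)) {
      expect_gte(d$estimates[[m]], d$ci[m, "lo"])
      expect_lte(d$estimates[[m]], d$ci[m, "hi"])
      expect_gte(d$ci[m, "lo"], 0)
      expect_lte(d$ci[m, "hi"], 1)
    }
  }
})

test_that("diagnostic comparison reports point deltas and CI overlap", {
  set.seed(46)
  ref <- rnorm(300, 26, 4); pred <- ref + rnorm(300, 0, 1)
  d <- binary_diagnostics(pred, ref, 25)
  same <- compare_diagnostics(d, d)
  expect_true(all(same$delta_pts == 0))
  expect_true(all(same$ci_overlap))
  pub_diag <- published_diagnostics()
  cmp <- compare_diagnostics(pub_diag$female$`25`$sr, pub_diag$female$`25`$corrected)
  expect_equal(round(cmp$delta_pts[cmp$metric == "sensitivity"], 1), 3.4)
  expect_false(cmp$ci_overlap[cmp$metric == "sensitivity"])
  cmp30 <- compare_diagnostics(pub_diag$female$`30`$sr, pub_diag$female$`30`$corrected)
  expect_equal(round(cmp30$delta_pts[cmp30$metric == "sensitivity"], 1), 5.9)
  expect_true(cmp30$ci_overlap[cmp30$metric == "sensitivity"])
})
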