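test_that("Spearman coefficient matches the independent mid-rank formula", {
  expect_equal(spearman_with_ci(1:5, c(2, 4, 6, 8, 10))$rho, 1.0)
  expect_equal(spearman_with_ci(1:5, c(10, 8, 6, 4, 2))$rho, -1.0)
  withr::with_seed(7, {
    for (r in 1:20) {
      x <- sample(1:4, 8, replace = TRUE)     # heavy ties
      y <- sample(1:3, 8, replace = TRUE)
      if (sd(x) == 0 || sd(y) == 0) next
      expect_equal(spearman_with_ci(x, y)$rho, midrank_spearman(x, y),
                   tolerance = 1e-12)
    }
  })
  expect_error(spearman_with_ci(rep(1, 6), 1:6),
               class = "pk_undefined_correlation")
  expect_error(spearman_with_ci(1:3, 1:3), class = "pk_invalid_input")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  withr::with_seed(11, {
    x <- rnorm(15)
    y <- x + rnorm(15)
    base <- spearman_with_ci(x, y)$rho
    expect_equal(spearman_with_ci(exp(x), y)$rho, base, tolerance = 1e-12)
    expect_equal(spearman_with_ci(x, y^3)$rho, base, tolerance = 1e-12)
  })
})

test_that("confidence intervals bracket the estimate for both methods", {
  withr::with_seed(13, {
    x <- rnorm(30)
    y <- 0.7 * x + rnorm(30, 0, 0.5)
  })
  fz <- spearman_with_ci(x, y, "fisher-z")
  expect_lte(fz$ci_low, fz$rho)
  expect_gte(fz$ci_high, fz$rho)
  bs <- spearman_with_ci(x, y, "bootstrap", n_boot = 500, seed = 5)
  expect_lte(bs$ci_low, bs$rho)
  expect_gte(bs$ci_high, bs$rho)
  td <- generics::tidy(fz)
  expect_named(td, c("estimate", "conf.low", "conf.high", "p.value", "n",
                     "method"))
})

test_that("coronary-disease staging follows the angiographic partition", {
  mk <- function(sten, rev = FALSE, tv = FALSE) {
    patient_record("x", stenosis_max = sten,
                   revascularization_object = rev, three_vessel = tv)
  }
  expect_equal(assign_cad_group(mk(0)), 1L)
  expect_equal(assign_cad_group(mk(40)), 2L)
  expect_equal(assign_cad_group(mk(50)), 2L)
  expect_equal(assign_cad_group(mk(60)), 3L)
  expect_equal(assign_cad_group(mk(60, rev = TRUE)), 4L)
  expect_equal(assign_cad_group(mk(90, tv = TRUE)), 4L)
  expect_error(assign_cad_group(mk(80)), class = "pk_ambiguous_group")
})

test_that("risk factors are counted over the six flags", {
  rec <- patient_record("x", hypertension = TRUE, smoking = TRUE)
  expect_equal(count_risk_factors(rec), 2L)
  expect_equal(count_risk_factors(patient_record("y")), 0L)
  all6 <- patient_record("z", hypertension = TRUE,
                         dyslipidemia_untreated = TRUE, bmi_over_35 = TRUE,
                         smoking = TRUE, diabetes = TRUE,
                         vascular_pathology = TRUE)
  expect_equal(count_risk_factors(all6), 6L)
  broken <- rec[, setdiff(names(rec), "diabetes")]
  expect_error(count_risk_factors(broken), class = "pk_missing_data")
})

test_that("a synthetic roster reproduces the published partition structure", {
  # 44 patients: CAD groups 5/6/6/27, risk-factor levels 2/10/19/11/2
  sten <- c(rep(0, 5), seq(20, 45, length.out = 6),
            seq(55, 70, length.out = 6), seq(55, 95, length.out = 27))
  rev <- c(rep(FALSE, 17), rep(TRUE, 27))
  risk_counts <- rep(c(0, 1, 2, 3, 4), times = c(2, 10, 19, 11, 2))
  roster <- purrr::map_dfr(1:44, function(i) {
    flags <- rep(FALSE, 6)
    if (risk_counts[i] > 0) flags[seq_len(risk_counts[i])] <- TRUE
    patient_record(sprintf("S%02d", i),
                   hypertension = flags[1],
                   dyslipidemia_untreated = flags[2],
                   bmi_over_35 = flags[3], smoking = flags[4],
                   diabetes = flags[5], vascular_pathology = flags[6],
                   stenosis_max = sten[i],
                   revascularization_object = rev[i])
  })
  groups <- assign_cad_group(roster)
  expect_equal(as.integer(table(groups)), c(5, 6, 6, 27))
  counts <- count_risk_factors(roster)
  expect_equal(as.integer(table(factor(counts, levels = 0:6))),
               c(2, 10, 19, 11, 2, 0, 0))
  expect_equal(sum(table(groups)), 44)
})

test_that("rank-sum p-values match exhaustive enumeration", {
  cmp <- compare_groups(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 2, 2, 2))
  expect_equal(generics::tidy(cmp)$median, c(2, 5))
  expect_equal(generics::glance(cmp)$p_value, 0.1)
  # symmetric case: exchangeable labels give p = 1
  sym <- compare_groups(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(generics::glance(sym)$p_value, 1.0)
  # randomized small cases against the test-local enumeration, with ties
  withr::with_seed(17, {
    for (r in 1:15) {
      n1 <- sample(2:4, 1)
      n2 <- sample(2:6, 1)
      v <- sample(1:5, n1 + n2, replace = TRUE)
      g <- rep(c("a", "b"), c(n1, n2))
      p_pkg <- generics::glance(compare_groups(v, g))$p_value
      p_ref <- enumerate_ranksum_p(v[g == "a"], v[g == "b"])
      expect_equal(p_pkg, p_ref, tolerance = 1e-12)
    }
  })
})

test_that("group comparisons summarize medians, quartiles and counts", {
  withr::with_seed(19, {
    v <- c(rnorm(5, 5.3, 0.8), rnorm(39, 6.2, 0.8))
    g <- rep(c(1, 2), c(5, 39))
  })
  cmp <- compare_groups(v, g, split = "1-vs-rest")
  s <- generics::tidy(cmp)
  expect_equal(s$n, c(5L, 39L))
  expect_true(all(s$q1 <= s$median & s$median <= s$q3))
  expect_match(generics::glance(cmp)$method, "exact")
  pairs <- compare_groups(c(v, rnorm(6, 7, 0.5)),
                          c(g, rep(3, 6)), split = "all-pairs")
  expect_equal(nrow(generics::glance(pairs)), 3)
})

test_that("the generator's group contrast is detectable at realistic power", {
  # CPWV drawn at the cohort level: group 1 mean 5.3 m/s (n=5) vs 6.2 m/s
  # (n=39), sd 0.8; fraction of significant rank-sum tests is measured
  hits <- withr::with_seed(23, {
    vapply(1:200, function(r) {
      v <- c(rnorm(5, 5.3, 0.8), rnorm(39, 6.2, 0.8))
      g <- rep(c(1, 2), c(5, 39))
      generics::glance(compare_groups(v, g))$p_value < 0.05
    }, logical(1))
  })
  expect_gte(mean(hits), 0.6)
})
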