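const_grid_cohort <- function(values, strains = seq(0.05, 0.5, 0.05)) {
  lapply(seq_along(values), function(i) {
    analytic_grid(strains, rep(values[i], length(strains)),
                  id = paste0("n", i))
  })
}

test_that("quartile table matches order-statistic interpolation", {
  qt <- stress_quartile_table(const_grid_cohort(1:4))
  expect_true(all(qt$median == 2.5))
  expect_true(all(qt$p75 == 3.25))
  expect_true(all(qt$p25 == 1.75))
  expect_true(all(qt$n == 4))
  expect_true(all(qt$ratio_p75_p25 == 3.25 / 1.75))
})

test_that("a single curve degenerates to equal statistics and unit ratios", {
  qt <- stress_quartile_table(const_grid_cohort(2.2))
  expect_true(all(qt$min == 2.2 & qt$max == 2.2 & qt$median == 2.2))
  expect_true(all(qt$ratio_p75_p25 == 1 & qt$ratio_max_min == 1))
  expect_error(stress_quartile_table(list()), "empty")
})

test_that("quantile engine agrees with the oracle on all small cohorts", {
  set.seed(66)
  for (n in 2:8) {
    vals <- round(runif(n, 0.1, 5), 3)
    qt <- stress_quartile_table(const_grid_cohort(vals))
    for (p in c(0.25, 0.5, 0.75)) {
      col <- c("0.25" = "p25", "0.5" = "median", "0.75" = "p75")[as.character(p)]
      expect_equal(qt[[col]][1], quantile_oracle(vals, p),
                   info = paste("n =", n, "p =", p))
    }
    expect_equal(qt$min[1], min(vals))
    expect_equal(qt$max[1], max(vals))
  }
})

test_that("ratio rows use unrounded statistics; rounding is display-only", {
  qt <- tibble::tibble(strain = 0.05, n = 129, min = 0.0404, p25 = 0.1214,
                       median = 0.195, p75 = 0.4583, max = 3.9604)
  qr <- add_ratio_rows(qt)
  expect_equal(qr$ratio_p75_p25, 0.4583 / 0.1214)
  fmt <- format_quartile_table(qr)
  expect_equal(fmt$ratio_p75_p25, round(0.4583 / 0.1214, 2))
  expect_equal(fmt$min, 0.04)
  # ratios of pre-rounded cells would differ from the displayed ratio
  expect_false(isTRUE(all.equal(round(fmt$p75 / fmt$p25, 2),
                                fmt$ratio_p75_p25)))
})

test_that("stiffness summaries give median and IQR per parameter", {
  profiles <- tibble::tibble(nodule_id = c("a", "b", "c"),
                             CS10 = c(1, 2, 3), CE10 = c(0.1, NA, 0.3))
  s <- stiffness_summary(profiles)
  cs <- s[s$parameter == "CS10", ]
  expect_equal(cs$median, 2)
  expect_equal(c(cs$p25, cs$p75), c(1.5, 2.5))
  expect_equal(s[s$parameter == "CE10", ]$n, 2)
  one <- stiffness_summary(tibble::tibble(nodule_id = "a", CS10 = 0.7))
  expect_equal(one$median, 0.7)
  expect_equal(one$p25, 0.7)
  expect_warning(
    stiffness_summary(tibble::tibble(nodule_id = "a", CS10 = NA_real_)),
    "omitted")
})

test_that("CT correlations match the textbook covariance formula", {
  profiles <- tibble::tibble(nodule_id = paste0("n", 1:5),
                             CS10 = c(0.2, 0.5, 0.4, 0.9, 1.4))
  records <- nodule_record(paste0("n", 1:5), rep(20, 5), rep(3, 5),
                           ct_hu = c(800, 900, 870, 1010, 1100))
  out <- correlate_with_ct(profiles, records)
  x <- records$ct_hu; y <- profiles$CS10
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand)
  expect_equal(out$n, 5L)
  # exact collinearity
  rec2 <- records; rec2$ct_hu <- 100 + 50 * profiles$CS10
  expect_equal(correlate_with_ct(profiles, rec2)$r, 1)
  # listwise deletion per parameter, and omission below the pair minimum
  rec3 <- records; rec3$ct_hu[1:3] <- NA
  expect_warning(out3 <- correlate_with_ct(profiles, rec3), "fewer than")
  expect_equal(nrow(out3), 0)
})

test_that("dialysis-by-pattern contrast reproduces the exact test", {
  d <- tibble::tibble(pattern = rep(c("three_phase", "gradual"), c(118, 11)),
                      dialysis = rep(c(TRUE, FALSE, TRUE, FALSE),
                                     c(20, 98, 7, 4)))
  cmp <- compare_groups(d, "pattern", "dialysis")
  expect_equal(glance(cmp)$method, "fisher_exact")
  expect_equal(round(glance(cmp)$p_value, 3), 0.002)
  td <- tidy(cmp)
  expect_equal(td$proportion[td$group == "three_phase"], 20 / 118)
  expect_equal(td$proportion[td$group == "gradual"], 7 / 11)
})

test_that("Fisher p agrees with full hypergeometric enumeration", {
  set.seed(88)
  for (k in 1:20) {
    tab <- matrix(rpois(4, 8), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    d <- tibble::tibble(
      g = rep(c("a", "b"), rowSums(tab)),
      y = c(rep(c(TRUE, FALSE), tab[1, ]), rep(c(TRUE, FALSE), tab[2, ]))
    )
    p_pkg <- glance(compare_groups(d, "g", "y"))$p_value
    p_or <- fisher_oracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(p_pkg, min(p_or, 1), tolerance = 1e-7)
  }
})

test_that("balanced tables and identical samples are null results", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 10),
                      y = rep(c(TRUE, FALSE), 10))
  expect_equal(glance(compare_groups(d, "g", "y"))$p_value, 1)
  dc <- tibble::tibble(g = rep(c("a", "b"), each = 12), y = rep(seq_len(12), 2))
  cmp <- compare_groups(dc, "g", "y")
  expect_equal(glance(cmp)$method, "mann_whitney_u")
  expect_equal(unname(glance(cmp)$statistic), 12 * 12 / 2)
  expect_gt(glance(cmp)$p_value, 0.95)
  expect_equal(tidy(cmp)$median, c(6.5, 6.5))
  expect_error(compare_groups(tibble::tibble(g = "a", y = 1), "g", "y"),
               "2 non-empty levels")
})

test_that("stress in gram-force units converts under standard gravity", {
  expect_equal(mpa_to_gf_mm2(1), 101.9716, tolerance = 1e-6)
  expect_equal(round(mpa_to_gf_mm2(0.378), 1), 38.5)
})
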