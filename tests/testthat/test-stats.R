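test_that("tertile encoding splits ranks with ties to the lower tertile", {
  f <- tertile_encode(1:9)
  expect_equal(as.character(f), rep(c("T1", "T2", "T3"), each = 3))
  expect_equal(attr(f, "cuts"), c(3, 6))
  expect_error(tertile_encode(rep(1, 10)), "distinct")
  withr::with_seed(1, {
    g <- tertile_encode(stats::runif(100))
    expect_lte(diff(range(table(g))), 1)
  })
  # boundary ties fall into the lower tertile
  tied <- tertile_encode(c(1, 2, 2, 2, 5, 6, 7, 8, 9))
  expect_equal(sum(tied == "T1"), 4)
})

test_that("group comparisons report the right test family", {
  tab <- generate_cohort_table(20, seed = 3)
  cont <- compare_groups(tab, "tpmi")
  expect_equal(cont$omnibus$method, "Kruskal-Wallis")
  expect_equal(nrow(cont$pairwise), 3)
  expect_true(all(c("median", "q1", "q3") %in% names(cont$summary)))
  cat_cmp <- compare_groups(tab, "gender")
  expect_equal(cat_cmp$omnibus$method, "Chi-square")
  tab$const <- 1
  expect_error(compare_groups(tab, "const"), "constant")
  # identical groups: Mann-Whitney p near 1
  two <- tibble::tibble(group = rep(c("A", "B"), each = 30),
                        v = rep(seq_len(30), 2))
  p <- compare_groups(two, "v")$pairwise$p.value
  expect_gt(p, 0.9)
})

test_that("a noiseless linear outcome is recovered exactly with the dual rule intact", {
  tab <- generate_cohort_table(40, seed = 4,
                               effect_spec = list(outcome = "tpmi",
                                                  effects = c(lge = -5.308,
                                                              gender = 3.3),
                                                  sigma = 0, intercept = 15))
  fit <- fit_outcome_model(tab, "tpmi")
  est <- fit$table
  expect_equal(est$estimate[est$term == "lge"], -5.308, tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "gender"], 3.3, tolerance = 1e-8)
  zero_terms <- est$estimate[!est$term %in% c("lge", "gender")]
  expect_true(all(abs(zero_terms) < 1e-8))
  expect_true(all(!est$final_sig | (est$uni_sig & est$multi_sig)))
  expect_equal(glance(fit)$n, nrow(tab))
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("statistics are invariant to row order", {
  tab <- generate_cohort_table(25, seed = 6)
  shuffled <- tab[withr::with_seed(99, sample(nrow(tab))), ]
  a <- compare_groups(tab, "fd"); b <- compare_groups(shuffled, "fd")
  expect_equal(a$omnibus$p.value, b$omnibus$p.value)
  fa <- fit_outcome_model(tab, "fd"); fb <- fit_outcome_model(shuffled, "fd")
  expect_equal(fa$table$estimate, fb$table$estimate)
  expect_equal(fa$table$p.multi, fb$table$p.multi)
})

test_that("null cohorts reject near the nominal rate", {
  rej <- vapply(1:300, function(s) {
    tab <- generate_cohort_table(20, seed = s,
                                 effect_spec = list(outcome = "tpmi",
                                                    effects = c()))
    compare_groups(tab, "tpmi")$omnibus$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("a planted location shift is detected with high power", {
  hits <- vapply(1:60, function(s) {
    tab <- generate_cohort_table(60, seed = 1000 + s,
                                 effect_spec = list(outcome = "tpmi",
                                                    effects = c(), sigma = 5))
    tab$tpmi[tab$group == "SHF"] <- tab$tpmi[tab$group == "SHF"] + 5  # 1 SD shift
    compare_groups(tab, "tpmi")$omnibus$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("rank-deficient designs are rejected with the aliased columns named", {
  tab <- generate_cohort_table(15, seed = 8)
  tab$htn <- TRUE                        # constant flag -> aliased
  expect_error(fit_outcome_model(tab, "tpmi"), "rank deficient")
})
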