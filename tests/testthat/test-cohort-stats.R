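toy_cohort <- function() {
  derive_cohort_columns(simulate_cohort(small_sim(n = 200, seed = 50))$cohort)
}

test_that("contingency tables cross-tabulate, transpose, and report missingness", {
  cohort <- toy_cohort()
  tab <- build_contingency(cohort, "mesenchymal_binary", "node_binary")
  expect_equal(sum(tab), nrow(cohort))
  swapped <- build_contingency(cohort, "node_binary", "mesenchymal_binary")
  expect_equal(as.matrix(t(tab)), as.matrix(swapped), ignore_attr = TRUE)

  cohort$node_binary[1:5] <- NA
  expect_message(tab2 <- build_contingency(cohort, "mesenchymal_binary",
                                           "node_binary"), "5 sample")
  expect_equal(attr(tab2, "n_missing"), 5)
  expect_equal(sum(tab2), nrow(cohort) - 5)

  expect_error(build_contingency(cohort, "mesenchymal_binary", "node_binary",
                                 filter = .data$age > 1000), "empty")
  expect_error(build_contingency(cohort, "no_such_var", "node_binary"),
               "Unknown variable")
})

test_that("chi-square matches the published-cohort value and an independent formula", {
  tab <- matrix(c(73, 36, 170, 139), 2, byrow = TRUE)
  res <- chi_square_test(tab)
  expect_equal(res$statistic, 4.73, tolerance = 0.002)
  expect_equal(res$p_value, 0.03, tolerance = 0.02)
  expect_equal(chi_square_test(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi_square_test(matrix(10, 2, 2))$p_value, 1)
  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)), "zero margin")

  # random tables vs direct sum((O-E)^2 / E)
  set.seed(91)
  for (i in 1:25) {
    t2 <- matrix(rpois(4, 30) + 1, 2)
    expected <- outer(rowSums(t2), colSums(t2)) / sum(t2)
    stat <- sum((t2 - expected)^2 / expected)
    res2 <- chi_square_test(t2)
    expect_equal(res2$statistic, stat, tolerance = 1e-10)
    expect_equal(res2$p_value, pchisq(stat, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("fisher exact equals full hypergeometric enumeration", {
  res <- fisher_exact_test(matrix(c(3, 1, 1, 3), 2))
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-12) # enumerated by hand
  expect_equal(fisher_exact_test(matrix(c(0, 0, 4, 6), 2))$p_value, 1)
  expect_error(fisher_exact_test(matrix(1:9, 3)), "2x2")

  set.seed(14)
  for (i in 1:50) {
    t2 <- matrix(as.integer(runif(4, 0, 12)), 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    expect_equal(fisher_exact_test(t2)$p_value, oracle_fisher_p(t2),
                 tolerance = 1e-9)
  }
})

test_that("chi-square and fisher converge to each other as counts grow", {
  # at moderate counts the two tests can disagree noticeably in the middle
  # of the p scale; agreement within 0.02 needs cells in the thousands
  set.seed(33)
  for (i in 1:20) {
    t2 <- matrix(as.integer(runif(4, 25, 120)), 2) * 50L
    expect_lt(abs(chi_square_test(t2)$p_value - fisher_exact_test(t2)$p_value),
              0.02)
  }
})

test_that("kruskal-wallis matches hand ranks and degenerates gracefully", {
  # groups (1,2,3) vs (4,5,6): H = 12/(6*7) * (3*(2-3.5)^2 + 3*(5-3.5)^2)
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 12 / 42 * (3 * 1.5^2 + 3 * 1.5^2),
               tolerance = 1e-12)
  flat <- kruskal_wallis(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # null calibration: permuted labels reject at about the nominal rate
  set.seed(77)
  rej <- mean(replicate(400, {
    kruskal_wallis(rnorm(30), sample(rep(c("a", "b", "c"), 10)))$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("the association-test policy picks the right test and can report both", {
  big <- matrix(c(73, 36, 170, 139), 2, byrow = TRUE)
  expect_equal(test_association(big)$method, "chi_square")
  small <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(test_association(small)$method, "fisher_exact")
  both <- test_association(big, "both")
  expect_setequal(both$method, c("chi_square", "fisher_exact"))
})

test_that("descriptive table sums, percentages, and medians are consistent", {
  cohort <- toy_cohort()
  desc <- descriptive_table(cohort)
  # within every stratum x variable block, counts sum to the stratum size
  # over non-missing values and percentages to 100
  blocks <- split(desc[desc$variable == "gender", ],
                  interaction(desc$site_group[desc$variable == "gender"],
                              desc$node_binary[desc$variable == "gender"],
                              desc$mesenchymal_binary[desc$variable == "gender"],
                              drop = TRUE))
  for (b in blocks) {
    expect_equal(sum(b$pct), 100, tolerance = 1e-9)
    stratum_n <- sum(cohort$site_group == b$site_group[1] &
                       cohort$node_binary == b$node_binary[1] &
                       cohort$mesenchymal_binary == b$mesenchymal_binary[1])
    expect_equal(sum(b$n), stratum_n)
  }
  # known marginals from the generator are recovered within sampling noise
  mes_np <- desc[desc$variable == "subtype" & desc$level == "mesenchymal" &
                   desc$node_binary == "N+", ]
  expect_gt(sum(mes_np$n), 0)

  single <- descriptive_table(cohort[1, ])
  expect_true(all(single$pct[!is.na(single$pct)] == 100))

  med <- desc[desc$variable == "age", ]
  expect_true(all(!is.na(med$median)))
})

test_that("published stratum counts reproduce the cohort's headline fractions", {
  counts <- published_cohort_counts()
  totals <- counts[counts$variable == "total", ]
  expect_equal(sum(totals$count), 418)
  agg <- stats::xtabs(count ~ subtype_group + node, totals)
  # nodal positivity: 67% mesenchymal vs 55% non-mesenchymal
  expect_equal(unname(agg["mesenchymal", "N+"] / sum(agg["mesenchymal", ])),
               0.67, tolerance = 0.005)
  expect_equal(unname(agg["non_mesenchymal", "N+"] / sum(agg["non_mesenchymal", ])),
               0.55, tolerance = 0.005)
})
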