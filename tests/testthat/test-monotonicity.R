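test_that("rest-score groups merge from the low end to reach minsize", {
  # 12 respondents, rest scores 0,0,1,1,2,2,...,5,5 via q2 + q3
  rest <- rep(0:5, each = 2)
  V <- cbind(q1 = rep(c(0L, 1L), 6), q2 = pmin(rest, 4L),
             q3 = rest - pmin(rest, 4L))
  rm <- rm_internal(V)
  g <- make_restscore_groups(rm, "q1", minsize = 4)
  expect_identical(g$group_sizes, c(4L, 4L, 4L))
  expect_identical(g$group_index, rep(1:3, each = 4))
  expect_identical(g$group_edges[, "min"], c(0, 2, 4))
  # minsize 1: one group per distinct rest score
  g1 <- make_restscore_groups(rm, "q1", minsize = 1)
  expect_identical(length(g1$group_sizes), 6L)
  # minsize above N/2: a single group, with a warning
  set.seed(2)
  V2 <- matrix(sample(0:4, 300, TRUE), 100, 3,
               dimnames = list(NULL, paste0("q", 1:3)))
  expect_warning(gb <- make_restscore_groups(rm_internal(V2), "q1",
                                             minsize = 60), "single|small")
  expect_identical(length(gb$group_sizes), 1L)
})

test_that("deterministic monotone data shows no violations and crit 0", {
  V <- guttman_matrix(n = 100, J = 5)
  res <- check_monotonicity(rm_internal(V), minsize = 20)
  expect_true(all(res$summary$vi == 0L))
  expect_true(all(res$summary$crit == 0))
  expect_true(all(res$summary$ac > 0L))
})

test_that("a constructed ISRF drop is counted at its exact magnitude", {
  # two groups of 20 defined by q2; P(q1 >= 2) drops 0.60 -> 0.50
  build <- function(p_lo, p_hi, n = 20L) {
    k_lo <- round(p_lo * n)
    k_hi <- round(p_hi * n)
    V <- cbind(q1 = c(rep(2L, k_lo), rep(1L, n - k_lo),
                      rep(2L, k_hi), rep(1L, n - k_hi)),
               q2 = rep(c(0L, 1L), each = n))
    rm_internal(V)
  }
  res <- check_monotonicity(build(0.60, 0.50), minvi = 0.03, minsize = 20)
  q1 <- res$summary[res$summary$item == "q1", ]
  expect_identical(q1$vi, 1L)
  expect_equal(q1$maxvi, 0.10, tolerance = 1e-12)
  expect_gt(q1$crit, 0)
  # a 0.02 drop stays below the minvi = 0.03 reporting threshold
  res2 <- check_monotonicity(build(0.60, 0.58, n = 50L), minvi = 0.03,
                             minsize = 50)
  expect_identical(res2$summary[res2$summary$item == "q1", "vi"], 0L)
  expect_identical(res2$summary[res2$summary$item == "q1", "crit"], 0)
})

test_that("crit is zero exactly when an item has no violations", {
  s <- inject_violation(single_factor_config(1500, a = 2.8, seed = 77),
                        violation_spec("anxiety", "nonmonotone_isrf",
                                       depth = 0.2, step = 1,
                                       interval = c(0, 4)))
  res <- check_monotonicity(s$responses)
  expect_true(all((res$summary$crit == 0) == (res$summary$vi == 0L)))
  expect_gt(res$summary[res$summary$item == "anxiety", "vi"], 0L)
})

test_that("strongly discriminating monotone data rarely shows violations", {
  hits <- vapply(1:30, function(r) {
    s <- generate_grm(single_factor_config(2000, a = 2.8, seed = 50000 + r))
    any(check_monotonicity(s$responses)$summary$vi > 0L)
  }, logical(1))
  expect_lte(mean(hits), 0.07)
})

test_that("an injected dip is flagged on the target item and only there", {
  hit <- clean <- logical(20)
  for (r in 1:20) {
    s <- inject_violation(single_factor_config(2000, a = 2.8,
                                               seed = 40000 + r),
                          violation_spec("anxiety", "nonmonotone_isrf",
                                         depth = 0.15, step = 1,
                                         interval = c(0, 4)))
    sm <- check_monotonicity(s$responses)$summary
    hit[r] <- sm[sm$item == "anxiety", "vi"] >= 1L
    clean[r] <- all(sm[sm$item != "anxiety", "crit"] == 0)
  }
  expect_gte(mean(hit), 0.90)
  expect_gte(mean(clean), 0.90)
})

test_that("irf_table sums the step response functions", {
  expect_equal(irf_table(matrix(c(0.9, 0.5, 0.2, 0.1), 4, 1)), 1.7)
  expect_equal(irf_table(matrix(1, 4, 3)), rep(4, 3))
  expect_equal(irf_table(matrix(0, 4, 3)), rep(0, 3))
  # IRF is non-decreasing across groups whenever every ISRF row is
  s <- generate_grm(grm_config(N = 2000, seed = 13))
  res <- check_monotonicity(s$responses)
  tab <- irf_table(res)
  for (it in unique(tab$item)) {
    rows_monotone <- all(apply(res$isrf[[it]]$prob, 1,
                               function(r) all(diff(r) >= 0)))
    if (rows_monotone) {
      expect_true(all(diff(tab$irf[tab$item == it]) >= 0))
    }
  }
})

test_that("adjacent-only comparisons are a subset of all-pairs comparisons", {
  s <- generate_grm(grm_config(N = 1000, seed = 19))
  all_p <- check_monotonicity(s$responses, pairs = "all")
  adj <- check_monotonicity(s$responses, pairs = "adjacent")
  expect_true(all(adj$summary$ac <= all_p$summary$ac))
  expect_true(all(adj$summary$vi <= all_p$summary$vi))
})
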