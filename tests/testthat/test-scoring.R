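test_that("the default composite rule is the elementwise worst-of-pair", {
  rule <- composite_rule(c("in", "out"), "mob")
  expect_identical(rule$mapping, outer(1:5, 1:5, pmax))
  expect_identical(rule$mapping[1, 1], 1L)
  expect_identical(rule$mapping[5, 3], 5L)
  expect_identical(rule$mapping[2, 4], rule$mapping[4, 2])
  expect_error(composite_rule(c("a", "b"), "c",
                              mapping = matrix(6L, 5, 5)), "1..5")
  asym <- outer(1:5, 1:5, pmax)
  asym[1, 2] <- 3L
  expect_error(composite_rule(c("a", "b"), "c", mapping = asym), "symmetric")
})

test_that("build_composite appends the mapped column, propagating missing", {
  ext <- cbind(inside = c(1, 5, 2, 3, NA), outside = c(1, 3, 4, 3, 2),
               other = c(2, 2, 2, 2, 2))
  rm <- response_matrix(ext)
  out <- build_composite(rm, composite_rule(c("inside", "outside"), "mobility"))
  expect_identical(out$item_ids, c("inside", "outside", "other", "mobility"))
  expect_identical(unname(out$values[, "mobility"] + 1L),
                   c(1L, 5L, 4L, 3L, NA))
  # sources can be dropped
  out2 <- build_composite(rm, composite_rule(c("inside", "outside"), "mobility"),
                          keep_sources = FALSE)
  expect_identical(out2$item_ids, c("other", "mobility"))
  # a user-supplied table overrides the default
  tab <- outer(1:5, 1:5, pmin)
  out3 <- build_composite(rm, composite_rule(c("inside", "outside"), "m2",
                                             mapping = tab))
  expect_identical(unname(out3$values[, "m2"] + 1L), c(1L, 3L, 2L, 3L, NA))
})

test_that("the LSS transform is exact on the closed form", {
  J <- 9L
  all1 <- response_matrix(matrix(1, 3, J, dimnames = list(NULL, paste0("q", 1:J))))
  expect_true(all(compute_lss(all1)$scores$raw == 9L))
  expect_true(all(compute_lss(all1)$scores$transformed == 0))
  all5 <- response_matrix(matrix(5, 3, J, dimnames = list(NULL, paste0("q", 1:J))))
  expect_true(all(compute_lss(all5)$scores$transformed == 100))
  # raw sum 13 on 9 items: (13 - 9) / 36 * 100
  one <- response_matrix(matrix(c(5, rep(1, 8)), 1, J,
                                dimnames = list(NULL, paste0("q", 1:J))))
  expect_equal(compute_lss(one)$scores$transformed, 400 / 36)
  expect_equal(round(compute_lss(one)$scores$transformed, 2), 11.11)
  # every attainable raw sum maps to its multiple of 100/36
  set.seed(3)
  V <- matrix(sample(1:5, 20 * J, TRUE), 20, J,
              dimnames = list(NULL, paste0("q", 1:J)))
  lss <- compute_lss(response_matrix(V))
  expect_equal(lss$scores$transformed, (lss$scores$raw - 9) * 100 / 36,
               tolerance = 1e-12)
  # invariance to item order
  perm <- response_matrix(V[, sample(J)])
  expect_equal(sort(compute_lss(perm)$scores$transformed),
               sort(lss$scores$transformed))
  # respondents missing a scale item are excluded and counted
  V[3, 2] <- NA
  lss2 <- compute_lss(response_matrix(V))
  expect_identical(lss2$n_excluded, 1L)
  expect_identical(lss2$n_used, 19L)
})

test_that("reliability formulas hit their closed-form anchors", {
  # J identical items
  set.seed(10)
  v <- sample(0:4, 50, TRUE)
  ident <- rm_internal(cbind(a = v, b = v, c = v))
  expect_equal(cronbach_alpha(ident), 1, tolerance = 1e-12)
  expect_equal(guttman_lambda2(ident), 1, tolerance = 1e-12)
  # exactly independent population pair: alpha = lambda2 = 0
  indep <- rm_internal(independent_pair_matrix())
  expect_equal(cronbach_alpha(indep), 0, tolerance = 1e-12)
  expect_equal(guttman_lambda2(indep), 0, tolerance = 1e-12)
  # random fixture equals an independent evaluation of the formulas
  V <- matrix(sample(0:4, 150, TRUE), 50, 3)
  n <- nrow(V)
  cv <- stats::cov(V) * (n - 1) / n
  alpha_direct <- 3 / 2 * (1 - sum(diag(cv)) / sum(cv))
  off <- cv; diag(off) <- 0
  l2_direct <- (sum(off) + sqrt(3 / 2 * sum(off^2))) / sum(cv)
  rm <- rm_internal(V)
  expect_equal(cronbach_alpha(rm), alpha_direct, tolerance = 1e-12)
  expect_equal(guttman_lambda2(rm), l2_direct, tolerance = 1e-12)
})

test_that("lambda-2 dominates alpha on random data", {
  set.seed(12)
  for (r in 1:20) {
    V <- matrix(sample(0:4, 40 * 4, TRUE), 40, 4)
    rm <- rm_internal(V)
    expect_gte(guttman_lambda2(rm), cronbach_alpha(rm) - 1e-12)
  }
})

test_that("a positive trait shift raises the median LSS of the shifted group", {
  hits <- vapply(1:20, function(r) {
    s <- generate_grm(grm_config(N = 1200, seed = 300 + r))
    ltc <- s$labels$long_term_condition
    ok <- vapply(list(1:9, 1:6, 7:9), function(idx) {
      sc <- scale_definition("s", s$responses$item_ids[idx])
      lss <- compute_lss(s$responses, sc)
      med <- tapply(lss$scores$transformed, ltc[lss$scores$respondent], median)
      med[["1"]] > med[["0"]]
    }, logical(1))
    all(ok)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
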