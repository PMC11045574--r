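test_that("constructed conditional-mean reversals are thresholded at m x 0.03", {
  # groups of 20 defined by q3; overall q1 easier than q2, but q1's
  # conditional mean exceeds q2's by `rev` in the first group
  build <- function(rev) {
    n <- 20L
    a_lo <- c(rep(2L, round(rev * n) + 4L), rep(1L, n - round(rev * n) - 4L))
    b_lo <- c(rep(2L, 4L), rep(1L, n - 4L))          # mean 1.2
    a_hi <- rep(1L, n)                               # mean 1.0
    b_hi <- c(rep(2L, 10L), rep(1L, 10L))            # mean 1.5
    V <- cbind(q1 = c(a_lo, a_hi), q2 = c(b_lo, b_hi),
               q3 = rep(c(0L, 1L), each = n))
    rm_internal(V)
  }
  # reversal 0.20 > 0.12: one pair violation
  res <- check_miio(build(0.20), minsize = 20)
  pair <- res$pair_violations[res$pair_violations$easier == "q1" &
                                res$pair_violations$harder == "q2", ]
  expect_identical(pair$vi, 1L)
  expect_equal(pair$maxvi, 0.20, tolerance = 1e-12)
  # reversal 0.10 <= 0.12: none
  res2 <- check_miio(build(0.10), minsize = 20)
  pair2 <- res2$pair_violations[res2$pair_violations$easier == "q1" &
                                  res2$pair_violations$harder == "q2", ]
  expect_identical(pair2$vi, 0L)
})

test_that("a constant conditional-mean offset never violates ordering", {
  # q2 = q1 + 1 level wherever possible: means differ by ~+1 in every group
  set.seed(44)
  q1 <- sample(0:3, 200, TRUE)
  V <- cbind(q1 = q1, q2 = q1 + 1L,
             q3 = sample(0:4, 200, TRUE), q4 = sample(0:4, 200, TRUE))
  res <- check_miio(rm_internal(V), minsize = 40)
  pair <- res$pair_violations[res$pair_violations$easier == "q1" &
                                res$pair_violations$harder == "q2", ]
  expect_identical(pair$vi, 0L)
})

test_that("relabeling two items permutes the order but not the violations", {
  s <- generate_grm(grm_config(N = 1500, seed = 55))
  rm <- s$responses
  r1 <- check_miio(rm)
  # give items 2 ("sad") and 5 ("cognition") each other's data
  V <- rm$values
  V[, c(2, 5)] <- V[, c(5, 2)]
  r2 <- check_miio(rm_internal(V))
  expect_identical(sum(r1$pair_violations$vi), sum(r2$pair_violations$vi))
  swap <- function(x) ifelse(x == "sad", "cognition",
                             ifelse(x == "cognition", "sad", x))
  expect_identical(swap(r1$item_order), r2$item_order)
})

test_that("backward selection stops with a violation-free surviving set", {
  s <- inject_violation(grm_config(N = 2000, seed = 66),
                        violation_spec("sad", "crossing_irf", depth = 0.2))
  res <- check_miio(s$responses)
  expect_lte(length(res$removed_items), 7L)   # at most J - 2
  expect_gte(length(res$kept_items), 2L)
  if (length(res$kept_items) > 2L) {
    expect_true(all(res$final_summary$vi == 0L))
  }
  expect_true(all(res$removed_items %in% s$responses$item_ids))
})

test_that("H^T is 1 for parallel shifts of one respondent ordering", {
  V <- cbind(a = rep(0:2, each = 4), b = rep(1:3, each = 4),
             c = rep(2:4, each = 4))
  ht <- compute_HT(rm_internal(V))
  expect_equal(as.numeric(ht), 1, tolerance = 1e-12)
  expect_identical(attr(ht, "label"), "highly accurate")
})

test_that("H^T equals the scalability oracle applied to the transpose", {
  set.seed(88)
  V <- matrix(sample(0:4, 8 * 5, TRUE), 8, 5,
              dimnames = list(NULL, paste0("q", 1:5)))
  keep <- apply(V, 1, function(r) max(r) > min(r))
  o <- oracle_H(t(V[keep, ]))
  ht <- compute_HT(rm_internal(V))
  expect_equal(as.numeric(ht), o$H_scale, tolerance = 1e-12)
  expect_identical(attr(ht, "n_excluded"), sum(!keep))
  # label rule of thumb at the study-like magnitude
  expect_identical(attr(compute_HT(generate_grm(grm_config(N = 2000,
                                                           seed = 9))$responses),
                        "label"),
                   "items cannot be ordered")
})

test_that("well-separated common-discrimination items rarely violate MIIO", {
  hits <- vapply(1:40, function(r) {
    s <- generate_grm(single_factor_config(2000, seed = 7000 + r))
    any(check_miio(s$responses)$pair_violations$vi > 0L)
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})
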