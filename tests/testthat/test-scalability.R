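test_that("max_covariance matches enumeration and bounds every joint table", {
  # identical margins: the comonotone coupling is the diagonal
  f <- c(3, 5, 2, 4, 1)
  v <- sum(f * (0:4)^2) / 15 - (sum(f * 0:4) / 15)^2
  expect_equal(max_covariance(f, f), v, tolerance = 1e-12)
  # two balanced binary margins, n = 4: enumerate all couplings
  expect_equal(max_covariance(c(2, 2), c(2, 2)), 0.25, tolerance = 1e-15)
  # any joint table with the given margins has covariance <= max_covariance
  set.seed(42)
  for (r in 1:50) {
    fi <- as.vector(stats::rmultinom(1, 40, c(.2, .3, .1, .25, .15)))
    fj <- as.vector(stats::rmultinom(1, 40, c(.35, .15, .2, .1, .2)))
    if (sum(fi > 0) < 2 || sum(fj > 0) < 2) next
    mc <- max_covariance(fi, fj)
    tab <- stats::r2dtable(1, fi, fj)[[1]]
    cv <- sum(tab * outer(0:4, 0:4)) / 40 -
      sum(fi * 0:4) / 40 * sum(fj * 0:4) / 40
    expect_lte(cv, mc + 1e-12)
  }
  expect_error(max_covariance(c(4, 0), c(2, 2)), "degenerate")
  expect_error(max_covariance(c(2, 2), c(2, 3)), "same n")
})

test_that("compute_H agrees with the brute-force cross-table oracle", {
  set.seed(7)
  V <- matrix(sample(0:4, 200 * 4, TRUE), 200, 4,
              dimnames = list(NULL, paste0("q", 1:4)))
  h <- compute_H(rm_internal(V), bootstrap_reps = 0)
  o <- oracle_H(V)
  expect_equal(unname(h$H_pair), unname(o$H_pair), tolerance = 1e-12)
  expect_equal(unname(h$H_item), unname(o$H_item), tolerance = 1e-12)
  expect_equal(h$H_scale, o$H_scale, tolerance = 1e-12)
  # and with the weighted-Guttman-error formulation, pair by pair
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(h$H_pair[i, j], oracle_H_guttman(V[, i], V[, j], 4),
                   tolerance = 1e-12)
    }
  }
})

test_that("Guttman-structured data attains H = 1 everywhere", {
  V <- guttman_matrix(n = 80, J = 5)
  h <- compute_H(rm_internal(V), bootstrap_reps = 0)
  expect_equal(unname(h$H_pair[upper.tri(h$H_pair)]), rep(1, 10),
               tolerance = 1e-12)
  expect_equal(unname(h$H_item), rep(1, 5), tolerance = 1e-12)
  expect_equal(h$H_scale, 1, tolerance = 1e-12)
})

test_that("a product-of-margins population table gives H_pair = 0", {
  V <- independent_pair_matrix()
  h <- compute_H(rm_internal(V, levels = 5), bootstrap_reps = 0)
  expect_equal(h$H_pair[1, 2], 0, tolerance = 1e-15)
  expect_equal(h$H_scale, 0, tolerance = 1e-15)
})

test_that("classify_H follows the half-open rule-of-thumb bins", {
  expect_identical(classify_H(0.561), "strong")
  expect_identical(classify_H(0.45), "moderate")
  expect_identical(classify_H(0.3), "weak")
  expect_identical(classify_H(0.4), "moderate")
  expect_identical(classify_H(0.5), "strong")
  expect_identical(classify_H(0.299), "unacceptable")
  expect_identical(classify_H(-0.2), "unacceptable")
})

test_that("H is invariant to affine relabelings, sign-stable to monotone ones", {
  set.seed(21)
  V <- matrix(sample(0:4, 150 * 3, TRUE), 150, 3)
  base <- oracle_H(V)$H_pair
  affine <- oracle_H(3 * V + 2)$H_pair
  expect_equal(affine, base, tolerance = 1e-12)
  mono <- oracle_H(matrix(c(0, 2, 3, 7, 10)[V + 1], nrow(V)))$H_pair
  expect_identical(sign(mono), sign(base))
})

test_that("H_scale lies between the item coefficients (mediant property)", {
  set.seed(5)
  for (r in 1:20) {
    V <- matrix(sample(0:4, 120 * 5, TRUE), 120, 5)
    h <- compute_H(rm_internal(V), bootstrap_reps = 0)
    expect_gte(h$H_scale, min(h$H_item) - 1e-12)
    expect_lte(h$H_scale, max(h$H_item) + 1e-12)
  }
})

test_that("zero-variance items are excluded with a warning", {
  set.seed(9)
  V <- matrix(sample(0:4, 50 * 3, TRUE), 50, 3,
              dimnames = list(NULL, c("a", "b", "flat")))
  V[, 3] <- 2L
  expect_warning(h <- compute_H(rm_internal(V), bootstrap_reps = 0), "flat")
  expect_identical(h$excluded_items, "flat")
  expect_length(h$H_item, 2L)
})

test_that("bootstrap SE of H_scale shrinks roughly as 1/sqrt(N)", {
  ses <- vapply(c(250, 1000, 4000), function(N) {
    s <- generate_grm(single_factor_config(N, seed = 100 + N))
    compute_H(s$responses, bootstrap_reps = 300, seed = 1)$se_scale
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(ses) ~ log(c(250, 1000, 4000))))[2]
  expect_lt(abs(slope + 0.5), 0.25)
})

test_that("independent items have near-zero H_scale at N = 5000", {
  set.seed(31)
  V <- matrix(sample(0:4, 5000 * 5, TRUE, prob = c(.3, .25, .2, .15, .1)),
              5000, 5)
  h <- compute_H(rm_internal(V), bootstrap_reps = 0)
  expect_lt(abs(h$H_scale), 0.05)
})
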