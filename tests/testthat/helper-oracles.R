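# Brute-force oracles, written independently of the package internals.
# All covariances use the divide-by-n convention.

ocov <- function(x, y) mean(x * y) - mean(x) * mean(y)

# maximum covariance by explicit comonotone coupling: sort both samples and
# pair order statistics rank for rank
oracle_maxcov <- function(x, y) ocov(sort(x), sort(y))

# scalability coefficients from explicit pairwise cross-tables
oracle_H <- function(V) {
  J <- ncol(V)
  n <- nrow(V)
  covm <- maxm <- matrix(NA_real_, J, J)
  for (i in seq_len(J - 1)) {
    for (j in (i + 1):J) {
      tab <- table(V[, i], V[, j])
      xi <- as.numeric(rownames(tab))
      yj <- as.numeric(colnames(tab))
      covm[i, j] <- covm[j, i] <-
        sum(tab * outer(xi, yj)) / n -
        sum(rowSums(tab) * xi) / n * sum(colSums(tab) * yj) / n
      maxm[i, j] <- maxm[j, i] <- oracle_maxcov(V[, i], V[, j])
    }
  }
  H_pair <- covm / maxm
  H_item <- rowSums(covm, na.rm = TRUE) / rowSums(maxm, na.rm = TRUE)
  up <- upper.tri(covm)
  list(H_pair = H_pair, H_item = H_item,
       H_scale = sum(covm[up]) / sum(maxm[up]))
}

# weighted-Guttman-error formulation for one item pair: 1 minus the observed
# error mass over the expected mass under independent margins, both obtained
# by counting pass/fail patterns over every cross-item step pair
oracle_H_guttman <- function(vi, vj, m) {
  FF <- 0
  EE <- 0
  for (x in seq_len(m)) {
    for (y in seq_len(m)) {
      Px <- mean(vi >= x)
      Py <- mean(vj >= y)
      Pboth <- mean(vi >= x & vj >= y)
      FF <- FF + min(Px, Py) - Pboth
      EE <- EE + min(Px, Py) - Px * Py
    }
  }
  1 - FF / EE
}

# Spearman rho as the Pearson correlation of mid-ranks, from scratch
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  ocov(rx, ry) / sqrt(ocov(rx, rx) * ocov(ry, ry))
}
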