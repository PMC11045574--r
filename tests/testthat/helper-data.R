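# fixture builders (all data generated in code)

rm_internal <- function(V, levels = 5L) {
  response_matrix(V + 1L, levels = levels)
}

# deterministic Guttman-structured data: items are nested step functions of a
# common respondent ordering, so every item pair is comonotone
guttman_matrix <- function(n = 60L, J = 5L, m = 4L, seed = 3L) {
  set.seed(seed)
  theta <- seq_len(n)
  V <- vapply(seq_len(J), function(j) {
    cuts <- sort(sample(seq_len(n - 1L), m))
    rowSums(outer(theta, cuts, ">"))
  }, numeric(n))
  colnames(V) <- paste0("g", seq_len(J))
  V
}

# exact product-of-margins population: two binary items, joint counts equal
# to the product of the margins (n = 16)
independent_pair_matrix <- function() {
  # margins u: (8, 8), v: (4, 12); joint counts (2, 6, 2, 6) = products / 16
  cbind(u = rep(c(0L, 1L), c(8L, 8L)),
        v = rep(c(0L, 1L, 0L, 1L), c(2L, 6L, 2L, 6L)))
}

# single-factor GRM config with well-separated difficulty locations
single_factor_config <- function(N, a = 1.8, seed = NULL,
                                 locations = seq(-0.5, 2.3, length.out = 9)) {
  grm_config(N = N, a = a, cluster = rep(1L, 9L),
             item_locations = locations, seed = seed)
}
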