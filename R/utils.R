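# shared internal helpers

# evaluate expr under a temporary RNG state; NULL seed = use current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# divide-by-n covariance matrix of the columns of V (no missing values)
cov_n <- function(V) {
  n <- nrow(V)
  mu <- colMeans(V)
  crossprod(V) / n - tcrossprod(mu)
}

# per-column level frequencies, levels 0..(levels-1)
level_margins <- function(V, levels) {
  apply(V, 2L, function(v) tabulate(v + 1L, nbins = levels))
}

# rest score of every respondent for `item` within `items` (internal coding)
rest_scores <- function(V, item) {
  rowSums(V[, setdiff(colnames(V), item), drop = FALSE])
}

# merge adjacent raw score values from the low end until every group has at
# least minsize members; a trailing undersized group is merged into its
# predecessor; returns integer group index aligned with `score`
merge_score_groups <- function(score, minsize) {
  vals <- sort(unique(score))
  counts <- vapply(vals, function(v) sum(score == v), integer(1L))
  grp_of_val <- integer(length(vals))
  g <- 1L
  acc <- 0L
  for (k in seq_along(vals)) {
    grp_of_val[k] <- g
    acc <- acc + counts[k]
    if (acc >= minsize && k < length(vals)) {
      g <- g + 1L
      acc <- 0L
    }
  }
  # trailing group that never reached minsize merges backwards
  if (acc < minsize && acc > 0L && g > 1L) {
    grp_of_val[grp_of_val == g] <- g - 1L
  }
  grp_of_val[match(score, vals)]
}

# default minimum rest-score group size ladder, by total sample size
default_minsize <- function(n) {
  if (n >= 500L) floor(n / 10) else if (n >= 250L) floor(n / 5) else max(floor(n / 3), 50L)
}
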