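#' Partition respondents into rest-score groups
#'
#' The rest score of a respondent for an item is their sum over the scale's
#' other items. Adjacent raw rest-score values are merged from the low end
#' until every group holds at least `minsize` respondents; a trailing
#' undersized group is merged into its predecessor. Groups are contiguous,
#' ordered intervals of the rest score.
#'
#' @param x a [response_matrix()].
#' @param item the item whose rest score is formed (excluded from the sum).
#' @param minsize minimum group size; `NULL` uses the sample-size ladder
#'   `N/10` (N >= 500), `N/5` (250 <= N < 500), `max(N/3, 50)` otherwise.
#' @param scale a [scale_definition()] or item ids; `NULL` = all items.
#' @return object of class `restscore_grouping`: `group_index`
#'   (per-respondent group id, 1 = lowest rest scores), `group_sizes`,
#'   `group_edges` (min/max rest score per group), `minsize`.
#' @export
make_restscore_groups <- function(x, item, minsize = NULL, scale = NULL) {
  scale <- resolve_scale(x, scale)
  if (!item %in% scale$items) stop("item not in scale", call. = FALSE)
  cc <- complete_cases(x, scale)
  n <- nrow(cc$values)
  if (is.null(minsize)) minsize <- default_minsize(n)
  stopifnot(minsize >= 1)
  if (n < 2 * minsize) {
    warning("sample too small for two rest-score groups; ",
            "no comparisons will be possible", call. = FALSE)
  }
  r <- rest_scores(cc$values, item)
  idx <- merge_score_groups(r, minsize)
  sizes <- tabulate(idx)
  edges <- t(vapply(seq_len(max(idx)), function(g) {
    range(r[idx == g])
  }, numeric(2L)))
  colnames(edges) <- c("min", "max")
  structure(list(group_index = idx, group_sizes = sizes, group_edges = edges,
                 minsize = minsize, item = item, n = n),
            class = "restscore_grouping")
}

# ISRF estimate for one item over a grouping: list with `prob` (m x G matrix
# of P(X >= x | g)), `count` (numerators) and `sizes`
estimate_isrf <- function(v, idx, m) {
  G <- max(idx)
  sizes <- tabulate(idx, nbins = G)
  count <- vapply(seq_len(G), function(g) {
    vg <- v[idx == g]
    vapply(seq_len(m), function(s) sum(vg >= s), numeric(1L))
  }, numeric(m))
  count <- matrix(count, nrow = m)
  prob <- sweep(count, 2L, sizes, "/")
  rownames(prob) <- rownames(count) <- paste0(">=", seq_len(m))
  list(prob = prob, count = count, sizes = sizes)
}

# one-sided pooled two-proportion z test that p_g > p_h
pooled_prop_z <- function(k_g, n_g, k_h, n_h) {
  pp <- (k_g + k_h) / (n_g + n_h)
  se <- sqrt(pp * (1 - pp) * (1 / n_g + 1 / n_h))
  if (se == 0) return(0)
  (k_g / n_g - k_h / n_h) / se
}

# composite misfit diagnostic; zero iff no violations, increasing in every
# ingredient (see the methods vignette for the rationale)
crit_value <- function(H_item, ac, vi, maxvi, sum_vi, zsig) {
  if (vi == 0 || ac == 0) return(0)
  50 * max(0, 0.3 - H_item) + sqrt(vi) + 100 * vi / ac +
    100 * maxvi + 50 * sum_vi + 10 * sqrt(zsig)
}

#' Check manifest monotonicity of the item step response functions
#'
#' For every item, respondents are grouped by the rest score (the item
#' excluded from its own rest score) and the item step response functions
#' (ISRFs) `P(X >= x | group)` are estimated per group. Manifest
#' monotonicity requires these cumulative probabilities not to decrease as
#' the rest score increases: for every step `x` and every ordered group
#' pair `g < h`, a decrease larger than `minvi` counts as a violation.
#' Significant violations are flagged by a one-sided pooled two-proportion
#' z-test at `alpha`. A composite `crit` diagnostic aggregates the item's
#' violation evidence (zero exactly when the item has no violations).
#'
#' @inheritParams make_restscore_groups
#' @param minvi minimum violation magnitude reported (default 0.03).
#' @param alpha significance level of the z-test (default 0.05).
#' @param pairs `"all"` compares every ordered group pair `g < h` (the
#'   stricter reading); `"adjacent"` only neighbouring groups.
#' @return object of class `monotonicity_result`: `summary` data.frame
#'   (item, `H_item`, `ac` active comparisons, `vi` violations, `maxvi`,
#'   `sum_vi`, `zsig`, `crit`), `isrf` (per-item ISRF estimates and
#'   groupings) and the settings used.
#' @export
check_monotonicity <- function(x, scale = NULL, minvi = 0.03, minsize = NULL,
                               alpha = 0.05, pairs = c("all", "adjacent")) {
  pairs <- match.arg(pairs)
  scale <- resolve_scale(x, scale)
  cc <- complete_cases(x, scale)
  V <- cc$values
  m <- cc$levels - 1L
  if (is.null(minsize)) minsize <- default_minsize(nrow(V))
  H <- h_from_values(V, cc$levels)
  zcrit <- stats::qnorm(1 - alpha)
  items <- colnames(V)
  isrf <- vector("list", length(items))
  names(isrf) <- items
  rows <- lapply(items, function(it) {
    r <- rest_scores(V, it)
    idx <- merge_score_groups(r, minsize)
    est <- estimate_isrf(V[, it], idx, m)
    isrf[[it]] <<- c(est, list(group_index = idx))
    G <- length(est$sizes)
    ac <- 0L; vi <- 0L; zsig <- 0L
    maxvi <- 0; sum_vi <- 0
    if (G >= 2L) {
      gp <- if (pairs == "all") utils::combn(G, 2L) else
        rbind(seq_len(G - 1L), 2L:G)
      for (s in seq_len(m)) {
        for (k in seq_len(ncol(gp))) {
          g <- gp[1L, k]; h <- gp[2L, k]
          if (est$sizes[g] == 0L || est$sizes[h] == 0L) next
          ac <- ac + 1L
          drop <- est$prob[s, g] - est$prob[s, h]
          if (drop > minvi) {
            vi <- vi + 1L
            maxvi <- max(maxvi, drop)
            sum_vi <- sum_vi + drop
            z <- pooled_prop_z(est$count[s, g], est$sizes[g],
                               est$count[s, h], est$sizes[h])
            if (z > zcrit) zsig <- zsig + 1L
          }
        }
      }
    }
    data.frame(item = it, H_item = H$H_item[it], ac = ac, vi = vi,
               maxvi = maxvi, sum_vi = sum_vi, zsig = zsig,
               crit = crit_value(H$H_item[it], ac, vi, maxvi, sum_vi, zsig))
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(summary = summary, isrf = isrf, scale_name = scale$name,
                 n_used = nrow(V),
                 settings = list(minvi = minvi, minsize = minsize,
                                 alpha = alpha, pairs = pairs)),
            class = "monotonicity_result")
}

#' @export
print.monotonicity_result <- function(x, ...) {
  cat(sprintf("Manifest monotonicity of scale '%s' (n = %d, minvi = %g)\n",
              x$scale_name, x$n_used, x$settings$minvi))
  print(x$summary[, c("item", "ac", "vi", "zsig", "crit")], digits = 3L)
  invisible(x)
}

#' Item response functions over rest-score groups
#'
#' The polytomous item response function is the sum of the item's step
#' response functions, i.e. the expected item score per rest-score group
#' (internal 0-based coding, range `0..m`).
#'
#' @param x a `monotonicity_result` (its ISRF estimates are used), or a bare
#'   ISRF probability matrix (steps in rows, groups in columns).
#' @return data.frame with one row per (item, group): group sizes and the
#'   expected-score `irf` value, suitable for plotting. For a bare matrix,
#'   the vector of column sums.
#' @export
irf_table <- function(x) {
  if (is.matrix(x)) {
    stopifnot(all(x >= 0 & x <= 1))
    return(colSums(x))
  }
  stopifnot(inherits(x, "monotonicity_result"))
  do.call(rbind, lapply(names(x$isrf), function(it) {
    est <- x$isrf[[it]]
    data.frame(item = it, group = seq_along(est$sizes),
               n = est$sizes, irf = colSums(est$prob), row.names = NULL)
  }))
}
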