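#' Maximum attainable covariance between two ordinal margins
#'
#' The norming constant of Loevinger's H: the largest sample covariance any
#' joint table with the given level margins can reach, attained by the
#' comonotone coupling (pair the two samples' order statistics rank for
#' rank). Covariances use the divide-by-n convention throughout the package
#' so that numerator and denominator conventions cancel in H.
#'
#' @param margin_i,margin_j level frequency vectors (counts per ordered
#'   level, lowest first); both must sum to the same total.
#' @param values_i,values_j numeric scores attached to the levels; default
#'   `0, 1, 2, ...`. H is invariant to a common affine recoding.
#' @return the maximum covariance (scalar).
#' @export
max_covariance <- function(margin_i, margin_j,
                           values_i = seq_along(margin_i) - 1,
                           values_j = seq_along(margin_j) - 1) {
  n <- sum(margin_i)
  if (n != sum(margin_j)) stop("margins must sum to the same n", call. = FALSE)
  if (n < 2L) stop("need n >= 2", call. = FALSE)
  mu_i <- sum(margin_i * values_i) / n
  mu_j <- sum(margin_j * values_j) / n
  var_i <- sum(margin_i * values_i^2) / n - mu_i^2
  var_j <- sum(margin_j * values_j^2) / n - mu_j^2
  if (var_i <= 0 || var_j <= 0) {
    stop("degenerate margin: zero variance, H undefined", call. = FALSE)
  }
  # comonotone coupling by a merge walk over the two cumulative margins
  exy <- 0
  a <- 1L
  b <- 1L
  ra <- margin_i[a]
  rb <- margin_j[b]
  while (a <= length(margin_i) && b <= length(margin_j)) {
    if (ra == 0L) { a <- a + 1L; if (a <= length(margin_i)) ra <- margin_i[a]; next }
    if (rb == 0L) { b <- b + 1L; if (b <= length(margin_j)) rb <- margin_j[b]; next }
    t <- min(ra, rb)
    exy <- exy + t * values_i[a] * values_j[b]
    ra <- ra - t
    rb <- rb - t
  }
  exy / n - mu_i * mu_j
}

# pairwise max-covariance matrix from a complete internal-coded value matrix
maxcov_matrix <- function(V, levels) {
  M <- level_margins(V, levels)
  J <- ncol(V)
  out <- matrix(NA_real_, J, J, dimnames = list(colnames(V), colnames(V)))
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      out[i, j] <- out[j, i] <- max_covariance(M[, i], M[, j])
    }
  }
  out
}

# H_pair / H_item / H_scale from a complete internal value matrix; returns a
# plain list (no bootstrap); used by compute_H, AISP and the bootstrap loop
h_from_values <- function(V, levels) {
  S <- cov_n(V)
  Smax <- maxcov_matrix(V, levels)
  diag(S) <- NA_real_
  H_pair <- S / Smax
  num_item <- rowSums(S, na.rm = TRUE)
  den_item <- rowSums(Smax, na.rm = TRUE)
  upper <- upper.tri(S)
  list(H_pair = H_pair,
       H_item = num_item / den_item,
       H_scale = sum(S[upper]) / sum(Smax[upper]))
}

#' Loevinger scalability coefficients with bootstrap standard errors
#'
#' Computes the item-pair coefficients `H_pair[i,j] = cov(X_i, X_j) /
#' max_covariance(margins)`, the item coefficients `H_item[i]` as the ratio
#' of summed covariances to summed maximum covariances over all other items
#' (equivalently, the normed covariance between the item and its rest
#' score), and the scale coefficient `H_scale` as the same ratio over all
#' item pairs — the weighted mean of the `H_item`. Standard errors come from
#' a nonparametric bootstrap over respondents.
#'
#' @param x a [response_matrix()].
#' @param scale a [scale_definition()] or item-id vector; `NULL` = all items.
#' @param bootstrap_reps bootstrap resamples for standard errors (default
#'   1000); `0` skips standard errors.
#' @param seed integer seed for the bootstrap, or `NULL`.
#' @return object of class `scalability_result`: list with `H_pair`,
#'   `H_item`, `H_scale`, `se_item`, `se_scale`, `item_means` (external
#'   coding), `n_used`, `scale_name`, `label` (rule-of-thumb classification
#'   of `H_scale`) and `se_method`.
#' @export
compute_H <- function(x, scale = NULL, bootstrap_reps = 1000L, seed = NULL) {
  scale <- resolve_scale(x, scale)
  cc <- complete_cases(x, scale)
  V <- cc$values
  n <- nrow(V)
  vars <- apply(V, 2L, stats::var)
  degenerate <- colnames(V)[vars == 0]
  if (length(degenerate)) {
    if (ncol(V) - length(degenerate) < 2L) {
      stop("degenerate item(s) with zero variance: ",
           paste(degenerate, collapse = ", "), call. = FALSE)
    }
    warning("excluding zero-variance item(s): ",
            paste(degenerate, collapse = ", "), call. = FALSE)
    V <- V[, vars > 0, drop = FALSE]
  }
  h <- h_from_values(V, cc$levels)
  se_item <- rep(NA_real_, ncol(V))
  se_scale <- NA_real_
  if (bootstrap_reps > 0L) {
    reps <- with_seed(seed, {
      replicate(bootstrap_reps, {
        idx <- sample.int(n, n, replace = TRUE)
        hb <- h_from_values(V[idx, , drop = FALSE], cc$levels)
        c(hb$H_item, hb$H_scale)
      })
    })
    sds <- apply(reps, 1L, stats::sd)
    se_item <- sds[seq_len(ncol(V))]
    se_scale <- sds[ncol(V) + 1L]
  }
  structure(list(H_pair = h$H_pair, H_item = h$H_item, H_scale = h$H_scale,
                 se_item = stats::setNames(se_item, colnames(V)),
                 se_scale = se_scale,
                 item_means = colMeans(V) + cc$offset,
                 n_used = n, scale_name = scale$name,
                 excluded_items = degenerate,
                 label = classify_H(h$H_scale),
                 se_method = sprintf("nonparametric bootstrap (%d reps)",
                                     bootstrap_reps)),
            class = "scalability_result")
}

#' Rule-of-thumb label for a scale coefficient
#'
#' Half-open bins: below 0.3 unacceptable, `[0.3, 0.4)` weak, `[0.4, 0.5)`
#' moderate, `0.5` and above strong.
#'
#' @param h scalar `H_scale` (at most 1).
#' @return one of `"unacceptable"`, `"weak"`, `"moderate"`, `"strong"`.
#' @export
classify_H <- function(h) {
  stopifnot(is.numeric(h), length(h) == 1L, h <= 1 + 1e-12)
  if (h < 0.3) "unacceptable"
  else if (h < 0.4) "weak"
  else if (h < 0.5) "moderate"
  else "strong"
}

#' @export
print.scalability_result <- function(x, digits = 3L, ...) {
  cat(sprintf("Scalability of scale '%s' (n = %d)\n", x$scale_name, x$n_used))
  tab <- data.frame(mean = round(x$item_means, digits),
                    H_item = round(x$H_item, digits),
                    se = round(x$se_item, digits))
  print(tab)
  cat(sprintf("H_scale = %.3f (se %.3f): %s scale\n",
              x$H_scale, x$se_scale, x$label))
  invisible(x)
}

#' Export a scalability result as a tidy table
#'
#' One row per item (mean score, `H_item`, bootstrap se) plus a final scale
#' row, the shape of a per-item scalability report table.
#'
#' @param x a `scalability_result`.
#' @param path optional CSV path to write to.
#' @return data.frame (invisibly if `path` given).
#' @export
scalability_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "scalability_result"))
  tab <- data.frame(item = c(names(x$H_item), "scale"),
                    mean = c(unname(x$item_means), NA_real_),
                    H = c(unname(x$H_item), x$H_scale),
                    se = c(unname(x$se_item), x$se_scale))
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
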