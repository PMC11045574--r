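#' Rule for merging two items into a composite item
#'
#' A composite item maps each pair of source levels to a composite level
#' through a symmetric `levels x levels` table with the identity on its
#' diagonal. The default is the worst-of-pair rule `max(a, b)`: the
#' composite records the more severe of the two responses.
#'
#' @param source_items character pair of item ids to combine.
#' @param name id of the new composite item.
#' @param mapping optional `levels x levels` integer table (external
#'   coding); `NULL` uses the elementwise maximum.
#' @param levels number of response levels (default 5).
#' @return object of class `composite_rule`.
#' @export
composite_rule <- function(source_items, name, mapping = NULL, levels = 5L) {
  stopifnot(length(source_items) == 2L)
  if (is.null(mapping)) {
    mapping <- outer(seq_len(levels), seq_len(levels), pmax)
  }
  mapping <- as.matrix(mapping)
  if (!all(dim(mapping) == levels)) {
    stop("mapping must be a ", levels, "x", levels, " table", call. = FALSE)
  }
  if (any(mapping != round(mapping)) || any(mapping < 1 | mapping > levels)) {
    stop("mapping cells must be levels in 1..", levels, call. = FALSE)
  }
  if (any(diag(mapping) != seq_len(levels))) {
    stop("mapping must be the identity on its diagonal", call. = FALSE)
  }
  if (!isTRUE(all.equal(mapping, t(mapping)))) {
    stop("mapping must be symmetric in its two arguments", call. = FALSE)
  }
  structure(list(source_items = as.character(source_items),
                 name = as.character(name), mapping = mapping,
                 levels = as.integer(levels)),
            class = "composite_rule")
}

#' Append a composite item built from two source items
#'
#' A respondent missing either source response gets a missing composite.
#'
#' @param x a [response_matrix()].
#' @param rule a [composite_rule()].
#' @param keep_sources keep the source columns (default `TRUE`)?
#' @return a [response_matrix()] with the composite column appended.
#' @export
build_composite <- function(x, rule, keep_sources = TRUE) {
  stopifnot(inherits(x, "response_matrix"), inherits(rule, "composite_rule"))
  absent <- setdiff(rule$source_items, x$item_ids)
  if (length(absent)) stop("source item(s) not in data: ",
                           paste(absent, collapse = ", "), call. = FALSE)
  if (rule$levels != x$levels) stop("rule and data disagree on levels",
                                    call. = FALSE)
  ext <- x$values + x$offset
  a <- ext[, rule$source_items[1L]]
  b <- ext[, rule$source_items[2L]]
  comp <- rep(NA_integer_, nrow(ext))
  ok <- !is.na(a) & !is.na(b)
  comp[ok] <- rule$mapping[cbind(a[ok], b[ok])]
  keep <- if (keep_sources) x$item_ids else setdiff(x$item_ids,
                                                    rule$source_items)
  out <- cbind(ext[, keep, drop = FALSE], comp)
  colnames(out) <- c(keep, rule$name)
  response_matrix(out, levels = x$levels)
}

#' Level sum score with 0-100 transform
#'
#' The level sum score (LSS) assigns each response its external level (1 =
#' least severe ... 5 = most severe) and sums over the scale's items; the
#' transformed score rescales the attainable range to 0-100, higher =
#' more problems. For `J` items on `L` levels:
#' `transformed = (raw - J) / (J * (L - 1)) * 100`.
#'
#' @inheritParams compute_H
#' @return object of class `lss_result`: data.frame `scores` with `raw`
#'   and `transformed` per complete respondent, `scale_name`, `n_used`,
#'   `n_excluded` (respondents missing a scale item), and the row indices
#'   of retained respondents (`respondent`).
#' @export
compute_lss <- function(x, scale = NULL) {
  scale <- resolve_scale(x, scale)
  vals <- x$values[, scale$items, drop = FALSE]
  keep <- which(rowSums(is.na(vals)) == 0L)
  if (!length(keep)) stop("no complete cases on scale '", scale$name, "'",
                          call. = FALSE)
  J <- length(scale$items)
  raw <- rowSums(vals[keep, , drop = FALSE]) + J * x$offset
  transformed <- (raw - J) / (J * (x$levels - 1)) * 100
  structure(list(scores = data.frame(respondent = keep, raw = as.integer(raw),
                                     transformed = transformed),
                 scale_name = scale$name, n_used = length(keep),
                 n_excluded = nrow(vals) - length(keep)),
            class = "lss_result")
}

#' @export
print.lss_result <- function(x, ...) {
  cat(sprintf("LSS for scale '%s': n = %d (%d excluded), median %.2f, IQR %.2f-%.2f\n",
              x$scale_name, x$n_used, x$n_excluded,
              stats::median(x$scores$transformed),
              stats::quantile(x$scores$transformed, 0.25),
              stats::quantile(x$scores$transformed, 0.75)))
  invisible(x)
}

#' Median and interquartile range of the LSS per group
#'
#' @param lss an [compute_lss()] result.
#' @param groups per-respondent labels (aligned with the full data the LSS
#'   was computed from; subset to complete cases internally).
#' @return data.frame with one row per group level: n, median, q1, q3 of
#'   the transformed score.
#' @export
lss_group_summary <- function(lss, groups) {
  stopifnot(inherits(lss, "lss_result"))
  g <- as.factor(groups)[lss$scores$respondent]
  do.call(rbind, lapply(levels(g), function(lv) {
    s <- lss$scores$transformed[g == lv]
    data.frame(group = lv, n = length(s), median = stats::median(s),
               q1 = unname(stats::quantile(s, 0.25)),
               q3 = unname(stats::quantile(s, 0.75)))
  }))
}

#' Cronbach's alpha
#'
#' `alpha = J/(J-1) * (1 - sum var(X_j) / var(sum X_j))`.
#'
#' @inheritParams compute_H
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(x, scale = NULL) {
  scale <- resolve_scale(x, scale)
  V <- complete_cases(x, scale)$values
  S <- cov_n(V)
  total_var <- sum(S)
  if (total_var <= 0) stop("zero total variance: reliability undefined",
                           call. = FALSE)
  J <- ncol(V)
  J / (J - 1) * (1 - sum(diag(S)) / total_var)
}

#' Guttman's lambda-2
#'
#' `lambda2 = (C2 + sqrt(J/(J-1) * sum of squared off-diagonal
#' covariances)) / var(sum X_j)` with `C2` the sum of off-diagonal
#' covariances; never smaller than Cronbach's alpha.
#'
#' @inheritParams compute_H
#' @return scalar lambda-2.
#' @export
guttman_lambda2 <- function(x, scale = NULL) {
  scale <- resolve_scale(x, scale)
  V <- complete_cases(x, scale)$values
  S <- cov_n(V)
  total_var <- sum(S)
  if (total_var <= 0) stop("zero total variance: reliability undefined",
                           call. = FALSE)
  J <- ncol(V)
  off <- S
  diag(off) <- 0
  (sum(off) + sqrt(J / (J - 1) * sum(off^2))) / total_var
}
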