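# per-pair violation scan for a fixed item set; returns the pair table.
# Items are compared in ascending order of overall mean; a violation occurs
# in a rest-score group when the conditional mean of the "easier" item
# exceeds that of the "harder" item by more than minvi_pair.
miio_pair_scan <- function(V, levels, minsize, minvi_pair, alpha) {
  items <- colnames(V)
  mu <- colMeans(V)
  ord <- order(mu, seq_along(mu))   # tied means -> original item index
  zcrit <- stats::qnorm(1 - alpha)
  out <- list()
  for (a in seq_len(length(ord) - 1L)) {
    for (b in (a + 1L):length(ord)) {
      i <- items[ord[a]]   # lower overall mean
      j <- items[ord[b]]
      rest <- rowSums(V[, setdiff(items, c(i, j)), drop = FALSE])
      idx <- merge_score_groups(rest, minsize)
      G <- max(idx)
      ac <- 0L; vi <- 0L; zsig <- 0L; maxvi <- 0; sum_vi <- 0
      for (g in seq_len(G)) {
        sel <- idx == g
        n_g <- sum(sel)
        if (n_g == 0L) next
        ac <- ac + 1L
        d <- mean(V[sel, i]) - mean(V[sel, j])
        if (d > minvi_pair) {
          vi <- vi + 1L
          maxvi <- max(maxvi, d)
          sum_vi <- sum_vi + d
          # one-sided Welch t-test that E[X_i|g] > E[X_j|g] (paired data,
          # conservative unpaired form)
          s2 <- stats::var(V[sel, i]) / n_g + stats::var(V[sel, j]) / n_g
          if (s2 > 0 && d / sqrt(s2) > zcrit) zsig <- zsig + 1L
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        easier = i, harder = j, ac = ac, vi = vi, maxvi = maxvi,
        sum_vi = sum_vi, zsig = zsig)
    }
  }
  pair_tab <- do.call(rbind, out)
  rownames(pair_tab) <- NULL
  pair_tab
}

# fold the pair table into per-item totals and crit diagnostics
miio_item_summary <- function(pair_tab, V, levels) {
  H <- h_from_values(V, levels)
  items <- colnames(V)
  rows <- lapply(items, function(it) {
    sel <- pair_tab$easier == it | pair_tab$harder == it
    ac <- sum(pair_tab$ac[sel]); vi <- sum(pair_tab$vi[sel])
    maxvi <- if (any(sel)) max(pair_tab$maxvi[sel]) else 0
    sum_vi <- sum(pair_tab$sum_vi[sel]); zsig <- sum(pair_tab$zsig[sel])
    data.frame(item = it, H_item = H$H_item[it], ac = ac, vi = vi,
               maxvi = maxvi, sum_vi = sum_vi, zsig = zsig,
               crit = crit_value(H$H_item[it], ac, vi, maxvi, sum_vi, zsig))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Check manifest invariant item ordering (MIIO)
#'
#' Items are ordered by their overall mean scores; invariant item ordering
#' requires that ordering to hold within every rest-score group (formed on
#' the total score excluding both items of a pair). A reversal of the
#' conditional means larger than `m x 0.03` (the number of item steps times
#' 0.03; 0.12 for five-level items) counts as a violation. Backward
#' selection then repeatedly removes the item with the most violations
#' (ties broken by larger `crit`, then lower item index) until no
#' violations remain. The H^T ordering-accuracy coefficient
#' ([compute_HT()]) is attached.
#'
#' @inheritParams check_monotonicity
#' @param minvi_pair violation threshold per pair comparison; default
#'   `(levels - 1) * 0.03`.
#' @return object of class `iio_result`: `item_order` (ascending overall
#'   mean), `pair_violations` table, per-item `summary` (vi, crit),
#'   `removed_items` (in removal order), `kept_items`, `HT`, `HT_label`,
#'   `n_used` and settings.
#' @export
check_miio <- function(x, scale = NULL, minsize = NULL, alpha = 0.05,
                       minvi_pair = NULL) {
  scale <- resolve_scale(x, scale)
  cc <- complete_cases(x, scale)
  V <- cc$values
  if (is.null(minsize)) minsize <- default_minsize(nrow(V))
  if (is.null(minvi_pair)) minvi_pair <- (cc$levels - 1L) * 0.03
  mu <- colMeans(V)
  item_order <- colnames(V)[order(mu, seq_len(ncol(V)))]
  pair_tab <- miio_pair_scan(V, cc$levels, minsize, minvi_pair, alpha)
  summary <- miio_item_summary(pair_tab, V, cc$levels)
  # backward elimination on a shrinking item set
  keep <- colnames(V)
  removed <- character(0)
  cur <- summary
  while (length(keep) > 2L && any(cur$vi > 0L)) {
    worst <- cur[order(-cur$vi, -cur$crit,
                       match(cur$item, colnames(V))), ][1L, "item"]
    removed <- c(removed, worst)
    keep <- setdiff(keep, worst)
    Vk <- V[, keep, drop = FALSE]
    cur <- miio_item_summary(
      miio_pair_scan(Vk, cc$levels, minsize, minvi_pair, alpha),
      Vk, cc$levels)
  }
  ht <- compute_HT(x, scale)
  structure(list(item_order = item_order, pair_violations = pair_tab,
                 summary = summary, removed_items = removed,
                 kept_items = keep, final_summary = cur,
                 HT = as.numeric(ht), HT_label = attr(ht, "label"),
                 n_used = nrow(V), scale_name = scale$name,
                 settings = list(minsize = minsize, minvi_pair = minvi_pair,
                                 alpha = alpha)),
            class = "iio_result")
}

#' @export
print.iio_result <- function(x, ...) {
  cat(sprintf("Manifest invariant item ordering, scale '%s' (n = %d)\n",
              x$scale_name, x$n_used))
  print(x$summary[, c("item", "vi", "crit")], digits = 3L)
  if (length(x$removed_items)) {
    cat("removed by backward selection:",
        paste(x$removed_items, collapse = ", "), "\n")
  }
  cat(sprintf("H^T = %.3f (%s)\n", x$HT, x$HT_label))
  invisible(x)
}

#' H^T: scalability of the transposed data matrix
#'
#' The ordering-accuracy coefficient: Loevinger's scale coefficient applied
#' to the transposed response matrix, so respondents play the role of items
#' and vice versa. High H^T means respondents agree on the difficulty
#' ordering of the items. Respondents with constant responses carry no
#' ordering information (zero variance across items) and are excluded, with
#' the count reported.
#'
#' @inheritParams compute_H
#' @return scalar H^T with attributes `label` (rule of thumb: below 0.3
#'   items cannot be ordered; 0.3-0.4 low accuracy; 0.4-0.5 accurate; 0.5
#'   and above highly accurate) and `n_excluded`.
#' @export
compute_HT <- function(x, scale = NULL) {
  scale <- resolve_scale(x, scale)
  if (length(scale$items) < 3L) stop("H^T needs at least 3 items", call. = FALSE)
  cc <- complete_cases(x, scale)
  V <- cc$values
  if (nrow(V) < 2L) stop("H^T needs at least 2 respondents", call. = FALSE)
  constant <- apply(V, 1L, function(r) max(r) == min(r))
  n_excluded <- sum(constant)
  V <- V[!constant, , drop = FALSE]
  if (nrow(V) < 2L) stop("fewer than 2 non-constant respondents", call. = FALSE)
  J <- ncol(V)
  mu <- rowMeans(V)
  # sum over respondent pairs of cov_n equals a column-sum identity; the
  # max-covariance of a pair is the covariance of their sorted rows
  Ssorted <- t(apply(V, 1L, sort))
  pair_sum <- function(M) (sum(colSums(M)^2) - sum(M^2)) / 2
  mean_sum <- (sum(mu)^2 - sum(mu^2)) / 2
  num <- pair_sum(V) / J - mean_sum
  den <- pair_sum(Ssorted) / J - mean_sum
  ht <- num / den
  label <- if (ht < 0.3) "items cannot be ordered" else if (ht < 0.4) {
    "low accuracy"
  } else if (ht < 0.5) "accurate" else "highly accurate"
  structure(ht, label = label, n_excluded = n_excluded)
}
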