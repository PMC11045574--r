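# ---- internal machinery ----------------------------------------------------
# AISP never needs the raw data beyond the pairwise covariance / max-covariance
# matrices and a standard error per pair, so these are computed once and the
# greedy search itself is pure arithmetic on them.

precompute_pair_stats <- function(V, levels, se_reps = 200L, seed = NULL) {
  n <- nrow(V)
  S <- cov_n(V)
  Smax <- maxcov_matrix(V, levels)
  diag(S) <- NA_real_
  H_pair <- S / Smax
  se_pair <- matrix(NA_real_, ncol(V), ncol(V))
  if (se_reps > 0L) {
    reps <- with_seed(seed, {
      replicate(se_reps, {
        idx <- sample.int(n, n, replace = TRUE)
        Vb <- V[idx, , drop = FALSE]
        Sb <- cov_n(Vb)
        Hb <- Sb / maxcov_matrix(Vb, levels)
        Hb[upper.tri(Hb)]
      })
    })
    if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1L)  # J = 2
    sds <- apply(reps, 1L, stats::sd)
    se_pair[upper.tri(se_pair)] <- sds
    se_pair[lower.tri(se_pair)] <- t(se_pair)[lower.tri(se_pair)]
  }
  list(S = S, Smax = Smax, H_pair = H_pair, se_pair = se_pair, n = n)
}

h_item_sub <- function(ps, members) {
  vapply(members, function(i) {
    oth <- setdiff(members, i)
    sum(ps$S[i, oth]) / sum(ps$Smax[i, oth])
  }, numeric(1L))
}

h_scale_sub <- function(ps, members) {
  sub <- ps$S[members, members]
  subm <- ps$Smax[members, members]
  up <- upper.tri(sub)
  sum(sub[up]) / sum(subm[up])
}

# greedy scale construction on precomputed pair statistics
aisp_core <- function(ps, lower_bound, alpha = 0.05) {
  J <- ncol(ps$H_pair)
  zcrit <- stats::qnorm(1 - alpha)
  zpair <- ifelse(ps$se_pair > 0, ps$H_pair / ps$se_pair,
                  ifelse(ps$H_pair > 0, Inf, -Inf))
  signif_pos <- !is.na(zpair) & zpair > zcrit
  eps <- 1e-12
  assignment <- integer(J)
  pool <- seq_len(J)
  label <- 0L
  banned <- matrix(FALSE, J, J)   # seed pairs whose scale collapsed
  repeat {
    # admissible seed pairs within the pool
    best <- NULL
    best_h <- -Inf
    for (i in pool) {
      for (j in pool) {
        if (j <= i || banned[i, j]) next
        h <- ps$H_pair[i, j]
        if (signif_pos[i, j] && h >= lower_bound - eps && h > best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    if (is.null(best)) break
    members <- best
    repeat {
      cand <- setdiff(pool, members)
      cand <- cand[vapply(cand, function(k) {
        all(signif_pos[k, members]) &&
          h_item_sub(ps, c(members, k))[length(members) + 1L] >= lower_bound - eps
      }, logical(1L))]
      if (!length(cand)) break
      hs <- vapply(cand, function(k) h_scale_sub(ps, c(members, k)), numeric(1L))
      members <- c(members, cand[which.max(hs)])  # which.max ties -> lower index
    }
    # post-hoc pruning: drop members whose within-scale H_item fell below the
    # bound, worst first, until the invariant holds
    while (length(members) >= 2L) {
      hi <- h_item_sub(ps, members)
      if (min(hi) >= lower_bound - eps) break
      members <- members[-which.min(hi)]
    }
    if (length(members) < 2L ||
        min(h_item_sub(ps, members)) < lower_bound - eps) {
      banned[best[1L], best[2L]] <- TRUE   # collapsed: never reseed this pair
      next
    }
    label <- label + 1L
    assignment[members] <- label
    pool <- setdiff(pool, members)
    if (length(pool) < 2L) break
  }
  assignment
}

#' Automated item selection procedure (AISP)
#'
#' Greedy bottom-up partition of the items into Mokken scales at scalability
#' lower bound `c`: a scale is seeded by the admissible item pair with the
#' largest `H_pair` (significantly positive at `alpha`, one-sided, and at
#' least `c`), then grown by repeatedly adding the item that maximises the
#' candidate scale's `H_scale` subject to the entrant's within-scale
#' `H_item >= c` and significantly positive pairwise `H` with every current
#' member. When no item qualifies, the scale closes and construction
#' restarts on the remainder; leftover items are labelled 0 (unscalable).
#' After a scale closes, members whose within-scale `H_item` dropped below
#' `c` are pruned worst-first, so every returned scale satisfies the
#' membership criterion.
#'
#' The significance test is a one-sided z-test of `H_pair > 0` using a
#' seeded nonparametric bootstrap standard error (`se_reps` resamples).
#'
#' @param x a [response_matrix()].
#' @param lower_bound scalability lower bound `c` in (0, 1).
#' @param alpha one-sided significance level (default 0.05).
#' @param se_reps bootstrap resamples for the pairwise standard errors
#'   (default 200).
#' @param seed integer seed for the bootstrap, or `NULL`.
#' @return object of class `aisp_partition`: `lower_bound`, named integer
#'   `assignment` (0 = unscalable, 1 = first scale, 2 = second scale, ...),
#'   `n_used`, and `method` metadata.
#' @export
run_aisp <- function(x, lower_bound, alpha = 0.05, se_reps = 200L,
                     seed = NULL) {
  stopifnot(lower_bound > 0, lower_bound < 1)
  cc <- complete_cases(x, NULL)
  V <- cc$values
  if (sum(apply(V, 2L, stats::var) > 0) < 2L) {
    stop("need at least 2 items with positive variance", call. = FALSE)
  }
  ps <- precompute_pair_stats(V, cc$levels, se_reps = se_reps, seed = seed)
  assignment <- aisp_core(ps, lower_bound, alpha)
  structure(list(lower_bound = lower_bound,
                 assignment = stats::setNames(assignment, colnames(V)),
                 n_used = nrow(V),
                 method = list(variant = "greedy", alpha = alpha,
                               se_reps = se_reps, seed = seed)),
            class = "aisp_partition")
}

#' @export
print.aisp_partition <- function(x, ...) {
  cat(sprintf("AISP partition at lower bound %.3f (n = %d)\n",
              x$lower_bound, x$n_used))
  print(x$assignment)
  invisible(x)
}

#' Sweep the AISP lower bound over a grid
#'
#' Runs [run_aisp()] once per bound on shared precomputed pair statistics
#' and tabulates the assignments items-by-bounds (0 = unscalable,
#' 1 = first scale, 2 = second scale, ...).
#'
#' @inheritParams run_aisp
#' @param bounds strictly increasing lower-bound grid within (0, 1), e.g.
#'   `seq(0.1, 0.6, by = 0.05)`.
#' @param path optional CSV path for the items-by-bounds table.
#' @return object of class `aisp_sweep`: an items x bounds integer matrix
#'   (`table`) plus the bounds and method metadata.
#' @export
sweep_lower_bounds <- function(x, bounds, alpha = 0.05, se_reps = 200L,
                               seed = NULL, path = NULL) {
  if (!length(bounds)) stop("bounds must be non-empty", call. = FALSE)
  if (any(bounds <= 0 | bounds >= 1) || is.unsorted(bounds, strictly = TRUE)) {
    stop("bounds must be strictly increasing within (0, 1)", call. = FALSE)
  }
  cc <- complete_cases(x, NULL)
  ps <- precompute_pair_stats(cc$values, cc$levels, se_reps = se_reps,
                              seed = seed)
  tab <- vapply(bounds, function(b) aisp_core(ps, b, alpha),
                integer(ncol(cc$values)))
  dimnames(tab) <- list(colnames(cc$values), format(bounds, trim = TRUE))
  out <- structure(list(table = tab, bounds = bounds, n_used = nrow(cc$values),
                        method = list(variant = "greedy", alpha = alpha,
                                      se_reps = se_reps, seed = seed)),
                   class = "aisp_sweep")
  if (!is.null(path)) {
    utils::write.csv(data.frame(item = rownames(tab), tab, check.names = FALSE),
                     path, row.names = FALSE)
  }
  out
}

#' @export
print.aisp_sweep <- function(x, ...) {
  cat("AISP lower-bound sweep (rows = items, columns = bounds)\n")
  print(x$table)
  invisible(x)
}

#' Find the lower bound at which a single scale first breaks up
#'
#' Scans the lower-bound grid of resolution `step` from below and returns
#' the smallest grid value at which the AISP partition is no longer a
#' single all-items scale — i.e. first yields more than one scale or any
#' unscalable item. Returns `NA` with attribute `no_split = TRUE` when no
#' such bound exists on the grid below 1.
#'
#' @inheritParams run_aisp
#' @param step grid resolution (default 0.001).
#' @return the threshold bound (scalar), or `NA` if the scale never splits.
#' @export
find_split_threshold <- function(x, step = 0.001, alpha = 0.05,
                                 se_reps = 200L, seed = NULL) {
  stopifnot(step > 0)
  cc <- complete_cases(x, NULL)
  ps <- precompute_pair_stats(cc$values, cc$levels, se_reps = se_reps,
                              seed = seed)
  grid <- seq(step, 1 - step / 2, by = step)
  for (b in grid) {
    a <- aisp_core(ps, b, alpha)
    if (max(a) > 1L || any(a == 0L)) return(b)
  }
  structure(NA_real_, no_split = TRUE)
}
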