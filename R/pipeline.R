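#' Two-sample rank-sum (Mann-Whitney/Wilcoxon) test
#'
#' Mid-rank handling of ties and the tie-corrected normal approximation,
#' two-sided. The statistic is the Mann-Whitney U of the first group
#' (number of (a, b) pairs with a > b, ties counted 1/2). When every value
#' in both groups is tied the test is vacuous and p = 1.
#'
#' @param scores_a,scores_b numeric score vectors, both non-empty.
#' @return list with `statistic` (U for the first group) and `p_value`.
#' @export
rank_sum_test <- function(scores_a, scores_b) {
  if (!length(scores_a) || !length(scores_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  u <- sum(vapply(scores_a, function(a) {
    sum(a > scores_b) + 0.5 * sum(a == scores_b)
  }, numeric(1L)))
  if (max(c(scores_a, scores_b)) == min(c(scores_a, scores_b))) {
    return(list(statistic = u, p_value = 1))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, exact = FALSE, correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Spearman rank correlation with mid-rank ties
#'
#' @param scores,external paired numeric vectors, at least 3 pairs.
#' @return rho, or `NA` (with a warning) when either vector is constant.
#' @export
spearman_correlation <- function(scores, external) {
  if (length(scores) != length(external) || length(scores) < 3L) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (stats::sd(scores) == 0 || stats::sd(external) == 0) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(scores, external, method = "spearman")
}

#' Configuration for the full analysis pipeline
#'
#' @param scales named list of item-id vectors defining the full scale and
#'   any subscales, e.g. `list(full = ..., psychosocial = ..., physical =
#'   ...)`; the first entry is taken as the full scale for the AISP sweep.
#' @param bounds AISP lower-bound grid (default `seq(0.1, 0.6, 0.05)`).
#' @param split_step grid resolution of the split-threshold search.
#' @param minvi monotonicity violation threshold (default 0.03).
#' @param minsize rest-score group floor; `NULL` = sample-size ladder.
#' @param bootstrap_reps bootstrap resamples for H standard errors.
#' @param aisp_se_reps bootstrap resamples inside AISP.
#' @param alpha significance level for violation tests and AISP.
#' @param known_groups label columns compared on the LSS (rank-sum tests).
#' @param strata label columns the scaling analyses are stratified by.
#' @param stratum_floor smallest stratum analysed (default 500).
#' @param seed integer seed recorded in, and used by, every stage.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(scales,
                            bounds = seq(0.1, 0.6, by = 0.05),
                            split_step = 0.001,
                            minvi = 0.03,
                            minsize = NULL,
                            bootstrap_reps = 1000L,
                            aisp_se_reps = 200L,
                            alpha = 0.05,
                            known_groups = c("carer", "long_term_condition"),
                            strata = c("country", "carer",
                                       "long_term_condition", "female",
                                       "age_band"),
                            stratum_floor = 500L,
                            seed = 1L) {
  stopifnot(is.list(scales), length(scales) >= 1L, !is.null(names(scales)))
  structure(list(scales = scales, bounds = bounds, split_step = split_step,
                 minvi = minvi, minsize = minsize,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 aisp_se_reps = as.integer(aisp_se_reps), alpha = alpha,
                 known_groups = known_groups, strata = strata,
                 stratum_floor = as.integer(stratum_floor),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML or JSON file
#'
#' The file names the item columns per scale and any of the
#' [analysis_config()] fields to override.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(analysis_config, raw)
}

# one stratum's (or the pooled sample's) scaling summary
scale_block <- function(x, scale_items, name, cfg) {
  sc <- scale_definition(name, scale_items)
  H <- compute_H(x, sc, bootstrap_reps = cfg$bootstrap_reps, seed = cfg$seed)
  mono <- check_monotonicity(x, sc, minvi = cfg$minvi, minsize = cfg$minsize,
                             alpha = cfg$alpha)
  iio <- check_miio(x, sc, minsize = cfg$minsize, alpha = cfg$alpha)
  lss <- compute_lss(x, sc)
  list(scalability = H, monotonicity = mono, iio = iio, lss = lss,
       alpha_reliability = cronbach_alpha(x, sc),
       lambda2 = guttman_lambda2(x, sc))
}

#' Run the complete scaling analysis
#'
#' For the pooled sample: Loevinger scalability (with bootstrap standard
#' errors) per scale, the AISP lower-bound sweep and split-threshold search
#' on the full scale, manifest monotonicity, manifest invariant item
#' ordering with H^T, reliability, level sum scores, and rank-sum
#' comparisons of the LSS across the known groups. Scaling coefficients
#' (H_S and H^T per scale) are then recomputed within every stratum whose
#' size reaches `stratum_floor`; smaller strata are skipped with a logged
#' reason. The returned bundle carries a manifest (config echo including
#' the seed) from which the whole analysis can be reproduced.
#'
#' @param x a [response_matrix()].
#' @param labels a [group_labels()] data.frame aligned with `x`.
#' @param config an [analysis_config()].
#' @param out_dir optional directory; when given, CSV tables, a JSON
#'   manifest and a plain-text log are written there.
#' @return list of class `scalemok_report`.
#' @export
run_full_analysis <- function(x, labels, config, out_dir = NULL) {
  stopifnot(inherits(x, "response_matrix"),
            inherits(config, "analysis_config"))
  labels <- as.data.frame(labels)
  if (nrow(labels) != nrow(x$values)) {
    stop("labels must have one row per respondent", call. = FALSE)
  }
  absent <- setdiff(c(config$known_groups, config$strata), names(labels))
  if (length(absent)) {
    stop("label column(s) not found: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  scales <- config$scales
  pooled <- lapply(names(scales), function(nm) {
    scale_block(x, scales[[nm]], nm, config)
  })
  names(pooled) <- names(scales)
  for (nm in names(pooled)) {
    note("scale '%s': n = %d complete cases", nm,
         pooled[[nm]]$scalability$n_used)
  }

  full_items <- scales[[1L]]
  x_full <- structure(list(values = x$values[, full_items, drop = FALSE],
                           item_ids = full_items, levels = x$levels,
                           offset = x$offset), class = "response_matrix")
  sweep <- sweep_lower_bounds(x_full, config$bounds, alpha = config$alpha,
                              se_reps = config$aisp_se_reps,
                              seed = config$seed)
  split <- find_split_threshold(x_full, step = config$split_step,
                                alpha = config$alpha,
                                se_reps = config$aisp_se_reps,
                                seed = config$seed)

  # known-group LSS comparisons per scale (Table-5 shape)
  known <- lapply(names(scales), function(nm) {
    lss <- pooled[[nm]]$lss
    do.call(rbind, lapply(config$known_groups, function(v) {
      g <- labels[[v]][lss$scores$respondent]
      lv <- levels(as.factor(g))
      if (length(lv) != 2L) {
        note("known group '%s' skipped for scale '%s': needs 2 levels", v, nm)
        return(NULL)
      }
      s0 <- lss$scores$transformed[g == lv[1L]]
      s1 <- lss$scores$transformed[g == lv[2L]]
      rs <- rank_sum_test(s1, s0)
      data.frame(scale = nm, variable = v,
                 reference = lv[1L], comparison = lv[2L],
                 n_ref = length(s0), n_cmp = length(s1),
                 median_ref = stats::median(s0),
                 median_cmp = stats::median(s1),
                 U = rs$statistic, p_value = rs$p_value)
    }))
  })
  known <- do.call(rbind, known)

  # stratified scaling coefficients
  strat <- list()
  for (v in config$strata) {
    for (lv in levels(as.factor(labels[[v]]))) {
      keep <- which(!is.na(labels[[v]]) & labels[[v]] == lv)
      if (length(keep) < config$stratum_floor) {
        note("stratum %s=%s skipped: n = %d below floor %d", v, lv,
             length(keep), config$stratum_floor)
        next
      }
      xs <- structure(list(values = x$values[keep, , drop = FALSE],
                           item_ids = x$item_ids, levels = x$levels,
                           offset = x$offset), class = "response_matrix")
      row <- lapply(names(scales), function(nm) {
        h <- tryCatch(
          compute_H(xs, scale_definition(nm, scales[[nm]]),
                    bootstrap_reps = config$bootstrap_reps,
                    seed = config$seed),
          error = function(e) NULL)
        ht <- tryCatch(compute_HT(xs, scale_definition(nm, scales[[nm]])),
                       error = function(e) NA_real_)
        if (is.null(h)) return(NULL)
        data.frame(stratum_var = v, stratum = lv, scale = nm,
                   n = h$n_used, H_scale = h$H_scale, se = h$se_scale,
                   label = h$label, HT = as.numeric(ht))
      })
      strat[[length(strat) + 1L]] <- do.call(rbind, row)
    }
  }
  strat <- if (length(strat)) do.call(rbind, strat) else NULL

  manifest <- list(package = "scalemok",
                   version = as.character(utils::packageVersion("scalemok")),
                   seed = config$seed,
                   config = unclass(config),
                   n_respondents = nrow(x$values),
                   items = x$item_ids,
                   aisp = sweep$method,
                   se_method = pooled[[1L]]$scalability$se_method,
                   multiple_testing = "none (per-comparison alpha)")
  report <- structure(list(pooled = pooled, aisp_sweep = sweep,
                           split_threshold = split, known_groups = known,
                           stratified = strat, manifest = manifest,
                           log = log),
                      class = "scalemok_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.scalemok_report <- function(x, ...) {
  cat("scalemok analysis report\n")
  for (nm in names(x$pooled)) {
    b <- x$pooled[[nm]]
    cat(sprintf("  %s: H_S = %.3f (%s), monotonicity vi = %d, H^T = %.3f, alpha = %.3f\n",
                nm, b$scalability$H_scale, b$scalability$label,
                sum(b$monotonicity$summary$vi), b$iio$HT,
                b$alpha_reliability))
  }
  cat(sprintf("  AISP split threshold: %s\n",
              ifelse(is.na(x$split_threshold), "no split",
                     format(x$split_threshold))))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' CSV tables (scalability, AISP sweep, monotonicity, MIIO, known-group
#' LSS, stratified coefficients), a JSON manifest with the full config echo
#' and seed, and a plain-text log.
#'
#' @param report a `scalemok_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "scalemok_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$pooled)) {
    b <- report$pooled[[nm]]
    scalability_table(b$scalability,
                      file.path(out_dir, paste0("scalability_", nm, ".csv")))
    utils::write.csv(b$monotonicity$summary,
                     file.path(out_dir, paste0("monotonicity_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(b$iio$summary,
                     file.path(out_dir, paste0("miio_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(irf_table(b$monotonicity),
                     file.path(out_dir, paste0("irf_", nm, ".csv")),
                     row.names = FALSE)
  }
  sw <- report$aisp_sweep
  utils::write.csv(data.frame(item = rownames(sw$table), sw$table,
                              check.names = FALSE),
                   file.path(out_dir, "aisp_sweep.csv"), row.names = FALSE)
  if (!is.null(report$known_groups)) {
    utils::write.csv(report$known_groups,
                     file.path(out_dir, "known_groups.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$stratified)) {
    utils::write.csv(report$stratified,
                     file.path(out_dir, "stratified.csv"), row.names = FALSE)
  }
  manifest <- report$manifest
  manifest$split_threshold <- as.numeric(report$split_threshold)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(report$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
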