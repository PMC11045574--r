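#' Configuration of the graded-response-model data generator
#'
#' The generator emulates a 9-item, five-level health-and-wellbeing
#' questionnaire: a dominant common factor realised as two correlated
#' cluster factors (6 psychosocial + 3 physical items), graded response
#' sampling `P(X_j >= x | theta) = logistic(a_j (theta - b_jx))`, and
#' known-group shifts of the latent trait for carers and respondents with a
#' long-term condition. Defaults: discrimination 2.8 on every item and
#' difficulty locations solved (against the analytic marginals) so the item
#' means sit around 1.8-2.9 on the external 1-5 scale, the spread typical
#' of a mixed physical/psychosocial wellbeing instrument in a general +
#' patient sample; between-cluster latent correlation 0.5, N = 3000,
#' long-term-condition prevalence 0.735 with trait shift +0.5, carer
#' prevalence 0.30 with shift +0.3, 55% women, country mix US/AUS/UK
#' roughly 27/15/58%. Under these defaults the subscales scale strongly
#' (H about 0.7) and the full scale around 0.55.
#'
#' @param J number of items.
#' @param levels response levels per item (default 5).
#' @param a positive discriminations, length `J` (recycled).
#' @param b `J x (levels-1)` matrix of strictly increasing thresholds per
#'   item; `NULL` builds `base_thresholds` shifted by `item_locations`.
#' @param item_locations per-item difficulty locations added to
#'   `base_thresholds` (default spreads the item means the way a mixed
#'   physical/psychosocial instrument does).
#' @param base_thresholds increasing vector of `levels - 1` step thresholds.
#' @param cluster item-to-factor assignment (integers starting at 1).
#' @param factor_correlation latent correlation between cluster factors.
#' @param group_effects named trait shifts, e.g.
#'   `c(long_term_condition = 0.5, carer = 0.3)`.
#' @param group_prevalences named prevalences for the binary labels
#'   (`long_term_condition`, `carer`, `female`).
#' @param country_prevalences named multinomial prevalences for the country
#'   label (must sum to 1).
#' @param N respondents to draw.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param item_ids item names; defaults to instrument-style names.
#' @return object of class `grm_config`.
#' @export
grm_config <- function(J = 9L, levels = 5L, a = 2.8,
                       b = NULL,
                       item_locations = NULL,
                       base_thresholds = c(-1.5, -0.5, 0.5, 1.5),
                       cluster = NULL,
                       factor_correlation = 0.5,
                       group_effects = c(long_term_condition = 0.5,
                                         carer = 0.3),
                       group_prevalences = c(long_term_condition = 0.735,
                                             carer = 0.30, female = 0.55),
                       country_prevalences = c(US = 0.27, AUS = 0.154,
                                               UK = 0.576),
                       N = 3000L, seed = NULL, item_ids = NULL) {
  J <- as.integer(J)
  if (is.null(cluster)) {
    cluster <- if (J == 9L) c(rep(1L, 6L), rep(2L, 3L)) else rep(1L, J)
  }
  stopifnot(length(cluster) == J, abs(factor_correlation) <= 1,
            all(group_prevalences >= 0 & group_prevalences <= 1), N >= 1)
  a <- rep_len(a, J)
  if (any(a <= 0)) stop("discriminations must be positive", call. = FALSE)
  if (is.null(item_ids)) {
    item_ids <- if (J == 9L) {
      c("anxiety", "sad", "fatigue", "loneliness", "cognition", "control",
        "pain", "daily_activities", "mobility")
    } else paste0("item", seq_len(J))
  }
  if (is.null(b)) {
    if (length(base_thresholds) != levels - 1L) {
      stop("base_thresholds must have levels - 1 entries", call. = FALSE)
    }
    if (is.null(item_locations)) {
      item_locations <- if (J == 9L) {
        c(anxiety = 1.07, sad = 0.99, fatigue = 0.54, loneliness = 1.30,
          cognition = 0.82, control = 1.44, pain = 1.35,
          daily_activities = 1.72, mobility = 1.87)
      } else {
        seq(-0.6, 0.6, length.out = J)
      }
    }
    b <- outer(rep_len(unname(item_locations), J), base_thresholds, "+")
  }
  b <- as.matrix(b)
  if (!all(dim(b) == c(J, levels - 1L))) {
    stop("b must be a J x (levels-1) matrix", call. = FALSE)
  }
  if (any(apply(b, 1L, function(r) any(diff(r) <= 0)))) {
    stop("thresholds must be strictly increasing per item", call. = FALSE)
  }
  if (abs(sum(country_prevalences) - 1) > 1e-8) {
    stop("country prevalences must sum to 1", call. = FALSE)
  }
  structure(list(J = J, levels = as.integer(levels), a = a, b = b,
                 cluster = as.integer(cluster),
                 factor_correlation = factor_correlation,
                 group_effects = group_effects,
                 group_prevalences = group_prevalences,
                 country_prevalences = country_prevalences,
                 N = as.integer(N), seed = seed, item_ids = item_ids),
            class = "grm_config")
}

#' Specification of an injected model violation
#'
#' Two adversarial perturbations for validating the diagnostics:
#' `"nonmonotone_isrf"` lowers the target item's step-`step` cumulative
#' probability by `depth` for respondents whose trait lies in `interval`
#' (later steps are clamped so the cumulative system stays valid), breaking
#' monotonicity. `"crossing_irf"` shifts the target item's difficulty by
#' `-4 * depth` below the interval midpoint and `+4 * depth` above it
#' (within `interval`), flattening its response functions so they cross
#' those of the other items and the item ordering reverses across
#' rest-score groups.
#'
#' @param item target item id.
#' @param type `"nonmonotone_isrf"` or `"crossing_irf"`.
#' @param depth probability decrement in `[0, 1)` (`0` = no perturbation).
#' @param step which item step (`1..levels-1`) the ISRF violation hits.
#' @param interval trait interval affected, increasing pair.
#' @return object of class `violation_spec`.
#' @export
violation_spec <- function(item, type = c("nonmonotone_isrf", "crossing_irf"),
                           depth = 0.15, step = 2L, interval = c(-1, 1)) {
  type <- match.arg(type)
  stopifnot(depth >= 0, depth < 1, length(interval) == 2L,
            interval[1L] < interval[2L])
  structure(list(item = as.character(item), type = type, depth = depth,
                 step = as.integer(step), interval = interval),
            class = "violation_spec")
}

# cumulative step probabilities P(X >= x | theta), N x (levels-1)
grm_cumprobs <- function(theta, a_j, b_j) {
  P <- vapply(seq_along(b_j), function(s) stats::plogis(a_j * (theta - b_j[s])),
              numeric(length(theta)))
  matrix(P, nrow = length(theta))
}

# shared sampling core; violation = NULL for clean data. Randomness is drawn
# in a fixed order (labels, factors, one uniform per item) so a depth-0
# violation reproduces the clean draw bit for bit.
grm_sample_core <- function(config, violation = NULL) {
  stopifnot(inherits(config, "grm_config"))
  if (!is.null(violation)) {
    stopifnot(inherits(violation, "violation_spec"))
    if (!violation$item %in% config$item_ids) {
      stop("violation target item not in config", call. = FALSE)
    }
  }
  with_seed(config$seed, {
    N <- config$N
    gp <- config$group_prevalences
    labels <- data.frame(
      country = sample(names(config$country_prevalences), N, replace = TRUE,
                       prob = config$country_prevalences),
      female = stats::rbinom(N, 1L, gp[["female"]]),
      carer = stats::rbinom(N, 1L, gp[["carer"]]),
      long_term_condition = stats::rbinom(N, 1L,
                                          gp[["long_term_condition"]]))
    age <- pmin(pmax(round(stats::rnorm(N, 50, 18)), 18), 90)
    labels$age <- age
    labels$age_band <- cut(age, c(-Inf, 35, 50, 65, Inf),
                           labels = c("<=35", "36-50", "51-65", ">65"))
    n_fac <- max(config$cluster)
    Sigma <- diag(n_fac)
    Sigma[Sigma == 0] <- config$factor_correlation
    Z <- matrix(stats::rnorm(N * n_fac), N, n_fac) %*% chol(Sigma)
    shift <- rep(0, N)
    ge <- config$group_effects
    if ("long_term_condition" %in% names(ge)) {
      shift <- shift + ge[["long_term_condition"]] * labels$long_term_condition
    }
    if ("carer" %in% names(ge)) shift <- shift + ge[["carer"]] * labels$carer
    theta <- Z + shift
    ext <- matrix(NA_integer_, N, config$J,
                  dimnames = list(NULL, config$item_ids))
    for (j in seq_len(config$J)) {
      th_j <- theta[, config$cluster[j]]
      b_j <- config$b[j, ]
      if (!is.null(violation) && violation$type == "crossing_irf" &&
          config$item_ids[j] == violation$item && violation$depth > 0) {
        mid <- mean(violation$interval)
        inside <- th_j >= violation$interval[1L] &
          th_j <= violation$interval[2L]
        # a per-respondent threshold shift is a trait shift of opposite sign
        loc <- ifelse(inside, 4 * violation$depth * sign(th_j - mid), 0)
        P <- grm_cumprobs(th_j - loc, config$a[j], b_j)
      } else {
        P <- grm_cumprobs(th_j, config$a[j], b_j)
      }
      if (!is.null(violation) && violation$type == "nonmonotone_isrf" &&
          config$item_ids[j] == violation$item && violation$depth > 0) {
        s <- violation$step
        inside <- th_j >= violation$interval[1L] &
          th_j <= violation$interval[2L]
        lowered <- P[inside, s] - violation$depth
        if (any(lowered < 0)) {
          stop("violation depth makes step probabilities negative; ",
               "narrow the interval or reduce depth", call. = FALSE)
        }
        P[inside, s] <- lowered
        if (s < ncol(P)) {   # keep P(X >= x) non-increasing in x
          for (s2 in (s + 1L):ncol(P)) {
            P[inside, s2] <- pmin(P[inside, s2], P[inside, s2 - 1L])
          }
        }
      }
      u <- stats::runif(N)
      ext[, j] <- 1L + rowSums(u < P)
    }
    truth <- list(theta = theta, theta_bar = rowMeans(theta),
                  group_shift = shift, cluster = config$cluster,
                  violated_item = if (is.null(violation)) NULL else
                    violation$item,
                  config = config)
    structure(list(responses = response_matrix(ext, levels = config$levels),
                   labels = group_labels(labels),
                   truth = truth),
              class = "grm_sample")
  })
}

#' Draw a synthetic questionnaire dataset from the graded response model
#'
#' Respondent factor scores come from a correlated multivariate normal (one
#' factor per item cluster), known-group trait shifts are added, and each
#' item is sampled through its cumulative step probabilities. The returned
#' truth record (trait draws, group labels, cluster map, full config echo)
#' supports recovery tests. Same seed, same output, bit for bit.
#'
#' @param config a [grm_config()].
#' @return object of class `grm_sample`: `responses` (a
#'   [response_matrix()]), `labels` (a [group_labels()] data.frame) and
#'   `truth`.
#' @export
generate_grm <- function(config) {
  grm_sample_core(config, NULL)
}

#' Draw a dataset with a controlled monotonicity or ordering violation
#'
#' @param config a [grm_config()].
#' @param violation a [violation_spec()]; depth 0 reproduces
#'   [generate_grm()] exactly.
#' @return a `grm_sample` whose truth record marks the violated item.
#' @export
inject_violation <- function(config, violation) {
  grm_sample_core(config, violation)
}

#' Analytic marginal level probabilities implied by a generator config
#'
#' Integrates the graded response curves over the latent trait
#' distribution (a normal mixture over the known-group shift combinations)
#' to give the population level frequencies each item converges to.
#'
#' @param config a [grm_config()].
#' @return `J x levels` matrix of level probabilities (rows sum to 1).
#' @export
grm_expected_marginals <- function(config) {
  stopifnot(inherits(config, "grm_config"))
  ge <- config$group_effects
  gp <- config$group_prevalences
  # mixture over (condition, carer) cells
  shifts <- 0
  weights <- 1
  for (v in intersect(names(ge), c("long_term_condition", "carer"))) {
    p <- gp[[v]]
    shifts <- c(outer(shifts, c(0, ge[[v]]), "+"))
    weights <- c(outer(weights, c(1 - p, p), "*"))
  }
  m <- config$levels - 1L
  out <- matrix(NA_real_, config$J, config$levels,
                dimnames = list(config$item_ids, seq_len(config$levels)))
  for (j in seq_len(config$J)) {
    pge <- vapply(seq_len(m), function(s) {
      sum(vapply(seq_along(shifts), function(k) {
        weights[k] * stats::integrate(function(t) {
          stats::plogis(config$a[j] * (t - config$b[j, s])) *
            stats::dnorm(t, shifts[k], 1)
        }, -Inf, Inf)$value
      }, numeric(1L)))
    }, numeric(1L))
    out[j, ] <- -diff(c(1, pge, 0))
  }
  out
}
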