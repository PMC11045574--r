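#' Ordinal item-response matrix
#'
#' The container every statistic in the package is computed on: one row per
#' respondent, one column per item, ordinal responses coded externally as
#' `1..levels` (1 = least severe). Internally responses are stored 0-based
#' (`0..levels-1`); all covariance-based statistics are invariant to that
#' offset, and level-sum scoring reports on the external scale.
#'
#' @param data integer matrix or data.frame of externally coded responses
#'   (`1..levels`); `NA` marks a missing response.
#' @param levels number of ordered response levels shared by all items
#'   (default 5, the five-level format of short health-and-wellbeing
#'   instruments).
#' @param item_ids character vector of item names; defaults to the column
#'   names of `data`.
#'
#' @return An object of class `response_matrix`: a list with `values`
#'   (internal 0-based integer matrix, `NA` = missing), `item_ids`, `levels`
#'   and the external coding `offset` (always 1).
#' @export
response_matrix <- function(data, levels = 5L, item_ids = colnames(data)) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.numeric(data)) stop("response data must be numeric", call. = FALSE)
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(ncol(data)))
  item_ids <- as.character(item_ids)
  if (anyDuplicated(item_ids)) stop("item ids must be unique", call. = FALSE)
  if (length(item_ids) != ncol(data)) {
    stop("item_ids length must match the number of columns", call. = FALSE)
  }
  if (nrow(data) < 1L || ncol(data) < 2L) {
    stop("need at least 1 respondent and 2 items", call. = FALSE)
  }
  ok <- is.na(data) | (data == round(data) & data >= 1 & data <= levels)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer or out-of-range response at row %d, column '%s'",
                 bad[1L], item_ids[bad[2L]]), call. = FALSE)
  }
  values <- matrix(as.integer(data) - 1L, nrow(data), ncol(data),
                   dimnames = list(NULL, item_ids))
  structure(list(values = values, item_ids = item_ids,
                 levels = as.integer(levels), offset = 1L),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d respondents x %d items, %d levels, %d missing\n",
              nrow(x$values), ncol(x$values), x$levels, sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' @export
as.data.frame.response_matrix <- function(x, ...) {
  as.data.frame(x$values + x$offset)
}

#' Missing-response indicator
#'
#' @param x a [response_matrix()].
#' @return logical matrix, `TRUE` where the response is missing.
#' @export
missing_mask <- function(x) {
  stopifnot(inherits(x, "response_matrix"))
  is.na(x$values)
}

#' Define a (sub)scale as a named subset of items
#'
#' @param name scale label, e.g. `"psychosocial"`.
#' @param items character vector of at least two item ids.
#' @return object of class `scale_definition`.
#' @export
scale_definition <- function(name, items) {
  items <- as.character(items)
  if (length(items) < 2L) stop("a scale needs at least 2 items", call. = FALSE)
  if (anyDuplicated(items)) stop("scale items must be unique", call. = FALSE)
  structure(list(name = as.character(name), items = items),
            class = "scale_definition")
}

# resolve a scale argument (scale_definition, character vector, or NULL = all
# items) against a response_matrix, validating membership
resolve_scale <- function(x, scale) {
  if (is.null(scale)) {
    return(scale_definition("all", x$item_ids))
  }
  if (is.character(scale)) scale <- scale_definition("scale", scale)
  stopifnot(inherits(scale, "scale_definition"))
  absent <- setdiff(scale$items, x$item_ids)
  if (length(absent)) {
    stop("scale items not present in data: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  scale
}

#' Read wide-format item responses from a delimited text file
#'
#' Values outside `level_range` (including non-missing codes such as 6 used
#' for "not applicable") are set to missing and counted in the attached load
#' report. A non-numeric, non-blank cell is an error naming the row and
#' column.
#'
#' @param path CSV/TSV file with a header row.
#' @param item_columns names of the item columns to read.
#' @param level_range integer pair, the admissible external codes
#'   (default `c(1, 5)`).
#' @param sep field separator; `NULL` guesses from the file extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @return a [response_matrix()] with attribute `load_report`: a list with
#'   `n_out_of_range` and `n_blank` counts.
#' @export
load_responses <- function(path, item_columns, level_range = c(1L, 5L),
                           sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), strip.white = TRUE)
  absent <- setdiff(item_columns, names(raw))
  if (length(absent)) {
    stop("missing item column(s) in file: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[, item_columns, drop = FALSE]
  n_blank <- sum(is.na(raw))
  num <- matrix(NA_real_, nrow(raw), ncol(raw),
                dimnames = list(NULL, item_columns))
  for (j in seq_along(item_columns)) {
    cell <- raw[[j]]
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & (is.na(val) | val != round(val)))
    if (length(bad)) {
      stop(sprintf("non-integer cell '%s' at row %d, column '%s'",
                   cell[bad[1L]], bad[1L], item_columns[j]), call. = FALSE)
    }
    num[, j] <- val
  }
  out_of_range <- !is.na(num) & (num < level_range[1L] | num > level_range[2L])
  num[out_of_range] <- NA_real_
  rm <- response_matrix(num - level_range[1L] + 1L,
                        levels = level_range[2L] - level_range[1L] + 1L,
                        item_ids = item_columns)
  attr(rm, "load_report") <- list(n_out_of_range = sum(out_of_range),
                                  n_blank = n_blank)
  rm
}

#' Restrict to a scale's items and to respondents complete on them
#'
#' Listwise deletion per analysed item set: subscale analyses retain every
#' respondent complete on that subscale, regardless of missingness elsewhere.
#' Respondent order is preserved. Idempotent.
#'
#' @param x a [response_matrix()].
#' @param scale a [scale_definition()], character vector of item ids, or
#'   `NULL` for all items.
#' @return a [response_matrix()] on the scale's items with no missing values;
#'   attribute `n_dropped` records how many respondents were removed.
#' @export
complete_cases <- function(x, scale = NULL) {
  stopifnot(inherits(x, "response_matrix"))
  scale <- resolve_scale(x, scale)
  vals <- x$values[, scale$items, drop = FALSE]
  keep <- !rowSums(is.na(vals))
  if (!any(keep)) stop("no complete cases on scale '", scale$name, "'",
                       call. = FALSE)
  out <- structure(list(values = vals[keep, , drop = FALSE],
                        item_ids = scale$items, levels = x$levels,
                        offset = x$offset),
                   class = "response_matrix")
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Per-respondent categorical labels for stratified analyses
#'
#' @param ... named label vectors (factor or character), e.g.
#'   `country = ..., carer = ...`; all must have one entry per respondent.
#' @param n expected number of respondents (checked against every vector).
#' @return a data.frame of factors, class `group_labels`.
#' @export
group_labels <- function(..., n = NULL) {
  vars <- list(...)
  if (length(vars) == 1L && is.data.frame(vars[[1L]])) vars <- as.list(vars[[1L]])
  if (!length(vars) || is.null(names(vars)) || any(names(vars) == "")) {
    stop("label vectors must be named", call. = FALSE)
  }
  len <- unique(lengths(vars))
  if (length(len) != 1L) stop("all label vectors must have equal length",
                              call. = FALSE)
  if (!is.null(n) && len != n) {
    stop("label vectors must have one entry per respondent", call. = FALSE)
  }
  out <- as.data.frame(lapply(vars, as.factor), optional = TRUE)
  class(out) <- c("group_labels", "data.frame")
  out
}
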