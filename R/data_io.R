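#' Construct an item-response matrix
#'
#' Container for `n` respondents by `p` ordinal items scored on the
#' four-point 0--3 scale used by DASS-21-type instruments. All entries must
#' be integers in `{0, 1, 2, 3}` with no missing values (listwise deletion
#' is applied at ingestion, see [read_responses()]).
#'
#' @param values integer matrix, respondents in rows, items in columns.
#' @param item_ids character vector of unique item labels; defaults to the
#'   column names of `values`.
#' @return An object of class `item_response_matrix`: a list with elements
#'   `values`, `item_ids` and `n`.
#' @export
item_response_matrix <- function(values, item_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(ncol(values)))
  item_ids <- as.character(item_ids)
  if (length(item_ids) != ncol(values)) {
    stop("`item_ids` must have one label per column", call. = FALSE)
  }
  if (anyDuplicated(item_ids)) stop("item labels must be unique", call. = FALSE)
  if (anyNA(values)) stop("missing entries are not allowed", call. = FALSE)
  if (!all(values == round(values))) {
    stop("scores must be integers", call. = FALSE)
  }
  if (any(values < 0 | values > 3)) {
    stop("scores must lie in 0..3 (four-point scale)", call. = FALSE)
  }
  storage.mode(values) <- "integer"
  colnames(values) <- item_ids
  structure(
    list(values = values, item_ids = item_ids, n = nrow(values)),
    class = "item_response_matrix"
  )
}

#' @export
print.item_response_matrix <- function(x, ...) {
  cat(sprintf(
    "<item_response_matrix> %d respondents x %d items (0-3 scale)\n",
    x$n, length(x$item_ids)
  ))
  invisible(x)
}

#' Read questionnaire responses with listwise deletion
#'
#' Reads a CSV of respondent-by-item scores and applies listwise deletion:
#' any row with a missing, non-numeric-coercible or out-of-range score on
#' one of the named items is dropped. Out-of-range values (outside 0--3)
#' are treated as invalid responses and excluded with a warning, since the
#' instrument admits only the four response categories; set
#' `strict = TRUE` to raise an error instead. Fractional scores always
#' raise a validation error naming the offending row and item.
#'
#' @param path CSV file with a header row naming the items.
#' @param item_ids items to retain, in order; defaults to all columns.
#' @param strict if `TRUE`, out-of-range scores raise an error rather than
#'   dropping the row.
#' @return An [item_response_matrix()] with attributes `n_read`,
#'   `n_dropped` and `n_retained` recording the ingestion log.
#' @export
read_responses <- function(path, item_ids = NULL, strict = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  df <- tryCatch(
    read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) {
      stop(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (is.null(item_ids)) item_ids <- colnames(df)
  missing_cols <- setdiff(item_ids, colnames(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("item column(s) missing from file: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  raw <- df[, item_ids, drop = FALSE]
  n_read <- nrow(raw)

  num <- matrix(NA_real_, n_read, length(item_ids),
                dimnames = list(NULL, item_ids))
  for (j in seq_along(item_ids)) {
    col <- raw[[j]]
    if (is.character(col)) {
      col[trimws(col) == ""] <- NA
      col <- suppressWarnings(as.numeric(col))
    }
    num[, j] <- as.numeric(col)
  }

  # fractional scores are a coding fault, not a skipped answer
  frac <- which(!is.na(num) & num != round(num), arr.ind = TRUE)
  if (nrow(frac) > 0) {
    stop(sprintf("non-integer score at row %d, item '%s'",
                 frac[1, 1], item_ids[frac[1, 2]]), call. = FALSE)
  }

  out_of_range <- !is.na(num) & (num < 0 | num > 3)
  if (any(out_of_range)) {
    bad <- which(out_of_range, arr.ind = TRUE)
    msg <- sprintf("%d score(s) outside 0..3 (first: row %d, item '%s')",
                   nrow(bad), bad[1, 1], item_ids[bad[1, 2]])
    if (strict) stop(msg, call. = FALSE)
    warning(paste0(msg, "; affected rows excluded"), call. = FALSE)
  }

  keep <- !apply(is.na(num) | out_of_range, 1, any)
  retained <- num[keep, , drop = FALSE]
  x <- item_response_matrix(retained, item_ids)
  attr(x, "n_read") <- n_read
  attr(x, "n_dropped") <- n_read - sum(keep)
  attr(x, "n_retained") <- sum(keep)
  x
}

#' Write an item-response matrix to CSV
#'
#' @param x an [item_response_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path) {
  stopifnot(inherits(x, "item_response_matrix"))
  write.csv(as.data.frame(x$values), path, row.names = FALSE)
  invisible(path)
}

#' The DASS-21 subscale membership
#'
#' The standard allocation of the 21 items to their subscales: items 1--7
#' Stress, 8--14 Anxiety, 15--21 Depression.
#'
#' @param item_ids labels for the 21 items, in instrument order.
#' @return A `community_map`.
#' @export
dass21_communities <- function(item_ids = paste0("item", 1:21)) {
  stopifnot(length(item_ids) == 21)
  community_map(list(
    Stress     = item_ids[1:7],
    Anxiety    = item_ids[8:14],
    Depression = item_ids[15:21]
  ))
}

#' Construct a community map
#'
#' Assigns every item to exactly one community (symptom subscale).
#' Communities here are pre-assigned from the instrument's structure, not
#' detected from data.
#'
#' @param x a named list `community -> character vector of item labels`.
#' @return An object of class `community_map`: list with `assignment`
#'   (named character vector item -> community) and `communities`
#'   (ordered community labels).
#' @export
community_map <- function(x) {
  if (!is.list(x) || is.null(names(x)) || any(names(x) == "")) {
    stop("community map must be a named list of item vectors", call. = FALSE)
  }
  items <- unlist(x, use.names = FALSE)
  if (anyDuplicated(items)) {
    dup <- items[duplicated(items)][1]
    stop(sprintf("item '%s' assigned to more than one community", dup),
         call. = FALSE)
  }
  assignment <- rep(names(x), lengths(x))
  names(assignment) <- items
  structure(
    list(assignment = assignment, communities = names(x)),
    class = "community_map"
  )
}

#' @export
print.community_map <- function(x, ...) {
  sizes <- table(factor(x$assignment, levels = x$communities))
  cat("<community_map>",
      paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Load a community map from YAML or JSON
#'
#' The file maps community labels to their member items, e.g.
#' `{"Stress": ["item1", ...], ...}`. The built-in DASS-21 allocation is
#' available as `preset = "dass21"`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file; ignored when `preset`
#'   is given.
#' @param preset name of a built-in map (currently `"dass21"`).
#' @return A [community_map()].
#' @export
load_community_map <- function(path = NULL, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "dass21")
    return(dass21_communities())
  }
  if (is.null(path) || !file.exists(path)) {
    stop("community map file not found", call. = FALSE)
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  community_map(lapply(raw, as.character))
}

#' Check that a community map covers a set of items
#'
#' @param cm a [community_map()].
#' @param item_ids item labels that must each have exactly one community.
#' @return `cm`, invisibly; errors when an item is unassigned.
#' @export
validate_communities <- function(cm, item_ids) {
  stopifnot(inherits(cm, "community_map"))
  missing <- setdiff(item_ids, names(cm$assignment))
  if (length(missing) > 0) {
    stop(sprintf("item(s) without a community: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(cm)
}

# round half away from zero, the convention of printed percentage tables
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Tabulate sample characteristics as counts and percentages
#'
#' Computes the percentage of the retained sample in each category,
#' rounded half-away-from-zero to two decimals (the convention of printed
#' descriptive tables).
#'
#' @param counts data frame with columns `variable`, `category`, `count`.
#' @param n total retained sample size.
#' @return A data frame `variable, category, count, percent`.
#' @export
summarize_sample <- function(counts, n) {
  stopifnot(is.data.frame(counts),
            all(c("variable", "category", "count") %in% names(counts)))
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (any(counts$count < 0)) stop("counts must be non-negative", call. = FALSE)
  per_var <- tapply(counts$count, counts$variable, sum)
  if (any(per_var > n)) {
    bad <- names(per_var)[per_var > n][1]
    stop(sprintf("counts for variable '%s' exceed n = %d", bad, n),
         call. = FALSE)
  }
  data.frame(
    variable = counts$variable,
    category = counts$category,
    count = counts$count,
    percent = round_half_away(100 * counts$count / n, 2),
    stringsAsFactors = FALSE
  )
}
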