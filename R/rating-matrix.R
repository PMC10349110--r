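#' @keywords internal
"_PACKAGE"

OBSERVER_GROUPS <- c("novice", "super_recognizer", "forensic_examiner",
                     "forensic_laboratory", "dnn")
OBSERVER_MODES <- c("offline", "online", "not_applicable")
GAP_CATEGORIES <- c("0-2y", "2-8y", "8+y")
RATING_SCALE <- -5:5

#' Build an item key for a set of 1-to-1 comparisons
#'
#' The item key is the comparison inventory of a proficiency test: one row per
#' face pair, with the ground-truth label (`same` person or `different`
#' people) and, optionally, the category of time elapsed between the two
#' photographs.
#'
#' @param item_id Character vector of unique item identifiers.
#' @param truth Character vector, `"same"` or `"different"`, one per item.
#' @param gap_category Optional character vector of time-gap categories
#'   (`"0-2y"`, `"2-8y"`, `"8+y"`), or `NA`.
#' @return A `data.frame` of class `item_key` with columns `item_id`,
#'   `truth`, `gap_category`.
#' @examples
#' item_key(c("it01", "it02"), c("same", "different"))
#' @export
item_key <- function(item_id, truth, gap_category = NA_character_) {
  item_id <- as.character(item_id)
  truth <- as.character(truth)
  if (length(item_id) != length(truth)) {
    stop("`item_id` and `truth` must have equal length", call. = FALSE)
  }
  if (anyDuplicated(item_id)) {
    stop("duplicate item ids: ",
         paste(unique(item_id[duplicated(item_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(truth %in% c("same", "different"))) {
    stop("`truth` must be 'same' or 'different'", call. = FALSE)
  }
  gap_category <- rep_len(as.character(gap_category), length(item_id))
  bad_gap <- !is.na(gap_category) & !gap_category %in% GAP_CATEGORIES
  if (any(bad_gap)) {
    stop("unknown gap categories: ",
         paste(unique(gap_category[bad_gap]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(item_id = item_id, truth = truth,
                    gap_category = gap_category, stringsAsFactors = FALSE)
  class(out) <- c("item_key", "data.frame")
  out
}

#' The 20-item proficiency-test inventory
#'
#' Standard layout of the annual industry proficiency test for forensic
#' facial image comparison: twenty 1-to-1 comparisons, 13 same-person and 7
#' different-people pairs, with 3 pairs separated by 0-2 years, 13 by 2-8
#' years and 4 by 8 or more years. Item ids are synthetic placeholders; the
#' truth/gap structure is what the analyses consume.
#'
#' @return An [item_key()] with 20 rows.
#' @export
enfsi_item_key <- function() {
  n_same <- 13
  n_diff <- 7
  ids <- sprintf("item%02d", seq_len(n_same + n_diff))
  truth <- c(rep("same", n_same), rep("different", n_diff))
  # 3 x 0-2y, 13 x 2-8y, 4 x 8+y, spread over both truth classes
  gap <- c(rep("0-2y", 2), rep("2-8y", 8), rep("8+y", 3),   # 13 same
           rep("0-2y", 1), rep("2-8y", 5), rep("8+y", 1))   # 7 different
  item_key(ids, truth, gap)
}

#' Construct a rating matrix
#'
#' The central container of the pipeline: an observers x items table of
#' responses, together with observer metadata (group, administration mode)
#' and the item key. Human observers rate on the 11-point ordinal support
#' scale (integers -5..+5, negative = support for "different people",
#' positive = support for "same person", 0 = inconclusive); machine scorers
#' (group `"dnn"`) carry real-valued similarity scores
#' (`value_kind = "raw_score"`).
#'
#' @param values Numeric matrix, observers in rows, items in columns. Row
#'   names are observer ids, column names item ids. `NA` marks a missing
#'   response.
#' @param observers `data.frame` with columns `observer_id`, `group` and
#'   optionally `mode`; one row per row of `values`.
#' @param key An [item_key()] covering the columns of `values`.
#' @param value_kind `"ordinal_11pt"` (validated integer -5..+5) or
#'   `"raw_score"` (any real value).
#' @return An object of class `rating_matrix`.
#' @export
rating_matrix <- function(values, observers, key,
                          value_kind = c("ordinal_11pt", "raw_score")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (ncol(values) == 0L || nrow(values) == 0L) {
    stop("rating matrix must have at least one observer and one item",
         call. = FALSE)
  }
  observers <- as.data.frame(observers, stringsAsFactors = FALSE)
  if (!all(c("observer_id", "group") %in% names(observers))) {
    stop("`observers` needs columns observer_id and group", call. = FALSE)
  }
  if (is.null(observers$mode)) observers$mode <- "not_applicable"
  observers$observer_id <- as.character(observers$observer_id)
  observers$group <- as.character(observers$group)
  observers$mode <- as.character(observers$mode)
  if (nrow(observers) != nrow(values)) {
    stop("observer table and value matrix disagree on observer count",
         call. = FALSE)
  }
  if (anyDuplicated(observers$observer_id)) {
    stop("duplicate observer ids", call. = FALSE)
  }
  bad_grp <- !observers$group %in% OBSERVER_GROUPS
  if (any(bad_grp)) {
    stop("unknown observer groups: ",
         paste(unique(observers$group[bad_grp]), collapse = ", "),
         call. = FALSE)
  }
  bad_mode <- !observers$mode %in% OBSERVER_MODES
  if (any(bad_mode)) {
    stop("unknown observer modes: ",
         paste(unique(observers$mode[bad_mode]), collapse = ", "),
         call. = FALSE)
  }
  rownames(values) <- observers$observer_id
  if (is.null(colnames(values))) {
    stop("value matrix must carry item ids as column names", call. = FALSE)
  }
  if (!inherits(key, "item_key")) {
    key <- item_key(key$item_id, key$truth,
                    if (is.null(key$gap_category)) NA else key$gap_category)
  }
  missing_items <- setdiff(colnames(values), key$item_id)
  if (length(missing_items)) {
    stop("items absent from key: ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  }
  if (value_kind == "ordinal_11pt") {
    check_ordinal_values(values)
  }
  structure(
    list(values = values, observers = observers, key = key,
         value_kind = value_kind),
    class = "rating_matrix"
  )
}

# Raise a validation error naming the offending cell(s).
check_ordinal_values <- function(values) {
  v <- values
  bad <- !is.na(v) & (v != round(v) | v < -5 | v > 5)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf(
      "invalid ordinal rating %s at observer '%s', item '%s' (must be an integer in -5..+5)",
      format(v[idx[1], idx[2]]), rownames(v)[idx[1]], colnames(v)[idx[2]]),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("<rating_matrix> %d observers x %d items (%s)\n",
              nrow(x$values), ncol(x$values), x$value_kind))
  tab <- table(x$observers$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  n_miss <- sum(is.na(x$values))
  if (n_miss > 0) cat("  missing cells:", n_miss, "\n")
  invisible(x)
}

#' @export
dim.rating_matrix <- function(x) dim(x$values)

#' Subset a rating matrix by observer
#' @param x A [rating_matrix()].
#' @param observer_ids Observer ids to keep, in order.
#' @return A `rating_matrix` restricted to those observers.
#' @export
subset_observers <- function(x, observer_ids) {
  stopifnot(inherits(x, "rating_matrix"))
  idx <- match(observer_ids, x$observers$observer_id)
  if (anyNA(idx)) {
    stop("unknown observer ids: ",
         paste(observer_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  rating_matrix(x$values[idx, , drop = FALSE],
                x$observers[idx, , drop = FALSE],
                x$key, x$value_kind)
}

#' Read a ratings file
#'
#' Reads the plain-text interchange format: comma-separated, one observer per
#' row, columns `observer_id`, `group`, `mode`, then one column per item id.
#' Empty cells are missing responses.
#'
#' @param path Path to a CSV file.
#' @param key An [item_key()]; item columns are validated against it.
#' @param value_kind `"ordinal_11pt"` or `"raw_score"`.
#' @return A [rating_matrix()].
#' @export
load_ratings <- function(path, key,
                         value_kind = c("ordinal_11pt", "raw_score")) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  meta_cols <- c("observer_id", "group", "mode")
  if (!all(meta_cols[1:2] %in% names(df))) {
    stop("malformed header: expected columns observer_id, group[, mode], ",
         "then item ids", call. = FALSE)
  }
  item_cols <- setdiff(names(df), meta_cols)
  if (length(item_cols) == 0L) stop("no item columns found", call. = FALSE)
  raw <- as.matrix(df[, item_cols, drop = FALSE])
  raw[raw == ""] <- NA_character_
  suppressWarnings(values <- matrix(as.numeric(raw), nrow = nrow(raw),
                                    dimnames = list(NULL, item_cols)))
  bad_num <- !is.na(raw) & is.na(values)
  if (any(bad_num)) {
    idx <- which(bad_num, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value '%s' at observer '%s', item '%s'",
                 raw[idx[1], idx[2]], df$observer_id[idx[1]],
                 item_cols[idx[2]]), call. = FALSE)
  }
  obs <- df[, intersect(meta_cols, names(df)), drop = FALSE]
  rownames(values) <- obs$observer_id
  rating_matrix(values, obs, key, value_kind)
}

#' Write a ratings file
#'
#' Inverse of [load_ratings()]: writes the comma-separated interchange format
#' with missing responses as empty cells. A round trip reproduces values,
#' groups and missingness exactly.
#'
#' @param x A [rating_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(x, path) {
  stopifnot(inherits(x, "rating_matrix"))
  df <- data.frame(observer_id = x$observers$observer_id,
                   group = x$observers$group,
                   mode = x$observers$mode,
                   stringsAsFactors = FALSE, check.names = FALSE)
  vals <- x$values
  if (x$value_kind == "ordinal_11pt") {
    chr <- ifelse(is.na(vals), "", as.character(vals))
  } else {
    chr <- ifelse(is.na(vals), "",
                  trimws(formatC(vals, digits = 15, format = "g")))
  }
  dim(chr) <- dim(vals)
  colnames(chr) <- colnames(vals)
  df <- cbind(df, as.data.frame(chr, stringsAsFactors = FALSE,
                                check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write an item key file
#' @param key An [item_key()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_item_key <- function(key, path) {
  utils::write.csv(as.data.frame(key), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read an item key file
#' @param path CSV with columns `item_id`, `truth` and optionally
#'   `gap_category`.
#' @return An [item_key()].
#' @export
load_item_key <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item_id", "truth") %in% names(df))) {
    stop("item key needs columns item_id and truth", call. = FALSE)
  }
  gap <- if ("gap_category" %in% names(df)) df$gap_category else NA_character_
  gap[!is.na(gap) & gap == ""] <- NA_character_
  item_key(df$item_id, df$truth, gap)
}

#' Rescale raw similarity scores onto the human rating range
#'
#' Maps one scorer's raw similarity scores linearly onto the ordinal rating
#' range so machine scores can be averaged with human ratings: the minimum
#' score maps to `lo`, the maximum to `hi`, everything in between by the same
#' affine map. Rank order is exactly preserved; the output is kept
#' real-valued (it is consumed by the fusion average, which is real-valued
#' anyway).
#'
#' @param scores Numeric vector of raw scores (at least two distinct values
#'   among the non-missing entries).
#' @param lo,hi Target range endpoints; defaults are the ends of the 11-point
#'   support scale.
#' @return Numeric vector of the same length, in `[lo, hi]`, `NA`s preserved.
#' @examples
#' rescale_scores_to_rating_range(c(0.2, 0.5, 0.8))  # -5 0 5
#' @export
rescale_scores_to_rating_range <- function(scores, lo = -5, hi = 5) {
  stopifnot(is.numeric(scores), lo < hi)
  ok <- !is.na(scores)
  if (sum(ok) < 2L) {
    stop("need at least two non-missing scores to rescale", call. = FALSE)
  }
  rng <- range(scores[ok])
  if (rng[1] == rng[2]) {
    stop("degenerate scale: all scores identical, rank information absent",
         call. = FALSE)
  }
  out <- scores
  out[ok] <- lo + (scores[ok] - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
  out
}

#' Validate a study against its item key
#'
#' Report-only consistency census: item count and truth-class counts, items
#' present in the matrix but absent from the key (and vice versa), per-group
#' observer counts, and per-observer missing-cell counts, flagging observers
#' with no responses at all.
#'
#' @param x A [rating_matrix()].
#' @param key An [item_key()]; defaults to the key stored in `x`.
#' @return A list of class `study_validation`.
#' @export
validate_study <- function(x, key = x$key) {
  stopifnot(inherits(x, "rating_matrix"))
  items_in_matrix <- colnames(x$values)
  missing_per_obs <- rowSums(is.na(x$values))
  key_sub <- key[match(intersect(items_in_matrix, key$item_id), key$item_id), ]
  out <- list(
    n_items_matrix = length(items_in_matrix),
    n_items_key = nrow(key),
    items_not_in_key = setdiff(items_in_matrix, key$item_id),
    items_not_in_matrix = setdiff(key$item_id, items_in_matrix),
    truth_counts = c(same = sum(key_sub$truth == "same"),
                     different = sum(key_sub$truth == "different")),
    group_sizes = table(x$observers$group),
    missing_per_observer = stats::setNames(missing_per_obs,
                                           x$observers$observer_id),
    empty_observers = x$observers$observer_id[
      missing_per_obs == length(items_in_matrix)],
    value_kind = x$value_kind
  )
  class(out) <- "study_validation"
  out
}

#' @export
print.study_validation <- function(x, ...) {
  cat("<study_validation>\n")
  cat(sprintf("  items: %d in matrix, %d in key (%d same / %d different)\n",
              x$n_items_matrix, x$n_items_key,
              x$truth_counts[["same"]], x$truth_counts[["different"]]))
  if (length(x$items_not_in_key)) {
    cat("  NOT IN KEY:", paste(x$items_not_in_key, collapse = ", "), "\n")
  }
  if (length(x$items_not_in_matrix)) {
    cat("  not answered:", paste(x$items_not_in_matrix, collapse = ", "), "\n")
  }
  cat("  groups:", paste(sprintf("%s=%d", names(x$group_sizes),
                                 x$group_sizes), collapse = ", "), "\n")
  n_missing <- sum(x$missing_per_observer)
  cat("  missing cells:", n_missing, "\n")
  if (length(x$empty_observers)) {
    cat("  EMPTY observers:", paste(x$empty_observers, collapse = ", "), "\n")
  }
  invisible(x)
}
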