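#' Rating-scale AUC for a single observer
#'
#' Area under the rating-threshold ROC curve, computed as the tie-corrected
#' Mann-Whitney rank statistic: the proportion of (same-person,
#' different-people) item pairs on which the same-person item received the
#' higher rating, ties counting one half. Larger ratings must mean stronger
#' support for "same person"; the statistic is invariant under any strictly
#' increasing transform of the ratings, so raw machine similarity scores can
#' be scored without rescaling.
#'
#' @param ratings Numeric vector of one observer's ratings, named by item id
#'   or aligned with `key`. Missing items are dropped for this observer.
#' @param key An [item_key()] (or data.frame with `item_id`, `truth`).
#' @return AUC as a proportion in `[0, 1]`.
#' @examples
#' key <- item_key(c("a", "b", "c", "d"),
#'                 c("same", "same", "different", "different"))
#' rating_auc(c(a = 3, b = 5, c = -2, d = 3), key)  # 0.875
#' @export
rating_auc <- function(ratings, key) {
  ab <- align_ratings(ratings, key)
  x <- ab$ratings[ab$truth == "same"]
  y <- ab$ratings[ab$truth == "different"]
  if (length(x) == 0L || length(y) == 0L) {
    stop("AUC undefined: a truth class has no non-missing rating",
         call. = FALSE)
  }
  r <- rank(c(x, y))
  (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
}

# Drop missing ratings and align with the key's truth labels.
align_ratings <- function(ratings, key) {
  truth <- key$truth
  if (!is.null(names(ratings))) {
    idx <- match(names(ratings), key$item_id)
    if (anyNA(idx)) {
      stop("ratings name items absent from key: ",
           paste(names(ratings)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    truth <- key$truth[idx]
  } else if (length(ratings) != nrow(key)) {
    stop("unnamed ratings must align with the key (length mismatch)",
         call. = FALSE)
  }
  ok <- !is.na(ratings)
  list(ratings = as.numeric(ratings[ok]), truth = truth[ok])
}

#' Rating-threshold ROC curve
#'
#' Sweeps a "respond same-person" cutoff across the distinct observed rating
#' values, from strictest to most lenient, giving one (false-positive rate,
#' true-positive rate) point per cutoff plus the (0,0) and (1,1) endpoints.
#' The trapezoidal area under this empirical curve equals [rating_auc()]
#' (ties contribute the trapezoids' sloped segments).
#'
#' @inheritParams rating_auc
#' @return A list of class `roc_curve`: `thresholds` (cutoff = respond
#'   "same" when rating >= threshold; `Inf` for the (0,0) point), `fpr`,
#'   `tpr`, and `auc` (trapezoidal area).
#' @export
roc_points <- function(ratings, key) {
  ab <- align_ratings(ratings, key)
  is_same <- ab$truth == "same"
  n_s <- sum(is_same)
  n_d <- sum(!is_same)
  if (n_s == 0L || n_d == 0L) {
    stop("ROC undefined: a truth class has no non-missing rating",
         call. = FALSE)
  }
  cuts <- sort(unique(ab$ratings), decreasing = TRUE)
  tpr <- vapply(cuts, function(t) sum(ab$ratings[is_same] >= t) / n_s,
                numeric(1))
  fpr <- vapply(cuts, function(t) sum(ab$ratings[!is_same] >= t) / n_d,
                numeric(1))
  thresholds <- c(Inf, cuts)
  tpr <- c(0, tpr)
  fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Per-group accuracy summary
#'
#' Computes each observer's rating-scale AUC and aggregates by observer
#' group, ranked from most to least accurate. Observers for whom AUC is
#' undefined (an entire truth class missing) are dropped with a warning;
#' groups left empty are omitted with a warning.
#'
#' @param x A [rating_matrix()]. Machine scorers may carry raw scores: AUC is
#'   rank-invariant.
#' @param key An [item_key()]; defaults to the key stored in `x`.
#' @return A list of class `group_accuracy`: `summary` (data.frame `group`,
#'   `n`, `mean_auc`, `sd_auc`, sorted by `mean_auc` descending) and
#'   `per_observer` (data.frame `observer_id`, `group`, `auc`).
#' @export
group_auc_summary <- function(x, key = x$key) {
  stopifnot(inherits(x, "rating_matrix"))
  aucs <- rep(NA_real_, nrow(x$values))
  for (i in seq_len(nrow(x$values))) {
    row <- x$values[i, ]
    names(row) <- colnames(x$values)
    aucs[i] <- tryCatch(rating_auc(row, key), error = function(e) NA_real_)
  }
  if (anyNA(aucs)) {
    warning(sum(is.na(aucs)), " observer(s) dropped: AUC undefined",
            call. = FALSE)
  }
  per_obs <- data.frame(observer_id = x$observers$observer_id,
                        group = x$observers$group,
                        auc = aucs, stringsAsFactors = FALSE)
  keep <- per_obs[!is.na(per_obs$auc), ]
  empty <- setdiff(unique(x$observers$group), unique(keep$group))
  if (length(empty)) {
    warning("group(s) with no scorable observer omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  agg <- do.call(rbind, lapply(split(keep, keep$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g), mean_auc = mean(g$auc),
               sd_auc = stats::sd(g$auc), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(-agg$mean_auc), ]
  rownames(agg) <- NULL
  structure(list(summary = agg, per_observer = per_obs),
            class = "group_accuracy")
}

#' @export
print.group_accuracy <- function(x, ...) {
  cat("<group_accuracy> mean rating-scale AUC by group\n")
  s <- x$summary
  s$mean_auc <- sprintf("%.1f%%", 100 * s$mean_auc)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Export a group accuracy summary as CSV
#' @param x A `group_accuracy` object.
#' @param path Output path for the group table.
#' @param per_observer_path Optional path for the per-observer AUC table.
#' @return `path`, invisibly.
#' @export
write_group_accuracy <- function(x, path, per_observer_path = NULL) {
  stopifnot(inherits(x, "group_accuracy"))
  utils::write.csv(x$summary, path, row.names = FALSE)
  if (!is.null(per_observer_path)) {
    utils::write.csv(x$per_observer, per_observer_path, row.names = FALSE)
  }
  invisible(path)
}
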