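#' Binarize an ordinal support rating
#'
#' Collapses the 11-point support scale to the categorical decision it
#' expresses: any positive rating supports "same person", any negative
#' rating supports "different people", and the midpoint 0 is an inconclusive
#' non-decision.
#'
#' @param rating Integer vector in `-5..+5` (`NA` allowed, propagated).
#' @return Character vector: `"same"`, `"different"` or `"inconclusive"`.
#' @export
binarize <- function(rating) {
  ok <- !is.na(rating)
  if (any(rating[ok] != round(rating[ok]) | abs(rating[ok]) > 5)) {
    stop("ratings must be integers in -5..+5", call. = FALSE)
  }
  out <- rep(NA_character_, length(rating))
  out[ok & rating > 0] <- "same"
  out[ok & rating < 0] <- "different"
  out[ok & rating == 0] <- "inconclusive"
  out
}

#' Hit and false-alarm rates over decisive responses
#'
#' The signal-detection layer treats "same person" as the signal: the hit
#' rate H is the probability of a "same" decision on same-person items, the
#' false-alarm rate F the probability of a "same" decision on
#' different-people items. Inconclusive (0) and missing responses are
#' non-decisions and enter neither numerator nor denominator. When either
#' raw rate is 0 or 1 the log-linear correction is applied to both rates
#' (0.5 added to each response count, 1 to each denominator) so the normal
#' quantile transform stays finite.
#'
#' @inheritParams rating_auc
#' @param inconclusive Sensitivity toggle for 0 responses: `"exclude"`
#'   (default; 0 is a non-decision) or `"different"` (0 counted as a
#'   "different people" decision).
#' @return List: `H`, `F`, `correction_applied`, `n_decisive_same`,
#'   `n_decisive_diff`.
#' @export
hit_fa_rates <- function(ratings, key,
                         inconclusive = c("exclude", "different")) {
  inconclusive <- match.arg(inconclusive)
  ab <- align_ratings(ratings, key)
  decision <- binarize(ab$ratings)
  if (inconclusive == "different") decision[decision == "inconclusive"] <- "different"
  decisive <- decision != "inconclusive"
  same_dec <- decisive & ab$truth == "same"
  diff_dec <- decisive & ab$truth == "different"
  n_s <- sum(same_dec)
  n_d <- sum(diff_dec)
  if (n_s == 0L || n_d == 0L) {
    stop("rates undefined: no decisive response in a truth class",
         call. = FALSE)
  }
  hits <- sum(decision[same_dec] == "same")
  fas <- sum(decision[diff_dec] == "same")
  H <- hits / n_s
  F <- fas / n_d
  corrected <- H %in% c(0, 1) || F %in% c(0, 1)
  if (corrected) {
    H <- (hits + 0.5) / (n_s + 1)
    F <- (fas + 0.5) / (n_d + 1)
  }
  list(H = H, F = F, correction_applied = corrected,
       n_decisive_same = n_s, n_decisive_diff = n_d)
}

#' Response criterion c
#'
#' Signal-detection response bias, `c = -0.5 * (qnorm(H) + qnorm(F))`.
#' Negative values mean a liberal bias toward responding "same person",
#' positive values a conservative bias toward "different people"; 0 is
#' neutral.
#'
#' @param H,F Hit and false-alarm rates, strictly inside (0, 1) — apply the
#'   boundary correction of [hit_fa_rates()] first.
#' @return Criterion c in z-units.
#' @export
criterion_c <- function(H, F) {
  check_rates(H, F)
  -0.5 * (stats::qnorm(H) + stats::qnorm(F))
}

#' Sensitivity d'
#'
#' Signal-detection sensitivity under the equal-variance Gaussian model,
#' `d' = qnorm(H) - qnorm(F)`.
#'
#' @inheritParams criterion_c
#' @return d' in z-units.
#' @export
d_prime <- function(H, F) {
  check_rates(H, F)
  stats::qnorm(H) - stats::qnorm(F)
}

check_rates <- function(H, F) {
  if (any(H <= 0 | H >= 1) || any(F <= 0 | F >= 1)) {
    stop("H and F must lie strictly in (0, 1); ",
         "boundary rates need the log-linear correction first",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-observer signal-detection table
#'
#' Applies [hit_fa_rates()], [d_prime()] and [criterion_c()] to every
#' observer of an ordinal rating matrix. Observers without a decisive
#' response in each truth class are excluded and listed in the `excluded`
#' attribute.
#'
#' @param x A [rating_matrix()] with `value_kind = "ordinal_11pt"`.
#' @param key An [item_key()]; defaults to the key stored in `x`.
#' @inheritParams hit_fa_rates
#' @return data.frame of class `sdt_summary`: `observer_id`, `group`, `H`,
#'   `F`, `d_prime`, `criterion_c`, `correction_applied`,
#'   `n_decisive_same`, `n_decisive_diff`; excluded observers in
#'   `attr(, "excluded")`.
#' @export
sdt_summary <- function(x, key = x$key,
                        inconclusive = c("exclude", "different")) {
  inconclusive <- match.arg(inconclusive)
  stopifnot(inherits(x, "rating_matrix"))
  if (x$value_kind != "ordinal_11pt") {
    stop("signal-detection profiling needs ordinal ratings", call. = FALSE)
  }
  rows <- list()
  excluded <- character(0)
  for (i in seq_len(nrow(x$values))) {
    row <- x$values[i, ]
    names(row) <- colnames(x$values)
    rates <- tryCatch(hit_fa_rates(row, key, inconclusive),
                      error = function(e) NULL)
    if (is.null(rates)) {
      excluded <- c(excluded, x$observers$observer_id[i])
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      observer_id = x$observers$observer_id[i],
      group = x$observers$group[i],
      H = rates$H, F = rates$F,
      d_prime = d_prime(rates$H, rates$F),
      criterion_c = criterion_c(rates$H, rates$F),
      correction_applied = rates$correction_applied,
      n_decisive_same = rates$n_decisive_same,
      n_decisive_diff = rates$n_decisive_diff,
      stringsAsFactors = FALSE)
  }
  if (length(excluded)) {
    message("excluded from SDT table (no decisive response in a class): ",
            paste(excluded, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("sdt_summary", "data.frame")
  out
}

#' Response-scale usage and error profiles
#'
#' Profiles how observers (or pooled groups) distribute responses and errors
#' over the 11-point scale. An error is a decisive response of the wrong
#' sign — a positive rating on a different-people item or a negative rating
#' on a same-person item; inconclusive (0) responses are never errors. The
#' headline statistics are the inconclusive rate (share of non-missing
#' responses equal to 0) and the high-confidence misidentification share
#' (share of all errors that are ratings of +4 or +5 on different-people
#' items).
#'
#' @param x A [rating_matrix()] with ordinal values.
#' @param key An [item_key()]; defaults to the key stored in `x`.
#' @param by `"group"` (pool all responses of each group) or `"observer"`.
#' @return A list of class `response_profile`: `usage` (units x 11 matrix of
#'   response proportions over scale points -5..+5, rows summing to 1),
#'   `error_dist` (units x 10 matrix of error proportions over the decisive
#'   scale points, rows summing to 1 where errors exist, `NaN` rows where a
#'   unit made no error), and `stats` (data.frame `unit`, `n_responses`,
#'   `n_errors`, `inconclusive_rate`, `high_conf_same_error_share`).
#' @export
response_profile <- function(x, key = x$key, by = c("group", "observer")) {
  by <- match.arg(by)
  stopifnot(inherits(x, "rating_matrix"))
  if (x$value_kind != "ordinal_11pt") {
    stop("response profiling needs ordinal ratings", call. = FALSE)
  }
  units <- if (by == "group") x$observers$group else x$observers$observer_id
  truth <- key$truth[match(colnames(x$values), key$item_id)]
  scale_pts <- RATING_SCALE
  err_pts <- setdiff(scale_pts, 0)
  u_levels <- unique(units)
  usage <- matrix(0, length(u_levels), length(scale_pts),
                  dimnames = list(u_levels, as.character(scale_pts)))
  error_dist <- matrix(0, length(u_levels), length(err_pts),
                       dimnames = list(u_levels, as.character(err_pts)))
  stats_df <- data.frame(unit = u_levels, n_responses = 0L, n_errors = 0L,
                         inconclusive_rate = NA_real_,
                         high_conf_same_error_share = NA_real_,
                         stringsAsFactors = FALSE)
  for (k in seq_along(u_levels)) {
    vals <- x$values[units == u_levels[k], , drop = FALSE]
    r <- as.vector(t(vals))                       # observer-major
    tr <- rep(truth, nrow(vals))
    ok <- !is.na(r)
    r <- r[ok]; tr <- tr[ok]
    n <- length(r)
    usage[k, ] <- if (n > 0) {
      tabulate(match(r, scale_pts), length(scale_pts)) / n
    } else 0
    is_err <- (r > 0 & tr == "different") | (r < 0 & tr == "same")
    n_err <- sum(is_err)
    if (n_err > 0) {
      error_dist[k, ] <- tabulate(match(r[is_err], err_pts),
                                  length(err_pts)) / n_err
      stats_df$high_conf_same_error_share[k] <-
        sum(is_err & r >= 4 & tr == "different") / n_err
    } else {
      error_dist[k, ] <- NaN
    }
    stats_df$n_responses[k] <- n
    stats_df$n_errors[k] <- n_err
    stats_df$inconclusive_rate[k] <- if (n > 0) sum(r == 0) / n else NA_real_
  }
  structure(list(usage = usage, error_dist = error_dist, stats = stats_df,
                 by = by),
            class = "response_profile")
}

#' @export
print.response_profile <- function(x, ...) {
  cat(sprintf("<response_profile> by %s\n", x$by))
  s <- x$stats
  s$inconclusive_rate <- sprintf("%.1f%%", 100 * s$inconclusive_rate)
  s$high_conf_same_error_share <-
    ifelse(is.na(x$stats$high_conf_same_error_share), "-",
           sprintf("%.1f%%", 100 * x$stats$high_conf_same_error_share))
  print(s, row.names = FALSE)
  invisible(x)
}

#' Export response profiles as CSV tables
#' @param x A `response_profile`.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_response_profile <- function(x, dir, prefix = "profile") {
  stopifnot(inherits(x, "response_profile"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- file.path(dir, paste0(prefix, "_",
                                 c("usage.csv", "errors.csv", "stats.csv")))
  utils::write.csv(data.frame(unit = rownames(x$usage), x$usage,
                              check.names = FALSE), files[1],
                   row.names = FALSE)
  utils::write.csv(data.frame(unit = rownames(x$error_dist), x$error_dist,
                              check.names = FALSE), files[2],
                   row.names = FALSE)
  utils::write.csv(x$stats, files[3], row.names = FALSE)
  invisible(files)
}
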