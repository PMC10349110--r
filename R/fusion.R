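#' Configure a fusion analysis
#'
#' A fusion composition specifies how a nominal group is assembled on each
#' resample: a named integer vector whose names are either observer groups
#' (that many distinct members are drawn at random from the group, without
#' replacement within a draw) or individual observer ids (that member is
#' included deterministically, the way a fixed top-performing machine scorer
#' is fused with random human experts).
#'
#' @param composition Named integer vector, e.g.
#'   `c(super_recognizer = 2)` or `c(forensic_examiner = 1, dnn07 = 1)`.
#' @param n_samples Number of resamples (default 1000).
#' @param seed Integer seed making the resampling reproducible.
#' @param label Optional display label; defaults to a compact rendering of
#'   the composition.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(composition, n_samples = 1000, seed = 1,
                          label = NULL) {
  if (is.null(names(composition)) || any(names(composition) == "")) {
    stop("`composition` must be a named vector", call. = FALSE)
  }
  composition <- vapply(composition, as.integer, integer(1))
  if (any(composition < 1L) || sum(composition) < 1L) {
    stop("composition counts must be positive", call. = FALSE)
  }
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  label <- label %||% paste(sprintf("%s:%d", names(composition), composition),
                            collapse = "+")
  structure(list(composition = composition, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), label = label),
            class = "fusion_config")
}

#' Average member ratings into a fused rating vector
#'
#' The fusion rule is the plain element-wise arithmetic mean of the members'
#' ratings on a common scale (machine scores must already be rescaled via
#' [rescale_scores_to_rating_range()]). Items a member skipped are averaged
#' over the members who responded; an item no member answered is missing in
#' the fused vector.
#'
#' @param member_rows Numeric matrix (members x items) or list of
#'   equal-length rating vectors.
#' @return Numeric vector of fused ratings, one per item.
#' @export
fuse_ratings <- function(member_rows) {
  if (is.list(member_rows)) {
    len <- unique(lengths(member_rows))
    if (length(len) != 1L) stop("member vectors differ in length",
                                call. = FALSE)
    member_rows <- do.call(rbind, member_rows)
  }
  member_rows <- as.matrix(member_rows)
  out <- colMeans(member_rows, na.rm = TRUE)
  out[colSums(!is.na(member_rows)) == 0L] <- NA_real_
  out
}

#' Resampled decision-fusion analysis
#'
#' Simulates collective decisions: on each of `n_samples` resamples a
#' nominal group is assembled per the composition, the members' per-item
#' ratings are averaged ([fuse_ratings()]) and the fused ratings are scored
#' with the rating-scale AUC ([rating_auc()]). Machine scorers' raw
#' similarity scores are rescaled onto the human rating range once, over the
#' analyzed item set, before any resampling. The run is reproducible: the
#' same configuration and data give bit-identical AUC samples.
#'
#' @param x A [rating_matrix()] holding all candidate members (human ratings
#'   ordinal, machine scorers in group `"dnn"` with raw scores permitted).
#' @param key An [item_key()]; defaults to the key stored in `x`.
#' @param config A [fusion_config()].
#' @return A list of class `fusion_result`: `config`, `auc_samples`
#'   (length `n_samples`), `median_auc`, `min_auc`, `max_auc`.
#' @export
run_fusion <- function(x, key = x$key, config) {
  stopifnot(inherits(x, "rating_matrix"), inherits(config, "fusion_config"))
  vals <- x$values
  is_dnn <- x$observers$group == "dnn"
  for (i in which(is_dnn)) {
    vals[i, ] <- rescale_scores_to_rating_range(vals[i, ])
  }
  comp <- config$composition
  pools <- vector("list", length(comp))
  for (k in seq_along(comp)) {
    nm <- names(comp)[k]
    if (nm %in% x$observers$group) {
      pool <- which(x$observers$group == nm)
      if (length(pool) < comp[k]) {
        stop(sprintf("composition asks for %d of group '%s' but only %d present",
                     comp[k], nm, length(pool)), call. = FALSE)
      }
    } else if (nm %in% x$observers$observer_id) {
      if (comp[k] != 1L) {
        stop("a named observer can appear at most once in a composition",
             call. = FALSE)
      }
      pool <- match(nm, x$observers$observer_id)
    } else {
      stop("composition entry '", nm, "' is neither a group nor an observer id",
           call. = FALSE)
    }
    pools[[k]] <- pool
  }
  aucs <- numeric(config$n_samples)
  item_names <- colnames(vals)
  withr_seed <- config$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)
  for (s in seq_len(config$n_samples)) {
    members <- unlist(lapply(seq_along(comp), function(k) {
      if (length(pools[[k]]) == 1L) pools[[k]]
      else sample(pools[[k]], comp[k], replace = FALSE)
    }))
    fused <- fuse_ratings(vals[members, , drop = FALSE])
    names(fused) <- item_names
    aucs[s] <- rating_auc(fused, key)
  }
  structure(list(config = config, auc_samples = aucs,
                 median_auc = stats::median(aucs),
                 min_auc = min(aucs), max_auc = max(aucs)),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %s: median AUC %.3f (range %.3f-%.3f, %d resamples)\n",
              x$config$label, x$median_auc, x$min_auc, x$max_auc,
              length(x$auc_samples)))
  invisible(x)
}

#' Compare fusion compositions
#'
#' Tabulates a set of fusion results — composition label, median, minimum
#' and maximum resampled AUC — sorted by median accuracy, flagging the best
#' composition.
#'
#' @param results List of [run_fusion()] results.
#' @return data.frame of class `fusion_report`: `composition`, `n_samples`,
#'   `median_auc`, `min_auc`, `max_auc`, `best`.
#' @export
fusion_report <- function(results) {
  if (inherits(results, "fusion_result")) results <- list(results)
  if (length(results) < 1L) stop("need at least one fusion result",
                                 call. = FALSE)
  out <- do.call(rbind, lapply(results, function(r) {
    data.frame(composition = r$config$label,
               n_samples = length(r$auc_samples),
               median_auc = r$median_auc, min_auc = r$min_auc,
               max_auc = r$max_auc, stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$median_auc), ]
  out$best <- seq_len(nrow(out)) == 1L
  rownames(out) <- NULL
  class(out) <- c("fusion_report", "data.frame")
  out
}
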