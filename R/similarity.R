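#' Tie-aware Spearman rank correlation
#'
#' Spearman's rho computed as the Pearson correlation of mid-ranks, the
#' tie-aware form needed here: human observers place at most 11 distinct
#' values on at most 13 items of a trial type, so ties are the norm rather
#' than the exception.
#'
#' @param x,y Numeric vectors of equal length (>= 2), each with at least two
#'   distinct values. Pairs with a missing value in either vector are
#'   dropped.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  vx <- sum(dx^2); vy <- sum(dy^2)
  if (vx == 0 || vy == 0) {
    stop("undefined correlation: zero variance in a vector", call. = FALSE)
  }
  sum(dx * dy) / sqrt(vx * vy)
}

#' Observer-by-observer correlation matrix for one trial type
#'
#' Restricts the matrix to one trial type (same-person or different-people
#' items) and computes the tie-aware Spearman correlation between every pair
#' of observers' responses to those items. Observers who cannot support a
#' rank correlation on that trial type — fewer than two non-missing
#' responses, or zero variance (a single distinct response value) — are
#' excluded and logged with a reason. Raw machine scores are used as-is
#' (rank correlation is invariant to rescaling).
#'
#' @param x A [rating_matrix()].
#' @param key An [item_key()]; defaults to the key stored in `x`.
#' @param trial_type `"same"` or `"different"`.
#' @return A list of class `correlation_matrix`: `observer_ids`, `groups`,
#'   `rho` (symmetric, unit diagonal; `NA` where a pair shares fewer than 2
#'   usable items), `trial_type`, `excluded` (data.frame `observer_id`,
#'   `reason`).
#' @export
correlation_matrix <- function(x, key = x$key,
                               trial_type = c("same", "different")) {
  trial_type <- match.arg(trial_type)
  stopifnot(inherits(x, "rating_matrix"))
  items <- key$item_id[key$truth == trial_type]
  items <- intersect(colnames(x$values), items)
  if (length(items) < 2L) {
    stop("fewer than 2 items of trial type '", trial_type, "'",
         call. = FALSE)
  }
  vals <- x$values[, items, drop = FALSE]
  n_ok <- rowSums(!is.na(vals))
  n_distinct <- apply(vals, 1, function(v) length(unique(v[!is.na(v)])))
  reason <- rep(NA_character_, nrow(vals))
  reason[n_ok < 2L] <- "fewer than 2 responses for this trial type"
  reason[n_ok >= 2L & n_distinct < 2L] <-
    "degenerate responses (single distinct value)"
  keep <- is.na(reason)
  excluded <- data.frame(observer_id = x$observers$observer_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  if (sum(keep) < 2L) {
    stop("fewer than 2 eligible observers after exclusions", call. = FALSE)
  }
  vals <- vals[keep, , drop = FALSE]
  ids <- x$observers$observer_id[keep]
  groups <- x$observers$group[keep]
  m <- length(ids)
  rho <- diag(1, m)
  dimnames(rho) <- list(ids, ids)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      r <- tryCatch(spearman_rho(vals[i, ], vals[j, ]),
                    error = function(e) NA_real_)
      rho[i, j] <- rho[j, i] <- r
    }
  }
  structure(list(observer_ids = ids, groups = groups, rho = rho,
                 trial_type = trial_type, excluded = excluded),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d observers, trial type '%s'\n",
              length(x$observer_ids), x$trial_type))
  off <- x$rho[upper.tri(x$rho)]
  cat(sprintf("  mean off-diagonal rho = %.3f (%d NA)\n",
              mean(off, na.rm = TRUE), sum(is.na(off))))
  if (nrow(x$excluded)) {
    cat("  excluded:", paste(sprintf("%s (%s)", x$excluded$observer_id,
                                     x$excluded$reason), collapse = "; "),
        "\n")
  }
  invisible(x)
}

#' Block-average agreement between observer groups
#'
#' Summarizes a correlation matrix as the plain average of its entries over
#' every pair of group blocks: cross-group blocks average all their entries,
#' within-group blocks average the off-diagonal only. Group labels default
#' to those stored in the matrix; passing a named vector (observer id ->
#' label) allows coarser groupings, e.g. collapsing all human groups to
#' `"human"` to read off machine-versus-human agreement.
#'
#' @param corr A [correlation_matrix()].
#' @param groups Optional character vector of group labels, either unnamed
#'   (aligned with `corr$observer_ids`) or named by observer id.
#' @return data.frame of class `block_agreement`: `group_a`, `group_b`,
#'   `trial_type`, `mean_rho`, `n_pairs`.
#' @export
block_agreement <- function(corr, groups = NULL) {
  stopifnot(inherits(corr, "correlation_matrix"))
  if (is.null(groups)) {
    groups <- corr$groups
  } else if (!is.null(names(groups))) {
    idx <- match(corr$observer_ids, names(groups))
    if (anyNA(idx)) {
      stop("`groups` missing labels for: ",
           paste(corr$observer_ids[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    groups <- unname(groups[idx])
  } else if (length(groups) != length(corr$observer_ids)) {
    stop("`groups` must match the number of observers in the matrix",
         call. = FALSE)
  }
  levels <- unique(groups)
  rows <- list()
  for (a in seq_along(levels)) {
    for (b in a:length(levels)) {
      ia <- which(groups == levels[a])
      ib <- which(groups == levels[b])
      block <- corr$rho[ia, ib, drop = FALSE]
      if (a == b) {
        vals <- block[upper.tri(block)]
      } else {
        vals <- as.vector(block)
      }
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L) {
        warning("no usable pairs for block ", levels[a], " x ", levels[b],
                call. = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = levels[a], group_b = levels[b],
        trial_type = corr$trial_type,
        mean_rho = mean(vals), n_pairs = length(vals),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("block_agreement", "data.frame")
  out
}

#' Render a correlation matrix as a heatmap image
#'
#' Writes a heatmap with the conventional diverging palette — blue for
#' negative rank correlation, yellow for zero, red for positive — with
#' observers ordered by group along both axes. Output format follows the
#' file extension (`.png` or `.svg`). Rendering is deterministic.
#'
#' @param corr A [correlation_matrix()].
#' @param path Output file path ending in `.png` or `.svg`.
#' @param width,height Device size in pixels (png) or inches (svg).
#' @return `path`, invisibly.
#' @export
heatmap_export <- function(corr, path, width = NULL, height = NULL) {
  stopifnot(inherits(corr, "correlation_matrix"))
  ord <- order(factor(corr$groups, levels = unique(corr$groups)))
  rho <- corr$rho[ord, ord]
  groups <- corr$groups[ord]
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    grDevices::png(path, width = width %||% 800, height = height %||% 800)
  } else if (ext == "svg") {
    grDevices::svg(path, width = width %||% 8, height = height %||% 8)
  } else {
    stop("unsupported figure format: .", ext, " (use .png or .svg)",
         call. = FALSE)
  }
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("#2166AC", "#FFFFBF", "#B2182B"))(201)
  n <- nrow(rho)
  z <- t(rho[n:1, , drop = FALSE])            # image() draws bottom-up
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::image(seq_len(n), seq_len(n), z, zlim = c(-1, 1), col = pal,
                  axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("Spearman rho, %s-person pairs",
                                 corr$trial_type),
                  useRaster = TRUE)
  # group boundaries
  bounds <- cumsum(rle(groups)$lengths)
  mids <- bounds - rle(groups)$lengths / 2
  graphics::abline(v = utils::head(bounds, -1) + 0.5, col = "grey20")
  graphics::abline(h = n - utils::head(bounds, -1) + 0.5, col = "grey20")
  graphics::axis(1, at = mids, labels = rle(groups)$values, tick = FALSE,
                 las = 2, cex.axis = 0.8)
  graphics::axis(2, at = n - mids + 1, labels = rle(groups)$values,
                 tick = FALSE, las = 2, cex.axis = 0.8)
  graphics::box()
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a correlation matrix and its exclusion log as CSV
#' @param corr A [correlation_matrix()].
#' @param path Output path for the matrix (observer ids in first column).
#' @param excluded_path Optional path for the exclusion log.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(corr, path, excluded_path = NULL) {
  stopifnot(inherits(corr, "correlation_matrix"))
  utils::write.csv(data.frame(observer_id = corr$observer_ids, corr$rho,
                              check.names = FALSE),
                   path, row.names = FALSE)
  if (!is.null(excluded_path)) {
    utils::write.csv(corr$excluded, excluded_path, row.names = FALSE)
  }
  invisible(path)
}
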