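# Base half-width of the innermost confidence band of the discretizer, in
# evidence (z) units. One constant; per-observer extremeness is controlled
# by kappa.
BIN_BASE_WIDTH <- 0.4

#' Generating parameters for a synthetic human observer
#'
#' The generator is an equal-variance Gaussian signal-detection model.
#' Each observer sees latent evidence on every item; `d_star` separates the
#' same-person and different-people evidence distributions (so the
#' closed-form expected AUC is `pnorm(d_star / sqrt(2))`), `c_star` places
#' the decision criterion (negative = liberal toward "same person"),
#' `kappa` controls confidence extremeness (the 11-point discretizer's bands
#' shrink geometrically in `kappa`, so large `kappa` piles responses onto
#' -5/+4/+5), `p_inconclusive` is the probability of responding 0 when the
#' evidence falls in the innermost, least-confident band around the
#' criterion, and `lambda_shared` is the loading on an item-level component
#' shared by all human observers, which induces the inter-observer rank
#' correlation the similarity analyses measure.
#'
#' @param d_star Sensitivity, >= 0 (z-units).
#' @param c_star Criterion (z-units).
#' @param kappa Confidence-extremeness gain, > 0.
#' @param p_inconclusive Probability of a 0 response in the innermost band,
#'   in `[0, 1)`.
#' @param lambda_shared Loading on the shared item component, in `[0, 1)`;
#'   idiosyncratic noise is scaled so total evidence noise has unit variance.
#' @return A list of class `observer_params`.
#' @export
observer_params <- function(d_star, c_star = 0, kappa = 1,
                            p_inconclusive = 0, lambda_shared = 0.5) {
  stopifnot(d_star >= 0, kappa > 0,
            p_inconclusive >= 0, p_inconclusive < 1,
            lambda_shared >= 0, lambda_shared < 1)
  structure(list(d_star = d_star, c_star = c_star, kappa = kappa,
                 p_inconclusive = p_inconclusive,
                 lambda_shared = lambda_shared),
            class = "observer_params")
}

#' Generating parameters for a synthetic machine scorer
#'
#' Machine scorers emit real-valued similarity scores: class separation
#' `d_star` plus a positive loading `lambda_shared` on the human-shared item
#' component (so that at `nu = 0` machines rank items like humans do), minus
#' a divergence component `nu` times the shared component that is active
#' only on different-people items. For `nu > lambda_shared` the machine's
#' rank-ordering of different-people pairs anti-correlates with human
#' ratings while agreement on same-person pairs is untouched — the
#' representational-divergence signature the similarity analysis is built to
#' detect.
#'
#' @param d_star Class separation, >= 0.
#' @param nu Divergence loading on different-people items, >= 0.
#' @param noise_sd Standard deviation of idiosyncratic score noise, > 0.
#' @param lambda_shared Loading on the shared item component, >= 0.
#' @return A list of class `dnn_params`.
#' @export
dnn_params <- function(d_star, nu = 0, noise_sd = 0.5, lambda_shared = 0.5) {
  stopifnot(d_star >= 0, nu >= 0, noise_sd > 0, lambda_shared >= 0)
  structure(list(d_star = d_star, nu = nu, noise_sd = noise_sd,
                 lambda_shared = lambda_shared),
            class = "dnn_params")
}

#' Configure a synthetic study
#'
#' @param n_items Total number of 1-to-1 comparisons.
#' @param n_same Number of same-person items, `0 < n_same < n_items`.
#' @param groups Named list of group rosters; names must be observer groups
#'   (`"novice"`, `"super_recognizer"`, `"forensic_examiner"`,
#'   `"forensic_laboratory"`, `"dnn"`). Each roster is a list with `n`
#'   (observer count), `params` ([observer_params()] or, for `"dnn"`,
#'   [dnn_params()]), and optional `d_star_sd` / `c_star_sd` giving
#'   between-observer Gaussian jitter on those parameters, and `mode`.
#' @param seed Integer seed; a fixed seed fixes the generated study.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_items, n_same, groups, seed = 1) {
  stopifnot(n_same > 0, n_same < n_items)
  if (is.null(names(groups)) || !all(names(groups) %in% OBSERVER_GROUPS)) {
    stop("group roster names must be observer groups", call. = FALSE)
  }
  for (nm in names(groups)) {
    g <- groups[[nm]]
    if (is.null(g$n) || g$n < 1) stop("roster '", nm, "' needs n >= 1",
                                      call. = FALSE)
    want <- if (nm == "dnn") "dnn_params" else "observer_params"
    if (!inherits(g$params, want)) {
      stop("roster '", nm, "' needs params of class ", want, call. = FALSE)
    }
  }
  structure(list(n_items = as.integer(n_items), n_same = as.integer(n_same),
                 groups = groups, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default synthetic proficiency study
#'
#' A ready-made configuration emulating a 20-item forensic proficiency test
#' (13 same-person, 7 different-people pairs) taken by 106 novices, 37
#' super-recognizers, 16 forensic examiners, 19 forensic laboratories and 10
#' machine scorers. Group sensitivities target mean rating-scale AUCs
#' representative of each group (novice 0.762, super-recognizer 0.880,
#' examiner 0.910, laboratory 0.974, machine 0.876): the base inversion is
#' the equal-variance relation `d* = sqrt(2) * qnorm(AUC)`, with the
#' super-recognizer value raised to offset the tie-induced AUC loss of their
#' extreme response style and the machine value set on its own score-noise
#' scale (both calibrated by simulating the generator); criteria place
#' super-recognizers strongly liberal (-1.08) and examiners neutral (-0.10);
#' extremeness and inconclusive-use parameters reproduce the contrast
#' between confidence-extreme super-recognizers (inconclusive on ~0.3% of
#' responses) and hedging examiners (~9% inconclusive). The machine
#' divergence `nu = 0.75` makes machine rank-orderings of different-people
#' pairs anti-correlate with human ratings while agreeing on same-person
#' pairs. See the package vignette for the derivations.
#'
#' @param seed Integer seed.
#' @return A [synthetic_config()].
#' @export
enfsi_synthetic_config <- function(seed = 1) {
  synthetic_config(
    n_items = 20, n_same = 13, seed = seed,
    groups = list(
      novice = list(
        n = 106, d_star_sd = 0.35, c_star_sd = 0.30, mode = "online",
        params = observer_params(d_star = 1.01, c_star = -0.20, kappa = 1.0,
                                 p_inconclusive = 0.05)),
      super_recognizer = list(
        n = 37, d_star_sd = 0.30, c_star_sd = 0.30, mode = "online",
        params = observer_params(d_star = 2.25, c_star = -1.08, kappa = 1.8,
                                 p_inconclusive = 0.02)),
      forensic_examiner = list(
        n = 16, d_star_sd = 0.30, c_star_sd = 0.20, mode = "offline",
        params = observer_params(d_star = 1.90, c_star = -0.10, kappa = 0.8,
                                 p_inconclusive = 0.46)),
      forensic_laboratory = list(
        n = 19, d_star_sd = 0.30, c_star_sd = 0.20, mode = "offline",
        params = observer_params(d_star = 2.75, c_star = 0.00, kappa = 1.0,
                                 p_inconclusive = 0.30)),
      dnn = list(
        n = 10, mode = "not_applicable",
        params = dnn_params(d_star = 1.04, nu = 0.75, noise_sd = 0.5))
    ))
}

# Discretize signed evidence-minus-criterion onto the 11-point scale.
# Band boundaries grow from the criterion as a geometric series with ratio
# 1/kappa: large kappa compresses the outer boundaries toward the criterion
# and pushes mass to the extreme ratings.
discretize_evidence <- function(diff, kappa, p_inconclusive, u01) {
  offsets <- BIN_BASE_WIDTH * cumsum((1 / kappa)^(0:3))
  magnitude <- findInterval(abs(diff), offsets) + 1L   # 1..5
  rating <- ifelse(diff >= 0, magnitude, -magnitude)
  inner <- magnitude == 1L
  rating[inner & u01 < p_inconclusive] <- 0L
  as.integer(rating)
}

#' Generate a synthetic study
#'
#' Draws a complete study from a [synthetic_config()]: an item key, a
#' rating matrix holding integer ratings for human groups and real-valued
#' similarity scores for the `"dnn"` group, and a truth record of every
#' observer's realized generating parameters (after jitter) plus the shared
#' item component. Same-person items carry a `+d*/2` evidence offset and
#' different-people items `-d*/2`; a standard-normal shared component `u`
#' induces inter-human correlation; human evidence is discretized onto the
#' 11-point scale around each observer's criterion. Deterministic given the
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @return List: `matrix` (a [rating_matrix()]; `value_kind` is
#'   `"ordinal_11pt"` when no machine group is present, `"raw_score"`
#'   otherwise), `key` (an [item_key()]), `truth` (data.frame of realized
#'   per-observer parameters) and `u` (the shared item component).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n_items <- config$n_items
  n_same <- config$n_same
  if (n_items == 20 && n_same == 13) {
    key <- enfsi_item_key()
  } else {
    key <- item_key(sprintf("item%03d", seq_len(n_items)),
                    c(rep("same", n_same), rep("different", n_items - n_same)))
  }
  is_same <- key$truth == "same"
  mu <- ifelse(is_same, 0.5, -0.5)     # scaled by each observer's d_star
  u <- stats::rnorm(n_items)

  obs_rows <- list(); value_rows <- list(); truth_rows <- list()
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    p <- g$params
    d_sd <- g$d_star_sd %||% 0
    c_sd <- g$c_star_sd %||% 0
    mode <- g$mode %||% if (gname == "dnn") "not_applicable" else "online"
    for (j in seq_len(g$n)) {
      oid <- sprintf("%s%03d", abbreviate_group(gname), length(obs_rows) + 1L)
      d_j <- max(0, p$d_star + if (d_sd > 0) stats::rnorm(1, 0, d_sd) else 0)
      if (gname == "dnn") {
        load_diff <- p$lambda_shared - p$nu
        score <- d_j * mu + p$lambda_shared * u * is_same +
          load_diff * u * (!is_same) + stats::rnorm(n_items, 0, p$noise_sd)
        values <- score
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          observer_id = oid, group = gname, d_star = d_j, c_star = NA_real_,
          kappa = NA_real_, p_inconclusive = NA_real_,
          lambda_shared = p$lambda_shared, nu = p$nu,
          noise_sd = p$noise_sd, stringsAsFactors = FALSE)
      } else {
        c_j <- p$c_star + if (c_sd > 0) stats::rnorm(1, 0, c_sd) else 0
        lam <- p$lambda_shared
        e <- d_j * mu + lam * u +
          sqrt(1 - lam^2) * stats::rnorm(n_items)
        values <- discretize_evidence(e - c_j, p$kappa, p$p_inconclusive,
                                      stats::runif(n_items))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          observer_id = oid, group = gname, d_star = d_j, c_star = c_j,
          kappa = p$kappa, p_inconclusive = p$p_inconclusive,
          lambda_shared = lam, nu = NA_real_, noise_sd = NA_real_,
          stringsAsFactors = FALSE)
      }
      obs_rows[[length(obs_rows) + 1L]] <- data.frame(
        observer_id = oid, group = gname, mode = mode,
        stringsAsFactors = FALSE)
      value_rows[[length(value_rows) + 1L]] <- values
    }
  }
  observers <- do.call(rbind, obs_rows)
  values <- do.call(rbind, value_rows)
  colnames(values) <- key$item_id
  value_kind <- if ("dnn" %in% observers$group) "raw_score" else "ordinal_11pt"
  mat <- rating_matrix(values, observers, key, value_kind)
  list(matrix = mat, key = key, truth = do.call(rbind, truth_rows), u = u)
}

abbreviate_group <- function(g) {
  c(novice = "nov", super_recognizer = "sr", forensic_examiner = "ex",
    forensic_laboratory = "lab", dnn = "dnn")[[g]]
}

#' Extract the human (ordinal) submatrix of a generated study
#'
#' Convenience for analyses that require ordinal ratings: drops `"dnn"`
#' observers and re-tags the matrix as ordinal.
#'
#' @param x A [rating_matrix()].
#' @return A [rating_matrix()] with `value_kind = "ordinal_11pt"`.
#' @export
human_submatrix <- function(x) {
  stopifnot(inherits(x, "rating_matrix"))
  keep <- x$observers$group != "dnn"
  if (!any(keep)) stop("no human observers present", call. = FALSE)
  rating_matrix(x$values[keep, , drop = FALSE],
                x$observers[keep, , drop = FALSE], x$key, "ordinal_11pt")
}

# Hanley-McNeil standard error of an empirical AUC.
auc_se <- function(auc, n_same, n_diff) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_same - 1) * (q1 - auc^2) +
          (n_diff - 1) * (q2 - auc^2)) / (n_same * n_diff))
}

#' Parameter-recovery report for a synthetic study
#'
#' Generates a study and pushes it back through the analysis stack,
#' comparing what the estimators recover against the generating truth:
#' per-observer estimated criterion and sensitivity versus `c*` and `d*`
#' (with mean absolute error and bias), per-observer empirical AUC versus
#' the closed-form equal-variance prediction `pnorm(d*/sqrt(2))` (with its
#' sampling standard error), and — when machine scorers are present — the
#' sign structure of the human-versus-machine block correlations by trial
#' type.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `recovery_report`: `sdt` (per-observer true vs
#'   estimated), `auc` (per-observer AUC vs closed form), `mae_c`, `mae_d`,
#'   `bias_c`, `bias_d`, `block` (block agreement table or `NULL`).
#' @export
recovery_suite <- function(config) {
  study <- generate_study(config)
  humans <- human_submatrix(study$matrix)
  sdt <- sdt_summary(humans)
  truth <- study$truth
  sdt$c_star <- truth$c_star[match(sdt$observer_id, truth$observer_id)]
  sdt$d_star <- truth$d_star[match(sdt$observer_id, truth$observer_id)]

  acc <- group_auc_summary(study$matrix)$per_observer
  acc$d_star <- truth$d_star[match(acc$observer_id, truth$observer_id)]
  acc$auc_expected <- stats::pnorm(acc$d_star / sqrt(2))
  n_s <- sum(study$key$truth == "same")
  n_d <- sum(study$key$truth == "different")
  acc$auc_se <- auc_se(acc$auc_expected, n_s, n_d)

  block <- NULL
  if ("dnn" %in% study$matrix$observers$group) {
    labels <- ifelse(study$matrix$observers$group == "dnn", "dnn", "human")
    names(labels) <- study$matrix$observers$observer_id
    block <- do.call(rbind, lapply(c("same", "different"), function(tt) {
      corr <- correlation_matrix(study$matrix, trial_type = tt)
      block_agreement(corr, groups = labels)
    }))
  }
  structure(list(
    sdt = sdt, auc = acc,
    mae_c = mean(abs(sdt$criterion_c - sdt$c_star)),
    mae_d = mean(abs(sdt$d_prime - sdt$d_star)),
    bias_c = mean(sdt$criterion_c - sdt$c_star),
    bias_d = mean(sdt$d_prime - sdt$d_star),
    block = block), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat(sprintf("  criterion: MAE %.3f, bias %+.3f\n", x$mae_c, x$bias_c))
  cat(sprintf("  d-prime:   MAE %.3f, bias %+.3f\n", x$mae_d, x$bias_d))
  cat(sprintf("  AUC vs closed form: mean |err| %.3f\n",
              mean(abs(x$auc$auc - x$auc$auc_expected))))
  if (!is.null(x$block)) {
    hx <- x$block[x$block$group_a != x$block$group_b, ]
    for (i in seq_len(nrow(hx))) {
      cat(sprintf("  block %s x %s (%s): mean rho %+.3f\n", hx$group_a[i],
                  hx$group_b[i], hx$trial_type[i], hx$mean_rho[i]))
    }
  }
  invisible(x)
}
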