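test_that("tie-aware Spearman matches the rank-then-Pearson oracle", {
  expect_equal(spearman_rho(c(1, 2, 3), c(2, 4, 9)), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1)), -1)
  # heavy ties: compare against stats::cor as an independent implementation
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(2, 1, 3, 4)),
               stats::cor(c(1, 2, 2, 4), c(2, 1, 3, 4), method = "spearman"))
  set.seed(505)
  for (rep in 1:50) {
    x <- sample(-5:5, 13, replace = TRUE)
    y <- sample(-5:5, 13, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_rho(x, y), stats::cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(spearman_rho(1, 1), "at least 2")
  # missing pairs dropped
  expect_equal(spearman_rho(c(1, 2, NA, 4), c(1, 3, 5, 9)), 1)
})

test_that("correlation matrices exclude degenerate observers with a reason", {
  key <- enfsi_item_key()
  base <- c(5, 4, 3, 5, 2, 1, 4, 3, 5, 2, 1, 4, 3, -1, -2, -3, -4, -5, -1, -2)
  flat_same <- c(rep(5, 13), -1, -2, -3, -4, -5, -1, -2)  # constant on same
  m <- small_matrix(rbind(base, base, flat_same),
                    groups = rep("super_recognizer", 3))
  corr <- correlation_matrix(m, trial_type = "same")
  expect_equal(corr$excluded$observer_id, "obs03")
  expect_match(corr$excluded$reason, "degenerate")
  expect_equal(dim(corr$rho), c(2L, 2L))
  expect_equal(unname(corr$rho[1, 2]), 1)          # identical observers
  expect_equal(diag(corr$rho), c(obs01 = 1, obs02 = 1))
  # same observer is fine on the different-people side
  corr_d <- correlation_matrix(m, trial_type = "different")
  expect_equal(nrow(corr_d$excluded), 0L)
  expect_true(isSymmetric(corr_d$rho))

  # fewer-than-2-responses exclusion
  sparse <- base; sparse[1:12] <- NA
  m2 <- small_matrix(rbind(base, base, sparse),
                     groups = rep("novice", 3))
  corr2 <- correlation_matrix(m2, trial_type = "same")
  expect_match(corr2$excluded$reason, "fewer than 2")
  expect_error(correlation_matrix(small_matrix(rbind(base, flat_same)),
                                  trial_type = "same"),
               "fewer than 2 eligible")
})

test_that("correlation matrices are permutation-equivariant in observer order", {
  study <- generate_study(mini_config(n_items = 30, n_same = 18, n = 8,
                                      d_star = 1.2, lambda_shared = 0.5,
                                      seed = 9))
  m <- study$matrix
  corr <- correlation_matrix(m, trial_type = "same")
  perm <- rev(m$observers$observer_id)
  corr_p <- correlation_matrix(subset_observers(m, perm),
                               trial_type = "same")
  expect_equal(corr_p$rho[corr$observer_ids, corr$observer_ids], corr$rho)
})

test_that("a shared latent component induces positive within-human agreement", {
  study <- generate_study(mini_config(n_items = 60, n_same = 36, n = 12,
                                      d_star = 1.5, lambda_shared = 0.6,
                                      seed = 21))
  for (tt in c("same", "different")) {
    corr <- correlation_matrix(study$matrix, trial_type = tt)
    ba <- block_agreement(corr)
    expect_gt(ba$mean_rho[1], 0)
  }
})

test_that("block agreement averages the right entries", {
  key <- enfsi_item_key()
  base <- c(5, 4, 3, 5, 2, 1, 4, 3, 5, 2, 1, 4, 3, -1, -2, -3, -4, -5, -1, -2)
  m <- small_matrix(rbind(base, base, base),
                    groups = c("novice", "novice", "forensic_examiner"))
  corr <- correlation_matrix(m, trial_type = "same")
  # the singleton examiner block has no off-diagonal pairs -> warned, omitted
  expect_warning(ba <- block_agreement(corr), "no usable pairs")
  expect_equal(nrow(ba), 2L)
  within <- ba[ba$group_a == "novice" & ba$group_b == "novice", ]
  expect_equal(within$mean_rho, 1)
  expect_equal(within$n_pairs, 1L)   # off-diagonal only
  cross <- ba[ba$group_a != ba$group_b, ]
  expect_equal(cross$mean_rho, 1)
  expect_equal(cross$n_pairs, 2L)

  # custom labels collapse groups
  labels <- stats::setNames(c("human", "human", "human"), corr$observer_ids)
  ba2 <- block_agreement(corr, groups = labels)
  expect_equal(nrow(ba2), 1L)
  expect_equal(ba2$n_pairs, 3L)
})

test_that("machine divergence drives down different-pair block agreement only", {
  rhos <- sapply(c(0, 0.5, 1.0), function(nu) {
    cfg <- mini_config(n_items = 100, n_same = 60, n = 15, d_star = 1.5,
                       lambda_shared = 0.5, seed = 77,
                       dnn = list(n = 6, params = dnn_params(
                         d_star = 1.0, nu = nu, noise_sd = 0.5)))
    study <- generate_study(cfg)
    labels <- ifelse(study$matrix$observers$group == "dnn", "dnn", "human")
    names(labels) <- study$matrix$observers$observer_id
    vapply(c("same", "different"), function(tt) {
      ba <- block_agreement(correlation_matrix(study$matrix,
                                               trial_type = tt),
                            groups = labels)
      ba$mean_rho[ba$group_a != ba$group_b]
    }, numeric(1))
  })
  # same-pair agreement stays positive at every divergence level
  expect_true(all(rhos["same", ] > 0))
  # different-pair agreement decreases monotonically in nu and goes negative
  expect_true(all(diff(rhos["different", ]) < 0))
  expect_gt(rhos["different", 1], 0)      # aligned scorers agree
  expect_lt(rhos["different", 3], 0)      # divergent scorers anti-correlate
})

test_that("heatmaps render deterministically to png and svg", {
  study <- generate_study(mini_config(n_items = 20, n_same = 13, n = 6,
                                      d_star = 1.5, lambda_shared = 0.5,
                                      seed = 5))
  corr <- correlation_matrix(study$matrix, trial_type = "same")
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "h1.svg")
  p2 <- file.path(dir, "h2.svg")
  heatmap_export(corr, p1)
  heatmap_export(corr, p2)
  expect_true(file.exists(p1) && file.size(p1) > 0)
  # the svg device numbers its defs with a session-global counter;
  # normalize those ids before comparing renders
  norm <- function(p) gsub("(source|clip|glyph)-[0-9]+(-[0-9]+)?", "\\1-N",
                           readLines(p))
  expect_identical(norm(p1), norm(p2))
  png_path <- file.path(dir, "h.png")
  heatmap_export(corr, png_path)
  expect_true(file.exists(png_path) && file.size(png_path) > 0)
  expect_error(heatmap_export(corr, file.path(dir, "h.pdf")), "unsupported")
})
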