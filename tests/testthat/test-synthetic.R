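test_that("generation is deterministic in the seed and leaves the RNG alone", {
  cfg <- enfsi_synthetic_config(seed = 5)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_study(enfsi_synthetic_config(seed = 6))
  expect_false(identical(s1$matrix$values, s3$matrix$values))

  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_study(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("the default study matches the proficiency-test census", {
  study <- generate_study(enfsi_synthetic_config(seed = 1))
  expect_equal(dim(study$matrix), c(188L, 20L))
  expect_equal(sum(study$key$truth == "same"), 13L)
  tab <- table(study$matrix$observers$group)
  expect_equal(as.integer(tab[c("novice", "super_recognizer",
                                "forensic_examiner", "forensic_laboratory",
                                "dnn")]),
               c(106L, 37L, 16L, 19L, 10L))
  humans <- human_submatrix(study$matrix)
  expect_true(all(humans$values %in% -5:5))
  expect_equal(humans$value_kind, "ordinal_11pt")
})

test_that("config validation rejects malformed rosters", {
  expect_error(synthetic_config(10, 0, list()), "n_same > 0")
  expect_error(synthetic_config(10, 5, list(wizards = list(n = 2))),
               "observer groups")
  expect_error(synthetic_config(10, 5, list(
    dnn = list(n = 2, params = observer_params(1)))), "dnn_params")
  expect_error(observer_params(-1), "d_star")
  expect_error(observer_params(1, kappa = 0), "kappa")
  expect_error(dnn_params(1, nu = -1), "nu")
})

test_that("zero sensitivity yields chance accuracy, strong signal yields ceiling", {
  flat <- generate_study(mini_config(n_items = 200, n_same = 130, n = 20,
                                     d_star = 0, seed = 3))
  aucs <- group_auc_summary(flat$matrix)$per_observer$auc
  expect_lt(abs(mean(aucs) - 0.5), 0.02)

  sharp <- generate_study(mini_config(n_items = 100, n_same = 60, n = 5,
                                      d_star = 8, kappa = 3, seed = 4))
  g <- group_auc_summary(sharp$matrix)
  expect_true(all(g$per_observer$auc == 1))
  prof <- response_profile(sharp$matrix, by = "group")
  expect_equal(prof$stats$n_errors, 0L)
})

test_that("simulated AUC matches the closed-form equal-variance prediction", {
  cfg <- mini_config(n_items = 2000, n_same = 1300, n = 1, d_star = 1.5,
                     lambda_shared = 0, seed = 12)
  study <- generate_study(cfg)
  auc <- group_auc_summary(study$matrix)$per_observer$auc
  expected <- pnorm(1.5 / sqrt(2))
  se <- facefuse:::auc_se(expected, 1300, 700)
  expect_lt(abs(auc - expected), 3 * se)
})

test_that("observer behavior is monotone in its generating knobs", {
  mean_auc <- function(d) {
    study <- generate_study(mini_config(n_items = 200, n_same = 130, n = 10,
                                        d_star = d, seed = 31))
    mean(group_auc_summary(study$matrix)$per_observer$auc)
  }
  aucs <- sapply(c(0.5, 1.5, 2.5), mean_auc)
  expect_true(all(diff(aucs) > 0))

  inc_rate <- function(p) {
    study <- generate_study(mini_config(n_items = 200, n_same = 130, n = 10,
                                        d_star = 1.5, p_inconclusive = p,
                                        seed = 32))
    response_profile(study$matrix, by = "group")$stats$inconclusive_rate
  }
  rates <- sapply(c(0, 0.3, 0.8), inc_rate)
  expect_true(all(diff(rates) > 0))
  expect_equal(rates[1], 0)

  # confidence extremeness: high-kappa observers live at -5/+4/+5
  extreme_mass <- function(kappa) {
    study <- generate_study(mini_config(n_items = 400, n_same = 200, n = 10,
                                        d_star = 1.5, kappa = kappa,
                                        seed = 33))
    usage <- response_profile(study$matrix, by = "group")$usage
    sum(usage[1, c("-5", "-4", "4", "5")])
  }
  expect_gt(extreme_mass(2.5), extreme_mass(0.8))
})

test_that("aligned machine scorers agree with humans on both trial types", {
  cfg <- mini_config(n_items = 100, n_same = 60, n = 12, d_star = 1.5,
                     lambda_shared = 0.5, seed = 41,
                     dnn = list(n = 5, params = dnn_params(
                       d_star = 1.0, nu = 0, noise_sd = 0.5)))
  study <- generate_study(cfg)
  labels <- ifelse(study$matrix$observers$group == "dnn", "dnn", "human")
  names(labels) <- study$matrix$observers$observer_id
  for (tt in c("same", "different")) {
    ba <- block_agreement(correlation_matrix(study$matrix, trial_type = tt),
                          groups = labels)
    expect_gte(ba$mean_rho[ba$group_a != ba$group_b], 0)
  }
})

test_that("the recovery suite recovers generating parameters", {
  # estimator recovery: independent decisive observers, so per-observer
  # errors average out across the cohort
  cfg <- synthetic_config(
    n_items = 200, n_same = 100, seed = 51,
    groups = list(
      super_recognizer = list(n = 20, params = observer_params(
        d_star = 1.5, c_star = -0.5, kappa = 1.2, lambda_shared = 0)),
      forensic_examiner = list(n = 20, params = observer_params(
        d_star = 1.8, c_star = 0.2, kappa = 0.9, lambda_shared = 0))))
  rec <- recovery_suite(cfg)
  expect_lte(rec$mae_c, 0.1)
  expect_lte(rec$mae_d, 0.25)
  expect_lt(abs(rec$bias_c), 0.05)
  # empirical AUC tracks the closed form within sampling error
  expect_true(mean(abs(rec$auc$auc - rec$auc$auc_expected) <=
                     3 * rec$auc$auc_se) >= 0.9)

  # representational structure: shared-loading humans vs divergent machines
  cfg2 <- synthetic_config(
    n_items = 200, n_same = 100, seed = 52,
    groups = list(
      super_recognizer = list(n = 20, params = observer_params(
        d_star = 1.5, c_star = -0.5, kappa = 1.2, lambda_shared = 0.5)),
      dnn = list(n = 5, params = dnn_params(d_star = 1.2, nu = 0.75))))
  rec2 <- recovery_suite(cfg2)
  hx <- rec2$block[rec2$block$group_a != rec2$block$group_b, ]
  expect_gt(hx$mean_rho[hx$trial_type == "same"], 0)
  expect_lt(hx$mean_rho[hx$trial_type == "different"], 0)
})
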