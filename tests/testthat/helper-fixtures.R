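# Shared fixtures and independent oracles used across test files.

# Brute-force AUC oracle: enumerate all (same, different) pairs, count wins
# and half-count ties. Independent of the rank-statistic implementation.
auc_brute <- function(same, diff) {
  wins <- 0
  for (s in same) for (d in diff) {
    if (s > d) wins <- wins + 1 else if (s == d) wins <- wins + 0.5
  }
  wins / (length(same) * length(diff))
}

# A 4-item key: a, b same; c, d different.
tiny_key <- function() {
  item_key(c("a", "b", "c", "d"), c("same", "same", "different", "different"))
}

# Small ordinal matrix on the 20-item inventory with prescribed rows.
small_matrix <- function(rows, groups = rep("novice", nrow(rows)),
                         key = enfsi_item_key()) {
  colnames(rows) <- key$item_id[seq_len(ncol(rows))]
  rating_matrix(rows,
                data.frame(observer_id = sprintf("obs%02d", seq_len(nrow(rows))),
                           group = groups),
                key[seq_len(ncol(rows)), ],
                "ordinal_11pt")
}

# Random named rating vector plus key for property tests.
random_instance <- function(n_same = 13, n_diff = 7,
                            values = -5:5) {
  n <- n_same + n_diff
  key <- item_key(sprintf("i%02d", 1:n),
                  c(rep("same", n_same), rep("different", n_diff)))
  ratings <- stats::setNames(sample(values, n, replace = TRUE), key$item_id)
  list(ratings = ratings, key = key)
}

# Minimal synthetic config: one human group, optional machine group.
mini_config <- function(n_items = 200, n_same = 130, n = 10,
                        d_star = 1.5, c_star = 0, kappa = 1,
                        p_inconclusive = 0, lambda_shared = 0,
                        dnn = NULL, seed = 1,
                        group = "super_recognizer") {
  groups <- stats::setNames(list(list(
    n = n, params = observer_params(d_star, c_star, kappa, p_inconclusive,
                                    lambda_shared))), group)
  if (!is.null(dnn)) groups$dnn <- dnn
  synthetic_config(n_items, n_same, groups, seed = seed)
}
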