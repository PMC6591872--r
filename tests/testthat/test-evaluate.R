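test_that("pair splits partition the known pairs into near-equal folds", {
  Y <- matrix(0, 5, 4)
  Y[1:10] <- 1
  split <- cvp_split(Y, n_folds = 5, seed = 1)
  expect_equal(as.integer(table(split$fold)), rep(2L, 5))
  lin <- (split$disease - 1L) * nrow(Y) + split$mirna
  expect_setequal(lin, which(Y == 1))
  expect_equal(anyDuplicated(lin), 0L)
  # deterministic under a fixed seed, caller RNG untouched
  set.seed(99); before <- runif(1)
  split2 <- cvp_split(Y, n_folds = 5, seed = 1)
  set.seed(99); expect_identical(runif(1), before)
  expect_identical(split, split2)
  expect_error(cvp_split(matrix(0, 3, 3), n_folds = 5), "at least 5")
})

test_that("AUC equals the tie-aware pairwise rank statistic", {
  expect_equal(auc_score(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_score(c(5, 5, 5, 5), c(1, 1, 0, 0)), 0.5)
  expect_equal(auc_score(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_error(auc_score(c(1, 2), c(1, 1)), "both classes")
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(10:120, 1)
    scores <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(auc_score(scores, labels), auc_brute(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("cross-validation is reproducible and evaluates against true unknowns", {
  sim <- tiny_sim()
  cv1 <- run_cv(sim$observed, sim$sim_mirna, sim$sim_disease,
                seed = 3, k = 4, audit = TRUE)
  cv2 <- run_cv(sim$observed, sim$sim_mirna, sim$sim_disease,
                seed = 3, k = 4)
  expect_identical(cv1$mean_auc, cv2$mean_auc)
  expect_true(cv1$mean_auc >= 0 && cv1$mean_auc <= 1)
  expect_identical(dim(cv1$per_fold_auc), c(1L, 5L))
  # negatives never include training positives
  for (rec in cv1$folds) {
    expect_true(all(sim$observed[rec$neg_idx] == 0))
  }
})

test_that("repeated cross-validation reports mean and spread over repeats", {
  sim <- tiny_sim()
  cv <- run_cv(sim$observed, sim$sim_mirna, sim$sim_disease,
               n_repeats = 2, seed = 4, k = 4)
  expect_length(cv$per_repeat_auc, 2L)
  expect_false(is.na(cv$sd_auc))
  expect_equal(cv$mean_auc, mean(cv$per_repeat_auc))
  expect_output(print(cv), "2 x 5-fold")
})

test_that("grid search enumerates the grid and returns the best cell", {
  sim <- tiny_sim()
  gs <- grid_search(sim$observed, sim$sim_mirna, sim$sim_disease,
                    lambda_l = c(0.5, 1), ratio_d = c(0, 0.01),
                    ratio_t = 0.01, seed = 5, k = 4)
  expect_equal(nrow(gs$table), 4L)
  expect_equal(gs$best$mean_auc, max(gs$table$mean_auc))

  single <- grid_search(sim$observed, sim$sim_mirna, sim$sim_disease,
                        lambda_l = 1, ratio_d = 0.01, ratio_t = 0.01,
                        seed = 5, k = 4)
  expect_equal(nrow(single$table), 1L)
  expect_equal(single$best$lambda_l, 1)
  expect_error(grid_search(sim$observed, lambda_l = numeric(0)), "empty")
})

test_that("sensitivity sweeps cover requested values and validate ranges", {
  sim <- tiny_sim()
  tab <- sensitivity_sweep("alpha", c(0, 1), sim$observed,
                           sim$sim_mirna, sim$sim_disease, seed = 6, k = 4)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$value, c(0, 1))
  expect_true(all(tab$mean_auc >= 0 & tab$mean_auc <= 1))
  expect_error(sensitivity_sweep("K", 20, sim$observed, seed = 6),
               "K must be an integer in \\[1, 19\\]")
  expect_error(sensitivity_sweep("p", 0, sim$observed), "\\(0, 1\\]")
  expect_error(sensitivity_sweep("alpha", 1.1, sim$observed), "\\[0, 1\\]")
})

test_that("per-disease ranking sorts by score with index tie-breaks and known flags", {
  Y <- matrix(0, 4, 2, dimnames = list(paste0("m", 1:4), c("dA", "dB")))
  Y[1, 1] <- 1
  scores <- cbind(c(0.9, 0.1, 0.5, 0.7), c(0, 0, 0, 0))
  tab <- rank_for_disease(Y, scores, "dA", top_k = 3)
  expect_equal(tab$mirna, c("m1", "m4", "m3"))
  expect_equal(tab$rank, 1:3)
  expect_equal(tab$known, c(TRUE, FALSE, FALSE))

  # all-tied column falls back to index order, all novel
  tab0 <- rank_for_disease(Y, scores, "dB", top_k = 4)
  expect_equal(tab0$mirna, paste0("m", 1:4))
  expect_false(any(tab0$known[2:4]))
  expect_error(rank_for_disease(Y, scores, "dC"), "unknown disease")
})
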