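test_that("evaluate_binary reproduces hand-derived confusion metrics", {
  # TP=2, FP=1, FN=1, TN=2 via scores/labels chosen to hit those counts
  y <- c(1, 1, 1, 0, 0, 0)
  s <- c(0.9, 0.8, 0.2, 0.7, 0.3, 0.1)
  met <- evaluate_binary(y, s)
  expect_identical(c(met$TP, met$FP, met$FN, met$TN), c(2L, 1L, 1L, 2L))
  expect_equal(met$accuracy, 2 / 3, tolerance = 1e-4)
  expect_equal(met$precision, 2 / 3, tolerance = 1e-4)
  expect_equal(met$sensitivity, 2 / 3, tolerance = 1e-4)
  expect_equal(met$specificity, 2 / 3, tolerance = 1e-4)
  expect_equal(met$f1, 2 / 3, tolerance = 1e-4)
  expect_equal(met$mcc, 1 / 3, tolerance = 1e-4)

  perfect <- evaluate_binary(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$auc, 1)

  # degenerate: no positive calls -> precision flagged, reported as 0
  deg <- evaluate_binary(c(1, 0), c(0.2, 0.1))
  expect_equal(deg$precision, 0)
  expect_true("precision" %in% deg$degenerate)
})

test_that("MCC is invariant under swapping the two classes", {
  set.seed(5)
  for (rep in 1:20) {
    y <- sample(0:1, 30, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- runif(30)
    m1 <- evaluate_binary(y, s)
    m2 <- evaluate_binary(1 - y, 1 - s, threshold = 0.5 - 1e-12)
    expect_equal(m1$mcc, m2$mcc, tolerance = 1e-10)
  }
})

test_that("rank-statistic AUC equals the exhaustive pair-counting oracle", {
  expect_equal(auc_rank(c(1, 0, 1), c(0.9, 0.8, 0.3)), 0.5)
  expect_error(auc_rank(c(1, 1), c(0.5, 0.6)), "one class")
  set.seed(10)
  for (rep in 1:100) {
    n <- sample(5:25, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), sample(1:3, 1))   # force ties sometimes
    expect_equal(auc_rank(y, s), oracle_auc(y, s), tolerance = 1e-12)
  }
})

test_that("grouped_kfold keeps groups atomic and partitions the records", {
  groups <- rep(paste0("g", 1:5), each = 2)      # 10 records, 5 groups of 2
  folds <- grouped_kfold(groups, k = 5, seed = 3)
  test_sets <- lapply(folds, `[[`, "test_idx")
  expect_identical(sort(unlist(test_sets)), 1:10)
  expect_true(all(lengths(test_sets) == 2L))
  for (f in folds) {
    expect_identical(sort(c(f$train_idx, f$test_idx)), 1:10)
    # each test fold is exactly one group
    expect_length(unique(groups[f$test_idx]), 1L)
  }
  # records sharing a group co-occur in every fold
  groups2 <- c("dupA", "dupA", "dupA", paste0("s", 1:7))
  for (f in grouped_kfold(groups2, k = 3, seed = 1)) {
    in_test <- which(groups2 == "dupA") %in% f$test_idx
    expect_true(all(in_test) || !any(in_test))
  }
  expect_error(grouped_kfold(c("a", "a", "b"), k = 3), "fewer groups")
})

test_that("training reduces the loss on separable data and is seed-reproducible", {
  ds <- simulate_dataset(sim_config(n_genes = 80, exon_count_range = c(2L, 3L),
                                    motif_mutation_prob = 0, seed = 7))
  mc <- model_config(l = 8L, h = 8L, a_dim = 4L, f_dim = 8L)
  tc <- train_config(seed = 2, max_epochs = 6L, batch_size = 32L, patience = 6L,
                     deterministic = TRUE)
  fit1 <- train_model(ds, mc, tc)
  expect_lt(tail(fit1$log$train_loss, 1), fit1$log$train_loss[1])
  fit2 <- train_model(ds, mc, tc)
  expect_identical(fit1$log, fit2$log)          # bit-identical epoch logs
  expect_identical(fit1$params, fit2$params)

  # max_epochs = 0 returns the initialized parameters unchanged
  fit0 <- train_model(ds, mc, train_config(seed = 2, max_epochs = 0L))
  expect_identical(unclass(fit0$params)[1:3], unclass(init_params(mc, seed = 2))[1:3])
  expect_identical(nrow(fit0$log), 0L)

  one_class <- subset_dataset(ds, which(vapply(ds$records, `[[`, integer(1), "label") == 1L))
  expect_error(train_model(one_class, mc, tc), "both classes")
})

test_that("cross_validate reports per-fold rows plus mean and sd", {
  ds <- simulate_dataset(sim_config(n_genes = 60, exon_count_range = c(2L, 3L),
                                    motif_mutation_prob = 0, seed = 8))
  mc <- model_config(l = 6L, h = 6L, a_dim = 3L, f_dim = 6L)
  tc <- train_config(seed = 4, max_epochs = 2L, batch_size = 32L)
  cv <- cross_validate(ds, mc, tc, k = 3L, seed = 9)
  expect_identical(nrow(cv$folds), 3L)
  expect_identical(cv$summary$metric,
                   c("accuracy", "precision", "sensitivity", "specificity", "f1", "mcc", "auc"))
  expect_true(all(is.finite(cv$summary$mean)))
})
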