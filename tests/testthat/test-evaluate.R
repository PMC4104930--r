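test_that("mse and the epsilon derivation", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  expect_error(mse(numeric(0), numeric(0)), "length")
  for (s in 1:5) {
    set.seed(s)
    a <- rnorm(20); b <- rnorm(20)
    expect_equal(mse(a, b), sum((a - b)^2) / 20)
  }
  expect_equal(epsilon_from_relative_error(0.25), 0.1)
  expect_equal(epsilon_from_relative_error(0.25, digits = 3), 0.097)
})

test_that("hyperparameter grids match the published settings", {
  g <- make_grids()
  expect_equal(length(g$C), 7)
  expect_equal(min(g$C), 2^-5)
  expect_equal(max(g$C), 2^7)
  expect_equal(g$B, c(0, 0.1, 0.25, 0.5, 0.75, 0.9, 1))
  expect_true(all(c(0, 1) %in% g$B))
  expect_equal(g$epsilon, 0.1)
  gk <- make_grids("kinome_grmt")
  expect_equal(gk$C, c(4, 16, 64, 256))
  expect_error(make_grids("nope"))
})

test_that("protocols share splits across algorithms and pair cleanly", {
  sim <- simulate_mt_tasks(n_per_task = 30, n_tasks = 3, n_attributes = 4,
                           seed = 51)
  proto <- mt_protocol("random_splits", repetitions = 3,
                       train_per_task = 20, test_per_task = 8, seed = 2)
  perf <- run_protocol(c("tSVM", "GRMT"), sim$train,
                       similarity = diag(3),
                       protocol = proto, grids = list(C = 1, B = 0,
                                                      epsilon = 0.1))
  expect_s3_class(perf, "mt_performance")
  expect_equal(nrow(perf), 2 * 3 * 3)
  # GRMT with identity A differs from tSVM only by the shared offset;
  # pairing structure is exact
  wide <- tidyr::pivot_wider(perf, id_cols = c(task, split),
                             names_from = algorithm, values_from = mse)
  expect_false(anyNA(wide$tSVM))
  expect_false(anyNA(wide$GRMT))
})

test_that("1SVM and the TDMT root coincide; TDMT B=0 leaves equal tSVM", {
  sim <- simulate_mt_tasks(n_per_task = 15, n_tasks = 3, n_attributes = 4,
                           seed = 53)
  grids <- list(C = 2, B = 0, epsilon = 0.1)
  star <- star_taxonomy(sim$train$task_labels, rep(0.5, 3))
  p1 <- mtqsar:::.fit_algorithm("1SVM", sim$train, NULL, NULL, grids, 3, 1)
  fit <- train_tdmt(star, sim$train,
                    tdmt_config("gs", C_grid = 2, B_grid = 0, seed = 1))
  root <- fit$nodes[[fit$info$root]]
  x <- sim$test$X[1:10, ]
  expect_equal(p1(x, rep(1, 10)),
               as.numeric(x %*% root$w) + root$offset, tolerance = 1e-6)
  pt <- mtqsar:::.fit_algorithm("tSVM", sim$train, NULL, NULL, grids, 3, 1)
  for (t in 1:3) {
    idx <- which(sim$test$task == t)
    expect_equal(predict(fit, sim$test$X[idx, ], t),
                 pt(sim$test$X[idx, ], rep(t, length(idx))),
                 tolerance = 1e-4)
  }
})

test_that("multi-task transfer helps similar tasks with shared-budget splits", {
  perf <- benchmark_simulated(c("tSVM", "GRMT"), n_per_task = 15,
                              n_tasks = 5, n_attributes = 14,
                              n_splits = 4, grids = list(C = 2^c(-1, 3),
                                                         B = 0,
                                                         epsilon = 0.1),
                              seed = 3)
  m <- tapply(perf$mse, perf$algorithm, mean)
  expect_lt(m["GRMT"], m["tSVM"])
})

test_that("leave-one-sequence-out redistributes the training budget", {
  sim <- simulate_mt_tasks(n_per_task = 40, n_tasks = 3, n_attributes = 4,
                           sigma2 = 0.1, seed = 55)
  star <- sim$taxonomy
  A <- sim$similarity
  proto <- mt_protocol("leave_one_sequence_out", repetitions = 2,
                       train_per_task = 20, test_per_task = 8, seed = 4)
  perf <- leave_one_sequence_out(c("1SVM", "GRMT", "TDMTtax"), sim$train,
                                 similarity = A, taxonomy = star,
                                 protocol = proto,
                                 grids = list(C = 1, B = 0, epsilon = 0.1))
  expect_equal(sort(unique(perf$algorithm)), c("1SVM", "GRMT", "TDMTtax"))
  # every task is held out once per repetition
  expect_equal(nrow(perf), 3 * 3 * 2)
  # highly similar tasks: held-out MSE stays in the same regime as the
  # within-task error (no catastrophic failure)
  expect_lt(mean(perf$mse[perf$algorithm == "GRMT"]),
            4 * mean(perf$mse[perf$algorithm == "1SVM"]) + 1)
})

test_that("leave-one-sequence-out budget accounting is exact", {
  sim <- simulate_mt_tasks(n_per_task = 40, n_tasks = 3, n_attributes = 3,
                           seed = 57)
  # spy on the split sizes through the tSVM predictor's training data:
  # total training size must match the standard protocol's total
  counts <- integer(0)
  orig_fit <- mtqsar:::.fit_algorithm
  local_fit <- function(...) {
    args <- list(...)
    counts <<- c(counts, length(args[[2]]$y))
    orig_fit(...)
  }
  proto <- mt_protocol("leave_one_sequence_out", repetitions = 1,
                       train_per_task = 15, test_per_task = 6, seed = 5)
  with_mocked_bindings(
    .fit_algorithm = local_fit,
    leave_one_sequence_out("1SVM", sim$train, protocol = proto,
                           grids = list(C = 1, B = 0, epsilon = 0.1)),
    .package = "mtqsar")
  expect_equal(counts, rep(3 * 15, 3))
})

test_that("TDMT prediction for a held-out star leaf equals the root model", {
  sim <- simulate_mt_tasks(n_per_task = 20, n_tasks = 3, n_attributes = 3,
                           seed = 59)
  keep <- sim$train$task != 2
  ds <- mt_dataset(sim$train$X[keep, ], sim$train$y[keep],
                   sim$train$task[keep],
                   task_labels = sim$train$task_labels)
  star <- star_taxonomy(sim$train$task_labels, c(0.8, 0.8, 0.8))
  fit <- train_tdmt(star, ds, tdmt_config("tax", C_grid = 1, seed = 1))
  one <- fit$nodes[[fit$info$root]]
  x <- sim$test$X[1:5, ]
  expect_equal(predict(fit, x, 2), as.numeric(x %*% one$w) + one$offset)
})

test_that("paired Wilcoxon tests with multiplicity corrections", {
  tbl <- tibble::tibble(
    algorithm = rep(c("a", "b"), each = 20),
    task = rep(rep(c("t1", "t2"), each = 10), 2),
    split = rep(1:10, 4),
    mse = c(rep(1, 20), rep(1, 10), seq(2, 3, length.out = 10)))
  res <- paired_tests(tbl, "a", "b", correction = "holm")
  expect_equal(res$label[res$task == "t1"], "NoChange")
  expect_true(res$degenerate[res$task == "t1"])
  expect_equal(res$label[res$task == "t2"], "Better")
  # Holm and BH on {0.01, 0.04} with m = 2 both give {0.02, 0.04}
  expect_equal(stats::p.adjust(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  expect_equal(stats::p.adjust(c(0.01, 0.04), "BH"), c(0.02, 0.04))
  expect_error(paired_tests(tbl, "a", "missing"), "must appear")
})

test_that("the Wilcoxon machinery is calibrated under the null", {
  set.seed(61)
  rejections <- 0
  n_tables <- 1000
  for (i in seq_len(n_tables)) {
    a <- rnorm(12)
    b <- rnorm(12)
    rejections <- rejections + (mtqsar:::.wilcoxon_p(a, b) < 0.05)
  }
  expect_equal(rejections / n_tables, 0.05, tolerance = 0.02 / 0.05)
})
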