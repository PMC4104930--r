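sim3 <- simulate_mt_tasks(n_per_task = 12, n_tasks = 3, n_attributes = 4,
                          seed = 41)

test_that("a node with B = 0 is an independent SVR", {
  sub <- sim3$train[sim3$train$task == 1]
  wp <- rnorm(ncol(sub$X))
  fit <- train_node(sub, wp, B = 0, C = 1, epsilon = 0.1,
                    options = tight_opts())
  ref <- train_svr(sub, C = 1, epsilon = 0.1, options = tight_opts())
  expect_lt(max(abs(fit$w - ref$w)), 1e-8)
  expect_equal(fit$offset, ref$offset)
})

test_that("with the loss removed the node collapses onto the scaled parent", {
  sub <- sim3$train[sim3$train$task == 2]
  wp <- rnorm(ncol(sub$X))
  fit <- train_node(sub, wp, B = 0.6, C = 0)
  expect_equal(fit$w, 0.6 * wp)
  expect_error(train_node(sub, wp, B = 1.2, C = 1), "B must lie")
})

test_that("node solutions match the node primal oracle", {
  for (s in 1:25) {
    p <- random_problem(s + 600)
    ds <- mt_dataset(p$X, p$y)
    set.seed(s)
    wp <- rnorm(ncol(p$X))
    B <- sample(c(0.1, 0.5, 0.75, 0.9, 1), 1)
    fit <- train_node(ds, wp, B = B, C = p$C, epsilon = p$epsilon,
                      options = tight_opts(seed = s))
    ora <- oracle_node(p$X, p$y - mean(p$y), wp, B, p$C, p$epsilon)
    expect_lt(max(abs(fit$w - ora$w)), 1e-5)
  }
})

test_that("pull strength B monotonically draws the node to its parent", {
  sub <- sim3$train[sim3$train$task == 1]
  set.seed(43)
  wp <- rnorm(ncol(sub$X))
  d <- vapply(make_grids()$B, function(B) {
    fit <- train_node(sub, wp, B = B, C = 1, epsilon = 0.1,
                      options = tight_opts())
    sqrt(sum((fit$w - wp)^2))
  }, numeric(1))
  expect_true(all(diff(d) <= 1e-7))
})

test_that("node objective beats both the scaled parent and the tSVM weight", {
  sub <- sim3$train[sim3$train$task == 3]
  set.seed(45)
  wp <- rnorm(ncol(sub$X))
  B <- 0.75
  fit <- train_node(sub, wp, B = B, C = 1, epsilon = 0.1,
                    options = tight_opts())
  obj <- function(w) mtqsar:::node_primal_objective(w, sub, wp, B, 1, 0.1)
  expect_lte(obj(fit$w), obj(B * wp) + 1e-8)
  tsvm <- train_svr(sub, C = 1, epsilon = 0.1, options = tight_opts())
  expect_lte(obj(fit$w), obj(tsvm$w) + 1e-8)
})

test_that("top-down training reduces to tSVM and 1SVM at the extremes", {
  star <- star_taxonomy(sim3$train$task_labels, rep(0.5, 3))
  one_C <- tdmt_config("gs", C_grid = 1, B_grid = 0, seed = 7)
  fit <- train_tdmt(star, sim3$train, one_C, options = tight_opts())
  # all-leaf B = 0: leaves are per-task SVR models
  for (t in 1:3) {
    sub <- sim3$train[sim3$train$task == t]
    ref <- train_svr(sub, C = 1, epsilon = 0.1, options = tight_opts())
    expect_lt(max(abs(fit$nodes[[t]]$w - ref$w)), 1e-5)
    expect_equal(predict(fit, sub, t), predict(ref, sub), tolerance = 1e-5)
  }
  # the root model is the pooled 1SVM
  one <- train_svr(sim3$train$X, sim3$train$y, C = 1,
                   epsilon = 0.1, options = tight_opts())
  root <- fit$nodes[[fit$info$root]]
  expect_lt(max(abs(root$w - one$w)), 1e-5)
})

test_that("identical leaves under full pull get identical models", {
  set.seed(47)
  X1 <- matrix(rnorm(10 * 4), 10, 4)
  y1 <- rnorm(10)
  ds <- mt_dataset(rbind(X1, X1), rep(y1, 2), rep(1:2, each = 10),
                   task_labels = c("a", "b"))
  star <- star_taxonomy(c("a", "b"), c(1, 1))
  fit <- train_tdmt(star, ds, tdmt_config("tax", C_grid = 2, seed = 3))
  expect_lt(max(abs(fit$nodes[[1]]$w - fit$nodes[[2]]$w)), 1e-6)
})

test_that("grid search picks sensible pull strengths", {
  # single-entry grid is returned verbatim
  sub <- sim3$train[sim3$train$task == 1]
  sel <- local_grid_search(sub, numeric(ncol(sub$X)), B_grid = 0.5,
                           C_grid = 2, inner_folds = 3, seed = 1)
  expect_equal(sel$B, 0.5)
  expect_equal(sel$C, 2)
  # node generated by the parent model itself: strong pull should win
  votes_same <- votes_anti <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 12
    wp <- rnorm(n, sd = 2)
    X <- matrix(rnorm(18 * n), 18, n)
    y_same <- as.numeric(X %*% wp) + rnorm(18, sd = 0.1)
    sel <- local_grid_search(mt_dataset(X, y_same), wp,
                             B_grid = make_grids()$B,
                             C_grid = 1, inner_folds = 3, seed = s)
    votes_same <- votes_same + (sel$B >= 0.5)
    y_anti <- as.numeric(X %*% (-wp)) + rnorm(18, sd = 0.1)
    sel2 <- local_grid_search(mt_dataset(X, y_anti), wp,
                              B_grid = make_grids()$B,
                              C_grid = 1, inner_folds = 3, seed = s)
    votes_anti <- votes_anti + (sel2$B <= 0.1)
  }
  expect_gte(votes_same, 8)
  expect_gte(votes_anti, 8)
})

test_that("fold reduction on tiny nodes warns", {
  tiny <- sim3$train[1:2]
  expect_warning(
    local_grid_search(tiny, numeric(ncol(tiny$X)), B_grid = 0, C_grid = 1,
                      inner_folds = 3, seed = 1),
    "reducing inner folds")
})

test_that("an unseen leaf inherits and predicts through its parent", {
  # drop task 3's training data entirely
  keep <- sim3$train$task != 3
  ds <- mt_dataset(sim3$train$X[keep, ], sim3$train$y[keep],
                   sim3$train$task[keep],
                   task_labels = sim3$train$task_labels)
  star <- star_taxonomy(sim3$train$task_labels, c(0.9, 0.9, 0.9))
  fit <- train_tdmt(star, ds, tdmt_config("tax", C_grid = 1, seed = 5))
  expect_true(fit$nodes[[3]]$inherited)
  root <- fit$nodes[[fit$info$root]]
  Xte <- sim3$test$X[sim3$test$task == 3, ]
  expect_equal(predict(fit, Xte, 3),
               as.numeric(Xte %*% root$w) + root$offset)
  expect_error(predict(fit, Xte, "nosuch"), "unknown task")
})

test_that("deeper taxonomies train every node and specialize downwards", {
  phy <- parse_newick("((task1:0.9,task2:0.9):0.5,task3:0.4);")
  fit <- train_tdmt(phy, sim3$train, tdmt_config("tax", C_grid = 1,
                                                 seed = 9))
  nd <- tdmt_nodes(fit)
  expect_equal(nrow(nd), 5)      # 3 leaves + root + 1 inner node
  expect_false(any(nd$inherited))
  # the literal-sum compatibility rule differs from the primal rule
  x <- sim3$test$X[1, ]
  expect_false(isTRUE(all.equal(
    predict(fit, x, 1), predict(fit, x, 1, rule = "literal_sum"))))
})

test_that("training cost grows linearly in the number of nodes", {
  # one solver call per node: measured through the per-node bookkeeping
  star <- star_taxonomy(sim3$train$task_labels, rep(0.5, 3))
  fit_star <- train_tdmt(star, sim3$train,
                         tdmt_config("tax", C_grid = 1, seed = 1))
  phy <- parse_newick("((task1:0.9,task2:0.9):0.5,task3:0.4);")
  fit_deep <- train_tdmt(phy, sim3$train,
                         tdmt_config("tax", C_grid = 1, seed = 1))
  expect_equal(length(fit_star$nodes), 4)
  expect_equal(length(fit_deep$nodes), 5)
  expect_true(all(!vapply(fit_deep$nodes, is.null, logical(1))))
})
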