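test_that("epsilon-insensitive loss follows the tube definition", {
  expect_equal(eps_insensitive_loss(1.05, 1.0, 0.1, 2), 0)
  expect_equal(eps_insensitive_loss(1.3, 1.0, 0.1, 2), 0.04)
  expect_equal(eps_insensitive_loss(1.3, 1.0, 0.1, 1), 0.2)
  expect_equal(eps_insensitive_loss(c(1, 2), c(1.05, 1.5), 0.1, 2),
               c(0, (0.5 - 0.1)^2))
  expect_error(eps_insensitive_loss(1, 1, -0.1), "non-negative")
  expect_error(eps_insensitive_loss(1, 1, 0.1, order = 3), "order")
})

test_that("feature normalization realizes the cosine kernel", {
  expect_equal(normalize_features(c(3, 4)), c(0.6, 0.8))
  a <- normalize_features(c(1, 0))
  b <- normalize_features(c(1, 1))
  expect_equal(sum(a * b), sqrt(0.5), tolerance = 1e-12)
  for (s in 1:5) {
    set.seed(s)
    x <- abs(rnorm(6))
    expect_equal(sum(normalize_features(x)^2), 1, tolerance = 1e-12)
  }
  expect_error(normalize_features(c(0, 0)), "all-zero")
  # matrix form, sparse rows stay sparse and unit-norm
  X <- Matrix::rsparsematrix(5, 8, 0.5, rand.x = function(n) abs(rnorm(n)))
  X[1, ] <- 0; X[1, 2] <- 2
  Xn <- normalize_features(X)
  expect_equal(unname(sqrt(Matrix::rowSums(Xn^2))), rep(1, 5),
               tolerance = 1e-12)
})

test_that("solve_dual handles the degenerate all-inside-tube case", {
  X <- matrix(rnorm(12), 4, 3)
  y <- c(0.05, -0.03, 0.02, -0.05)    # all |y| <= eps
  res <- solve_dual(X, y, C = 10, epsilon = 0.1)
  expect_equal(res$beta, rep(0, 4))
  expect_equal(res$w, rep(0, 3))
  expect_equal(res$dual_objective, 0)
})

test_that("zero linear terms reduce to the standard SVR dual", {
  set.seed(7)
  X <- matrix(rnorm(18), 6, 3)
  y <- rnorm(6)
  a <- solve_dual(X, y, C = 2, epsilon = 0.1, options = tight_opts())
  b <- solve_dual(X, y, C = 2, epsilon = 0.1, linear_terms = numeric(6),
                  options = tight_opts())
  expect_identical(a$w, b$w)
})

test_that("coordinate descent matches the dense primal oracle", {
  for (s in 1:50) {
    p <- random_problem(s)
    res <- solve_dual(p$X, p$y, C = p$C, epsilon = p$epsilon,
                      options = tight_opts(seed = s))
    ora <- oracle_svr(p$X, p$y, p$C, p$epsilon)
    expect_lt(max(abs(res$w - ora$w)), 1e-5)
    # strong duality: primal minimum equals the negated dual minimum
    prim <- mtqsar:::svr_primal_objective(res$w, p$X, p$y, p$C, p$epsilon)
    expect_lt(abs(prim + res$dual_objective), 1e-6 * max(1, abs(prim)))
  }
})

test_that("support vectors lie on or outside the tube", {
  for (s in 1:10) {
    p <- random_problem(s + 100)
    res <- solve_dual(p$X, p$y, C = p$C, epsilon = p$epsilon,
                      options = tight_opts(seed = s))
    sv <- which(res$beta != 0)
    if (length(sv)) {
      resid <- abs(as.numeric(p$X %*% res$w)[sv] - p$y[sv])
      expect_true(all(resid >= p$epsilon - 1e-9))
    }
  }
})

test_that("training error is non-increasing in C over the standard grid", {
  set.seed(11)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- as.numeric(X %*% rnorm(5)) + rnorm(40, sd = 0.4)
  fits <- lapply(make_grids()$C, function(C)
    train_svr(X, y, C = C, epsilon = 0.1, options = tight_opts()))
  # the eps-insensitive training loss is monotone in C by convexity
  loss <- vapply(fits, function(m)
    sum(eps_insensitive_loss(predict(m, X), y, 0.1, 2)), numeric(1))
  expect_true(all(diff(loss) <= 1e-8))
  # raw training MSE follows, up to residual drift inside the zero-loss tube
  errs <- vapply(fits, function(m) mse(y, predict(m, X)), numeric(1))
  expect_true(all(diff(errs) <= 1e-3))
})

test_that("larger epsilon yields sparser models", {
  set.seed(13)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- as.numeric(X %*% rnorm(4)) + rnorm(30, sd = 0.5)
  nsv <- vapply(c(0, 0.1, 0.3, 0.6, 1), function(eps) {
    m <- train_svr(X, y, C = 1, epsilon = eps, options = tight_opts())
    sum(m$beta != 0)
  }, numeric(1))
  expect_true(all(diff(nsv) <= 0))
})

test_that("train_svr centers labels and predicts through the offset", {
  # single instance within a wide tube: prediction recovers the label
  X <- matrix(c(1, 0, 0), 1, 3)
  m <- train_svr(X, y = 7.0, C = 100, epsilon = 0.1)
  expect_equal(predict(m, c(1, 0, 0)), 7.0, tolerance = 0.1 + 1e-9)
  # constant labels: zero weight, offset equal to the constant
  X2 <- matrix(rnorm(15), 5, 3)
  m2 <- train_svr(X2, y = rep(4.2, 5), C = 10, epsilon = 0.1)
  expect_equal(m2$w, rep(0, 3))
  expect_equal(m2$offset, 4.2)
  expect_equal(predict(m2, X2), rep(4.2, 5))
  expect_error(train_svr(X2[0, , drop = FALSE], numeric(0)), "non-empty")
})

test_that("L1-loss solution respects the box and matches a fine grid check", {
  set.seed(17)
  X <- matrix(rnorm(10 * 2), 10, 2)
  y <- rnorm(10)
  res <- solve_dual(X, y, C = 0.5, epsilon = 0.1, loss_order = 1,
                    options = tight_opts())
  expect_true(all(abs(res$beta) <= 0.5 + 1e-12))
  # primal value of the solver's w should not beat-able by small perturbations
  f <- function(w) 0.5 * sum(w^2) +
    0.5 * sum(pmax(abs(as.numeric(X %*% w) - y) - 0.1, 0))
  base <- f(res$w)
  set.seed(18)
  for (k in 1:30) expect_gte(f(res$w + rnorm(2, sd = 0.01)), base - 1e-7)
})

test_that("non-convergence is flagged, not silent", {
  set.seed(19)
  X <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20, sd = 3)
  expect_warning(
    res <- solve_dual(X, y, C = 50, epsilon = 0,
                      options = solver_options(tolerance = 1e-12,
                                               max_iter = 2L)),
    "did not converge")
  expect_false(res$converged)
})

test_that("dataset round-trips through the delimited sparse format", {
  sim <- simulate_mt_tasks(n_per_task = 5, n_tasks = 3, n_attributes = 3,
                           seed = 21)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mt_dataset(sim$train, path)
  back <- read_mt_dataset(path, n_features = ncol(sim$train$X))
  expect_equal(as.matrix(back$X), as.matrix(sim$train$X),
               ignore_attr = TRUE)
  expect_equal(back$y, sim$train$y)
  expect_equal(back$task, sim$train$task)
})

test_that("similarity matrix files round-trip exactly", {
  A <- matrix(c(1, 0.25, 0.1, 0.25, 1, 0.5, 0.1, 0.5, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_matrix(A, path)
  expect_equal(read_similarity_matrix(path), A)
})
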