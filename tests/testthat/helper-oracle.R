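# Independent primal oracles: dense BFGS minimization of the convex, C1
# primal objectives. These deliberately share no code with the package's
# dual coordinate-descent path.

tight_opts <- function(seed = 1L)
  solver_options(tolerance = 1e-9, max_iter = 200000L, seed = seed)

# single-task L2-loss eps-insensitive SVR primal (labels already centered)
oracle_svr <- function(X, y, C, epsilon) {
  X <- as.matrix(X)
  f <- function(w) {
    xi <- as.numeric(X %*% w)
    0.5 * sum(w^2) + C * sum(pmax(abs(xi - y) - epsilon, 0)^2)
  }
  g <- function(w) {
    r <- as.numeric(X %*% w) - y
    a <- pmax(abs(r) - epsilon, 0) * sign(r)
    w + 2 * C * as.numeric(t(X) %*% a)
  }
  o <- stats::optim(numeric(ncol(X)), f, g, method = "BFGS",
                    control = list(maxit = 50000, reltol = 1e-16))
  list(w = o$par, objective = o$value)
}

# graph-regularized multi-task primal over all task weights jointly;
# K = I_T + L (optionally with ridge dropped for unseen tasks)
oracle_grmt <- function(X, y, task, A, C, epsilon, unseen_tasks = integer()) {
  X <- as.matrix(X)
  Tn <- nrow(A)
  n <- ncol(X)
  L <- diag(colSums(A), Tn) - A
  K <- diag(Tn) + L
  for (t in unseen_tasks) K[t, t] <- K[t, t] - 1
  f <- function(v) {
    W <- matrix(v, n, Tn)
    xi <- rowSums(X * t(W)[task, , drop = FALSE])
    0.5 * sum(diag(crossprod(W) %*% K)) +
      C * sum(pmax(abs(xi - y) - epsilon, 0)^2)
  }
  g <- function(v) {
    W <- matrix(v, n, Tn)
    xi <- rowSums(X * t(W)[task, , drop = FALSE])
    a <- 2 * C * pmax(abs(xi - y) - epsilon, 0) * sign(xi - y)
    G <- W %*% K
    for (t in unique(task)) {
      idx <- which(task == t)
      G[, t] <- G[, t] + as.numeric(t(X[idx, , drop = FALSE]) %*% a[idx])
    }
    as.numeric(G)
  }
  o <- stats::optim(numeric(n * Tn), f, g, method = "BFGS",
                    control = list(maxit = 50000, reltol = 1e-16))
  list(W = matrix(o$par, n, Tn), objective = o$value)
}

# top-down node primal with parent pull (labels already centered)
oracle_node <- function(X, y, wp, B, C, epsilon) {
  X <- as.matrix(X)
  f <- function(w) {
    xi <- as.numeric(X %*% w)
    (1 - B) / 2 * sum(w^2) + B / 2 * sum((w - wp)^2) +
      C * sum(pmax(abs(xi - y) - epsilon, 0)^2)
  }
  g <- function(w) {
    r <- as.numeric(X %*% w) - y
    a <- pmax(abs(r) - epsilon, 0) * sign(r)
    (1 - B) * w + B * (w - wp) + 2 * C * as.numeric(t(X) %*% a)
  }
  o <- stats::optim(numeric(ncol(X)), f, g, method = "BFGS",
                    control = list(maxit = 50000, reltol = 1e-16))
  list(w = o$par, objective = o$value)
}

# small random dense multi-task problem for property sweeps
random_problem <- function(seed, l_max = 12, n_max = 6, t_max = 3) {
  set.seed(seed)
  Tn <- sample.int(t_max, 1)
  l <- sample(seq(Tn, l_max), 1)
  n <- sample.int(n_max, 1)
  X <- matrix(round(stats::rnorm(l * n), 3), l, n)
  y <- round(stats::rnorm(l, sd = 2), 3)
  task <- c(seq_len(Tn), sample.int(Tn, l - Tn, replace = TRUE))
  A <- matrix(stats::runif(Tn * Tn), Tn, Tn)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  list(X = X, y = y, task = task, A = A, Tn = Tn,
       C = round(stats::runif(1, 0.3, 4), 2),
       epsilon = sample(c(0, 0.05, 0.1, 0.3), 1))
}
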