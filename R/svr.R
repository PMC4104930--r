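#' The epsilon-insensitive loss
#'
#' \eqn{l_\epsilon(\xi, y) = \max(|\xi - y| - \epsilon, 0)^{order}}: residuals
#' within the tube of half-width `epsilon` cost nothing; outside it the excess
#' is penalized linearly (L1) or quadratically (L2). The L2 form models the
#' mean squared error directly and is the package default throughout.
#'
#' @param xi predicted value(s) \eqn{w^T x}.
#' @param y observed value(s).
#' @param epsilon non-negative tube half-width.
#' @param order 1 or 2 (L1 or L2 loss).
#' @return Non-negative numeric of the common length of `xi` and `y`.
#' @examples
#' eps_insensitive_loss(1.3, 1.0, epsilon = 0.1, order = 2) # (0.3 - 0.1)^2
#' @export
eps_insensitive_loss <- function(xi, y, epsilon = 0.1, order = 2) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon < 0)
    stop("epsilon must be a non-negative scalar")
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  pmax(abs(xi - y) - epsilon, 0)^order
}

#' Solver options
#'
#' @param tolerance stopping threshold on the maximal projected-gradient
#'   violation over one epoch, relative to the first epoch's violation
#'   (floored at 1), so the criterion is insensitive to the scale of `C`
#'   and of the labels.
#' @param max_iter maximum number of epochs (full passes over the data).
#' @param seed integer seed driving the per-epoch random permutation of
#'   coordinate order.
#' @return A list of options for [solve_dual()] and the training functions.
#' @export
solver_options <- function(tolerance = 1e-3, max_iter = 30000L, seed = 1L) {
  stopifnot(tolerance > 0, max_iter >= 1)
  list(tolerance = tolerance, max_iter = as.integer(max_iter),
       seed = as.integer(seed))
}

#' Dual coordinate descent for linear epsilon-insensitive SVR
#'
#' Minimizes the SVR dual
#' \deqn{f_D(\beta) = \tfrac12 \beta^T Q \beta +
#'   \sum_i \epsilon|\beta_i| - y_i\beta_i + \tfrac{\beta_i^2}{4C}}
#' (the \eqn{\beta^2/(4C)} term realizes the L2 loss; with L1 loss it is
#' dropped and \eqn{|\beta_i| \le C} is enforced instead), extended with
#' custom per-instance linear terms \eqn{-\sum_i \beta_i p_i}, which amount
#' to shifting the effective labels to \eqn{y_i + p_i}. The primal weight
#' vector is recovered as \eqn{w = \sum_i \beta_i x_i}.
#'
#' Labels are assumed to be centered by the caller. One coordinate epoch
#' visits all instances in a fresh random permutation; the solver stops when
#' the largest projected-gradient violation within an epoch falls below
#' `options$tolerance`. Non-convergence at `max_iter` is flagged on the
#' result (with a warning), never silent.
#'
#' @param X instances in rows (matrix or sparseMatrix) or an [mt_dataset()].
#' @param y centered labels (ignored if `X` is an `mt_dataset`).
#' @param C positive cost parameter.
#' @param epsilon non-negative tube half-width.
#' @param linear_terms numeric vector `p` of per-instance linear terms
#'   (default all zero, giving the standard SVR dual).
#' @param loss_order 1 or 2.
#' @param options see [solver_options()].
#' @return A list with `w`, `beta`, `dual_objective`, `iterations`,
#'   `converged`, `max_violation`.
#' @export
solve_dual <- function(X, y = NULL, C = 1, epsilon = 0.1,
                       linear_terms = NULL, loss_order = 2,
                       options = solver_options()) {
  if (inherits(X, "mt_dataset")) {
    y <- X$y
    X <- X$X
  }
  stopifnot(C > 0, epsilon >= 0, loss_order %in% c(1, 2))
  l <- nrow(X)
  if (is.null(linear_terms)) linear_terms <- numeric(l)
  stopifnot(length(linear_terms) == l, length(y) == l)
  Xt <- .solver_matrix(X)
  res <- .cd_svr(Xt, as.numeric(y), C, epsilon, as.numeric(linear_terms),
                 as.integer(loss_order), options$tolerance,
                 options$max_iter, options$seed)
  if (!res$converged)
    warning(sprintf(
      "dual coordinate descent did not converge in %d epochs (violation %.3g)",
      options$max_iter, res$max_violation))
  res
}

#' Train a linear epsilon-insensitive SVR model
#'
#' Solves the primal problem
#' \deqn{\min_w \tfrac12\|w\|^2 + C \sum_i l_\epsilon(w^T x_i, y_i)}
#' via its dual with coordinate descent. The target values are centered
#' before optimization and the training-label mean is kept as the model's
#' bias, so predictions are \eqn{\hat y = w^T x + \mathrm{offset}} (no
#' regularized bias term).
#'
#' @param dataset an [mt_dataset()] (task structure ignored), or a
#'   matrix/sparseMatrix of instances in rows.
#' @param y labels when `dataset` is a plain matrix.
#' @param C,epsilon,loss_order SVR parameters; see [eps_insensitive_loss()].
#' @param offset optional fixed centering value; defaults to `mean(y)`. Used
#'   by multi-task reductions that must share a common offset.
#' @param options see [solver_options()].
#' @return An object of class `svr_model` with elements `w`, `offset`, `C`,
#'   `epsilon`, `loss_order`, `beta`, `converged`, `dual_objective`.
#' @examples
#' d <- simulate_mt_tasks(n_per_task = 20, n_tasks = 1, n_attributes = 4,
#'                        seed = 1)
#' fit <- train_svr(d$train, C = 1, epsilon = 0.1)
#' head(predict(fit, d$test))
#' @export
train_svr <- function(dataset, y = NULL, C = 1, epsilon = 0.1,
                      loss_order = 2, offset = NULL,
                      options = solver_options()) {
  if (inherits(dataset, "mt_dataset")) {
    y <- dataset$y
    X <- dataset$X
  } else {
    X <- dataset
  }
  if (is.null(y) || nrow(X) == 0) stop("training data must be non-empty")
  if (is.null(offset)) offset <- mean(y)
  res <- solve_dual(X, y - offset, C = C, epsilon = epsilon,
                    loss_order = loss_order, options = options)
  structure(
    list(w = res$w, offset = offset, C = C, epsilon = epsilon,
         loss_order = loss_order, beta = res$beta,
         converged = res$converged, iterations = res$iterations,
         dual_objective = res$dual_objective),
    class = "svr_model"
  )
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf(
    "<svr_model> %d features, C = %g, epsilon = %g, L%d loss, %d SVs%s\n",
    length(x$w), x$C, x$epsilon, x$loss_order, sum(x$beta != 0),
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Predict from a fitted SVR model
#'
#' @param object an `svr_model`.
#' @param newdata an [mt_dataset()], matrix/sparseMatrix of instances in
#'   rows, or a single numeric feature vector.
#' @param ... unused.
#' @return Numeric vector \eqn{w^T x + \mathrm{offset}}.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  .linear_predict(object$w, object$offset, newdata)
}

.linear_predict <- function(w, offset, newdata) {
  if (inherits(newdata, "mt_dataset")) newdata <- newdata$X
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(w))
    stop("feature dimension of newdata does not match the model")
  as.numeric(newdata %*% w) + offset
}

# primal objective of the single-task SVR (used for duality-gap checks)
svr_primal_objective <- function(w, X, y, C, epsilon, loss_order = 2) {
  if (inherits(X, "mt_dataset")) {
    y <- X$y
    X <- X$X
  }
  xi <- as.numeric(X %*% w)
  0.5 * sum(w^2) + C * sum(eps_insensitive_loss(xi, y, epsilon, loss_order))
}
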