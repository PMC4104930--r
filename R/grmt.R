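#' Graph Laplacian of a task-similarity matrix
#'
#' Given a symmetric non-negative adjacency matrix `A` encoding pairwise task
#' similarities, computes \eqn{L = D - A} with
#' \eqn{D_{st} = \delta_{st}\sum_k A_{kt}}, and the cached inverse
#' \eqn{M = (I_T + L)^{-1}} used by the graph-regularized multi-task dual.
#' `M` is obtained by a symmetric positive-definite solve, not explicit
#' inversion. Note that `L` is unchanged by any modification of `diag(A)`
#' (the diagonal cancels in `D - A`), so the convention `diag(A) = 1` is
#' harmless.
#'
#' @param A symmetric numeric matrix with non-negative entries.
#' @return A list of class `graph_laplacian` with elements `L`, `M`, `A`.
#' @examples
#' graph_laplacian(matrix(c(1, 0.5, 0.5, 1), 2))$L
#' @export
graph_laplacian <- function(A) {
  .check_adjacency(A)
  Tn <- nrow(A)
  L <- diag(colSums(A), Tn) - A
  K <- diag(Tn) + L
  M <- chol2inv(chol(K))
  dimnames(L) <- dimnames(M) <- dimnames(A)
  structure(list(L = L, M = M, A = A), class = "graph_laplacian")
}

.check_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("A must be a square matrix")
  if (any(A < 0)) stop("A must be non-negative")
  if (max(abs(A - t(A))) > 1e-9) stop("A must be symmetric")
  invisible(A)
}

#' Graph regularizer on a set of task weight vectors
#'
#' The similarity-weighted sum of squared distances between task models,
#' \deqn{J(w_1,\dots,w_T) = \tfrac14 \sum_s\sum_t A_{st}\|w_s - w_t\|^2
#'     = \tfrac12 \sum_s\sum_t L_{st} w_s^T w_t.}
#'
#' @param weights a `features x T` matrix of task weight vectors (columns).
#' @param A symmetric non-negative `T x T` similarity matrix.
#' @return Non-negative scalar.
#' @export
grmt_regularizer <- function(weights, A) {
  .check_adjacency(A)
  if (ncol(weights) != nrow(A))
    stop("number of weight vectors must match dim(A)")
  G <- crossprod(weights)             # G_st = w_s' w_t
  sq <- outer(diag(G), diag(G), "+") - 2 * G
  0.25 * sum(A * sq)
}

#' Train a graph-regularized multi-task SVR (GRMT)
#'
#' Jointly trains one linear SVR per task while coupling the task weight
#' vectors through the graph-Laplacian penalty
#' \eqn{\frac12\sum_{st} L_{st} w_s^T w_t} built from the task-similarity
#' matrix `A`:
#' \deqn{\min_{w_1..w_T} \tfrac12\sum_t \|w_t\|^2 +
#'   \tfrac14\sum_{s,t} A_{st}\|w_s-w_t\|^2 +
#'   C\sum_i l_\epsilon(w_{t_i}^T x_i, y_i).}
#' The dual is solved by coordinate descent where the effective inner
#' products are weighted by \eqn{M = (I_T + L)^{-1}}. Labels are centered by
#' the global mean across all tasks and that mean is the shared prediction
#' offset.
#'
#' With `A = I_T` (equivalently, any diagonal `A`) the coupling vanishes and
#' the per-task models coincide with independently trained SVRs sharing the
#' same `C` and offset.
#'
#' @param dataset an [mt_dataset()]; every task id must lie in
#'   `1..nrow(A)`.
#' @param A symmetric non-negative task-similarity matrix (`T x T`). Entries
#'   are used as supplied; normalization to \[0, 1\] is the similarity
#'   provider's job.
#' @param C,epsilon SVR parameters (L2 loss).
#' @param unseen_tasks integer ids of tasks with no training instances whose
#'   ridge term \eqn{\|w_t\|^2} should be dropped, so that such a task's
#'   weight is determined purely by its similarity to trained tasks
#'   (leave-one-sequence-out adaptation). The modified system must remain
#'   positive definite, which requires each unseen task to have positive
#'   similarity to some other task.
#' @param offset optional fixed centering value (defaults to the global
#'   label mean).
#' @param options see [solver_options()].
#' @return An object of class `grmt_model` with `W` (`features x T` weight
#'   matrix), `offset`, `C`, `epsilon`, `A`, `laplacian`, `beta`,
#'   `converged`, `dual_objective`, `task_labels`.
#' @export
train_grmt <- function(dataset, A, C = 1, epsilon = 0.1,
                       unseen_tasks = integer(), offset = NULL,
                       options = solver_options()) {
  stopifnot(inherits(dataset, "mt_dataset"))
  .check_adjacency(A)
  Tn <- nrow(A)
  if (any(dataset$task > Tn))
    stop("task id outside 1..T for the supplied similarity matrix")
  if (length(unseen_tasks) &&
      any(unseen_tasks %in% dataset$task))
    stop("unseen_tasks must have no training instances")
  lap <- graph_laplacian(A)
  M <- lap$M
  if (length(unseen_tasks)) {
    K <- diag(Tn) + lap$L
    for (t in unseen_tasks) K[t, t] <- K[t, t] - 1
    ch <- tryCatch(chol(K), error = function(e) NULL)
    ev_ok <- !is.null(ch) &&
      min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) > 1e-10
    if (!ev_ok)
      stop("dropping the ridge term of the unseen task(s) leaves the ",
           "system non-positive-definite (no similarity ties the task ",
           "to a trained one)")
    M <- chol2inv(ch)
  }
  if (is.null(offset)) offset <- mean(dataset$y)
  Xt <- .solver_matrix(dataset$X)
  res <- .cd_grmt(Xt, dataset$y - offset, dataset$task - 1L, M, C, epsilon,
                  options$tolerance, options$max_iter, options$seed)
  if (!res$converged)
    warning(sprintf(
      "GRMT coordinate descent did not converge in %d epochs (violation %.3g)",
      options$max_iter, res$max_violation))
  W <- res$W
  colnames(W) <- dataset$task_labels[seq_len(Tn)]
  structure(
    list(W = W, offset = offset, C = C, epsilon = epsilon, A = A,
         laplacian = lap, beta = res$beta, converged = res$converged,
         iterations = res$iterations, dual_objective = res$dual_objective,
         task_labels = colnames(W)),
    class = "grmt_model"
  )
}

#' @export
print.grmt_model <- function(x, ...) {
  cat(sprintf(
    "<grmt_model> %d tasks, %d features, C = %g, epsilon = %g, %d SVs%s\n",
    ncol(x$W), nrow(x$W), x$C, x$epsilon, sum(x$beta != 0),
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Predict for a specific task from a multi-task model
#'
#' @param model a `grmt_model` (or any object with a `features x T` weight
#'   matrix `W` and scalar `offset`).
#' @param newdata instances in rows (or a single feature vector).
#' @param task integer task id in `1..T` or a task label.
#' @return Numeric vector \eqn{w_t^T x + \mathrm{offset}}.
#' @export
predict_task <- function(model, newdata, task) {
  if (is.character(task)) {
    task <- match(task, model$task_labels)
    if (is.na(task)) stop("unknown task label")
  }
  if (task < 1 || task > ncol(model$W)) stop("unknown task id")
  .linear_predict(model$W[, task], model$offset, newdata)
}

#' @param object a `grmt_model`.
#' @param newdata instances in rows.
#' @param task task id(s) (scalar, or one per instance).
#' @param ... unused.
#' @rdname predict_task
#' @export
predict.grmt_model <- function(object, newdata, task, ...) {
  if (inherits(newdata, "mt_dataset") && missing(task)) task <- newdata$task
  if (length(task) == 1) return(predict_task(object, newdata, task))
  X <- if (inherits(newdata, "mt_dataset")) newdata$X else newdata
  stopifnot(length(task) == nrow(X))
  out <- numeric(nrow(X))
  for (t in unique(task)) {
    idx <- which(task == t)
    out[idx] <- predict_task(object, X[idx, , drop = FALSE], t)
  }
  out
}

# primal objective of the GRMT problem (duality/oracle checks)
grmt_primal_objective <- function(W, dataset, A, C, epsilon) {
  xi <- numeric(length(dataset$y))
  for (t in unique(dataset$task)) {
    idx <- which(dataset$task == t)
    xi[idx] <- as.numeric(dataset$X[idx, , drop = FALSE] %*% W[, t])
  }
  0.5 * sum(W^2) + grmt_regularizer(W, A) +
    C * sum(eps_insensitive_loss(xi, dataset$y, epsilon, 2))
}
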