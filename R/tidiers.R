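#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an SVR model into a term/estimate tibble
#'
#' @param x an `svr_model`.
#' @param keep_zero include zero-weight features (default drops them).
#' @param ... unused.
#' @return A tibble with columns `term` (0-based feature index) and
#'   `estimate`.
#' @export
tidy.svr_model <- function(x, keep_zero = FALSE, ...) {
  idx <- if (keep_zero) seq_along(x$w) else which(x$w != 0)
  tibble::tibble(term = idx - 1L, estimate = x$w[idx])
}

#' @rdname tidy.svr_model
#' @export
glance.svr_model <- function(x, ...) {
  tibble::tibble(C = x$C, epsilon = x$epsilon, loss_order = x$loss_order,
                 offset = x$offset, n_support_vectors = sum(x$beta != 0),
                 dual_objective = x$dual_objective,
                 iterations = x$iterations, converged = x$converged)
}

#' Tidy a graph-regularized multi-task model
#'
#' @param x a `grmt_model`.
#' @param keep_zero include zero weights.
#' @param ... unused.
#' @return A tibble with columns `task`, `term`, `estimate`.
#' @export
tidy.grmt_model <- function(x, keep_zero = FALSE, ...) {
  purrr::map_dfr(seq_len(ncol(x$W)), function(t) {
    w <- x$W[, t]
    idx <- if (keep_zero) seq_along(w) else which(w != 0)
    tibble::tibble(task = x$task_labels[t], term = idx - 1L,
                   estimate = w[idx])
  })
}

#' @rdname tidy.grmt_model
#' @export
glance.grmt_model <- function(x, ...) {
  tibble::tibble(n_tasks = ncol(x$W), C = x$C, epsilon = x$epsilon,
                 offset = x$offset, n_support_vectors = sum(x$beta != 0),
                 regularizer = grmt_regularizer(x$W, x$A),
                 dual_objective = x$dual_objective,
                 iterations = x$iterations, converged = x$converged)
}

#' Tidy a top-down multi-task model
#'
#' @param x a `tdmt_model`.
#' @param ... unused.
#' @return [tdmt_nodes()] of the model: one row per taxonomy node with the
#'   selected B and C.
#' @export
tidy.tdmt_model <- function(x, ...) tdmt_nodes(x)

#' @rdname tidy.tdmt_model
#' @export
glance.tdmt_model <- function(x, ...) {
  nd <- tdmt_nodes(x)
  tibble::tibble(mode = x$config$mode, n_tasks = x$info$n_tips,
                 n_nodes = nrow(nd),
                 n_inherited = sum(nd$inherited),
                 mean_leaf_B = mean(nd$B[nd$is_leaf], na.rm = TRUE),
                 epsilon = x$config$epsilon)
}

#' Box plot of per-task test errors by algorithm
#'
#' @param object an `mt_performance` tibble (from [run_protocol()],
#'   [benchmark_simulated()], ...).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mt_performance <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$algorithm, y = .data$mse,
                               fill = .data$algorithm)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "test MSE") +
    ggplot2::theme_minimal()
}

#' Learning-curve plot of mean test MSE against training-set size
#'
#' @param curve output of [learning_curve_simulated()].
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(curve) {
  summ <- curve |>
    dplyr::group_by(.data$algorithm, .data$n_per_task) |>
    dplyr::summarise(mse = mean(.data$mse), .groups = "drop")
  ggplot2::ggplot(summ,
                  ggplot2::aes(x = .data$n_per_task, y = .data$mse,
                               colour = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training instances per task", y = "mean test MSE",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
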