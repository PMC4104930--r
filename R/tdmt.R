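#' Train one node of a top-down multi-task model
#'
#' Solves the node problem
#' \deqn{\min_w \tfrac{1-B}{2}\|w\|^2 + \tfrac{B}{2}\|w - w_p\|^2 +
#'   C\sum_{i\in S} l_\epsilon(w^T x_i, y_i),}
#' which balances fitting the instances `S` of the current subtree against
#' staying close to the (fixed) parent weight \eqn{w_p}. Up to a constant it
#' equals \eqn{\tfrac12\|w\|^2 - B w^T w_p + C\sum l_\epsilon}; substituting
#' \eqn{v = w - B w_p} reduces it to a standard SVR on labels shifted by the
#' parent's contribution, solved via [solve_dual()] with custom linear terms,
#' with \eqn{w = B w_p + v}. `B = 0` is an independent model; `B = 1` pulls
#' maximally towards the parent; `C = 0` gives the analytic minimum
#' \eqn{w = B w_p}.
#'
#' Labels are centered on the node's own mean unless `offset` is supplied.
#'
#' @param dataset instances of the node's subtree (an [mt_dataset()], task
#'   structure ignored).
#' @param parent_weight numeric weight vector of the parent model (all zeros
#'   at the root).
#' @param B pull strength in \[0, 1\].
#' @param C,epsilon SVR parameters (L2 loss).
#' @param offset optional fixed centering value; defaults to the node label
#'   mean.
#' @param options see [solver_options()].
#' @return A list with `w`, `offset`, `B`, `C`, `epsilon`, `beta`,
#'   `converged`.
#' @export
train_node <- function(dataset, parent_weight, B, C = 1, epsilon = 0.1,
                       offset = NULL, options = solver_options()) {
  if (B < 0 || B > 1) stop("B must lie in [0, 1]")
  stopifnot(inherits(dataset, "mt_dataset"))
  if (is.null(offset)) offset <- mean(dataset$y)
  pull <- B * parent_weight
  if (C == 0) {
    # loss term absent: the regularizer's analytic minimizer
    return(list(w = pull, offset = offset, B = B, C = C, epsilon = epsilon,
                beta = numeric(length(dataset$y)), converged = TRUE))
  }
  # parent contribution on the (uncentered) features, node-centered labels
  p <- -as.numeric(dataset$X %*% pull)
  res <- solve_dual(dataset$X, dataset$y - offset, C = C, epsilon = epsilon,
                    linear_terms = p, loss_order = 2, options = options)
  list(w = pull + res$w, offset = offset, B = B, C = C, epsilon = epsilon,
       beta = res$beta, converged = res$converged)
}

#' Top-down multi-task configuration
#'
#' @param mode `"tax"` (pull strengths B taken from the scaled taxonomy edge
#'   weights) or `"gs"` (B chosen per node by a local grid search with inner
#'   cross-validation).
#' @param C_grid candidate cost values; default the standard grid
#'   \eqn{2^{-5}, 2^{-3}, \dots, 2^{7}}.
#' @param B_grid candidate pull strengths for `"gs"` mode.
#' @param inner_folds folds of the per-node inner cross-validation.
#' @param prevent_negative_transfer logical; add `B = 0` to the grid at leaf
#'   nodes so a leaf may opt out of transfer entirely. Off by default.
#' @param epsilon tube half-width.
#' @param seed integer seed for fold assignment and the solver.
#' @return A list of class `tdmt_config`.
#' @export
tdmt_config <- function(mode = c("tax", "gs"),
                        C_grid = make_grids()$C,
                        B_grid = make_grids()$B,
                        inner_folds = 3L,
                        prevent_negative_transfer = FALSE,
                        epsilon = 0.1,
                        seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(C_grid) >= 1, length(B_grid) >= 1, inner_folds >= 2)
  structure(
    list(mode = mode, C_grid = sort(C_grid), B_grid = sort(B_grid),
         inner_folds = as.integer(inner_folds),
         prevent_negative_transfer = isTRUE(prevent_negative_transfer),
         epsilon = epsilon, seed = as.integer(seed)),
    class = "tdmt_config")
}

#' Local grid search for a node's (B, C)
#'
#' Evaluates every (B, C) combination by `inner_folds`-fold cross-validation
#' of the node problem with the parent weight held fixed, and returns the
#' pair with minimal mean validation MSE. Ties are broken towards smaller B,
#' then smaller C. If the node has fewer instances than folds, the fold
#' count is reduced (with a warning).
#'
#' @param dataset the node's instances.
#' @param parent_weight fixed parent weight vector.
#' @param B_grid,C_grid candidate values.
#' @param inner_folds number of folds (>= 2).
#' @param epsilon tube half-width.
#' @param seed integer seed (fold assignment, solver).
#' @return A list with `B`, `C` and the full `grid` tibble of mean CV MSEs.
#' @export
local_grid_search <- function(dataset, parent_weight, B_grid, C_grid,
                              inner_folds = 3L, epsilon = 0.1, seed = 1L) {
  l <- length(dataset$y)
  stopifnot(l >= 2, inner_folds >= 2)
  if (l < inner_folds) {
    warning(sprintf(
      "node has %d instances; reducing inner folds from %d to %d",
      l, inner_folds, l))
    inner_folds <- l
  }
  folds <- .stratified_folds(dataset$task, inner_folds, seed)
  grid <- tidyr::expand_grid(B = sort(unique(B_grid)),
                             C = sort(unique(C_grid)))
  cv_mse <- purrr::pmap_dbl(grid, function(B, C) {
    errs <- vapply(seq_len(inner_folds), function(k) {
      tr <- dataset[folds != k]
      va <- dataset[folds == k]
      if (!length(va$y) || !length(tr$y)) return(NA_real_)
      fit <- train_node(tr, parent_weight, B = B, C = C, epsilon = epsilon,
                        options = solver_options(seed = seed))
      mse(va$y, .linear_predict(fit$w, fit$offset, va$X))
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  })
  best <- which(cv_mse <= min(cv_mse) + 1e-12)[1]  # grid sorted: small B, C
  list(B = grid$B[best], C = grid$C[best],
       grid = dplyr::mutate(grid, cv_mse = cv_mse))
}

# fold ids balanced within each task where possible
.stratified_folds <- function(task, k, seed) {
  .with_seed(seed, {
    folds <- integer(length(task))
    for (t in unique(task)) {
      idx <- which(task == t)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    folds
  })
}

#' Train a top-down multi-task SVR over a task taxonomy
#'
#' Trains one model per taxonomy node in breadth-first, top-down order. The
#' root is fit on all instances (its pull strength is unused); every other
#' node is fit on the instances of its subtree while being pulled towards
#' its parent's fixed optimal weight with strength B. In `"tax"` mode B is
#' the scaled weight of the edge to the parent and only C is searched per
#' node; in `"gs"` mode (B, C) are chosen jointly per node by
#' [local_grid_search()]. Leaf models are the task models.
#'
#' A node with no training instances (possible under leave-one-sequence-out)
#' inherits its parent's model; predictions for such an unseen task are the
#' parent's predictions.
#'
#' @param taxonomy a `phylo` taxonomy whose leaf labels are the dataset's
#'   task labels (see [parse_newick()], [star_taxonomy()]).
#' @param dataset an [mt_dataset()]; every task must appear as a leaf.
#' @param config a [tdmt_config()].
#' @param options solver options; the config seed is used when omitted.
#' @return An object of class `tdmt_model`: a list with per-node models
#'   (`nodes`), the `taxonomy`, `config` and the leaf->node map.
#' @export
train_tdmt <- function(taxonomy, dataset, config = tdmt_config(),
                       options = NULL) {
  stopifnot(inherits(dataset, "mt_dataset"))
  validate_taxonomy(taxonomy)
  if (is.null(options)) options <- solver_options(seed = config$seed)
  taxonomy <- scale_weights(taxonomy)
  info <- .taxonomy_nodes(taxonomy)
  leaf_task <- match(taxonomy$tip.label, dataset$task_labels)
  present <- dataset$task_labels[sort(unique(dataset$task))]
  if (!all(present %in% taxonomy$tip.label))
    stop("every task with data must appear as a taxonomy leaf")
  n_feat <- ncol(dataset$X)
  nodes <- vector("list", length(info$parent))
  for (v in info$order) {
    tasks_v <- leaf_task[info$tips_under[[v]]]
    idx <- which(dataset$task %in% tasks_v)
    is_root <- v == info$root
    parent_model <- if (is_root) NULL else nodes[[info$parent[v]]]
    wp <- if (is_root) numeric(n_feat) else parent_model$w
    if (!length(idx)) {
      # empty subtree: inherit the parent model (B irrelevant)
      nodes[[v]] <- list(w = wp, offset = parent_model$offset,
                         B = NA_real_, C = NA_real_,
                         epsilon = config$epsilon, inherited = TRUE,
                         converged = TRUE)
      next
    }
    sub <- dataset[idx]
    is_leaf <- v <= info$n_tips
    if (is_root) {
      B_grid <- 0
    } else if (config$mode == "tax") {
      B_grid <- info$weight[v]
      if (is_leaf && config$prevent_negative_transfer)
        B_grid <- unique(c(0, B_grid))
    } else {
      B_grid <- config$B_grid
      if (is_leaf && config$prevent_negative_transfer)
        B_grid <- unique(c(0, B_grid))
    }
    sel <- local_grid_search(sub, wp, B_grid = B_grid,
                             C_grid = config$C_grid,
                             inner_folds = config$inner_folds,
                             epsilon = config$epsilon,
                             seed = config$seed + v)
    fit <- train_node(sub, wp, B = sel$B, C = sel$C,
                      epsilon = config$epsilon, options = options)
    fit$inherited <- FALSE
    fit$n_instances <- length(idx)
    nodes[[v]] <- fit
  }
  structure(
    list(nodes = nodes, taxonomy = taxonomy, config = config,
         info = info, leaf_task = leaf_task,
         task_labels = dataset$task_labels),
    class = "tdmt_model")
}

#' @export
print.tdmt_model <- function(x, ...) {
  cat(sprintf(
    "<tdmt_model> mode = %s, %d tasks, %d nodes\n",
    x$config$mode, x$info$n_tips, length(x$nodes)))
  invisible(x)
}

#' Predict from a top-down multi-task model
#'
#' Uses the leaf model of the requested task: \eqn{\hat y = w_{leaf}^T x +
#' \mathrm{offset}_{leaf}} (the leaf weight is the full model, consistent
#' with the node training loss). For a task whose leaf had no training
#' instances the parent model is used. `rule = "literal_sum"` instead adds
#' the parent weight to the leaf weight at prediction time — a compatibility
#' convention kept for comparison only, inconsistent with independent
#' (`B = 0`) leaves.
#'
#' @param object a `tdmt_model`.
#' @param newdata instances in rows (or an [mt_dataset()]).
#' @param task task id (into the training task labels) or leaf label;
#'   vectorized per instance if of matching length.
#' @param rule prediction convention (see above).
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.tdmt_model <- function(object, newdata, task,
                               rule = c("primal", "literal_sum"), ...) {
  rule <- match.arg(rule)
  if (inherits(newdata, "mt_dataset") && missing(task)) task <- newdata$task
  X <- if (inherits(newdata, "mt_dataset")) newdata$X else newdata
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (length(task) == 1) task <- rep(task, nrow(X))
  stopifnot(length(task) == nrow(X))
  out <- numeric(nrow(X))
  for (t in unique(task)) {
    leaf <- .match_leaf(object, t)
    mdl <- object$nodes[[leaf]]
    w <- mdl$w
    if (rule == "literal_sum" && !isTRUE(mdl$inherited)) {
      par <- object$info$parent[leaf]
      if (!is.na(par)) w <- w + object$nodes[[par]]$w
    }
    idx <- which(task == t)
    out[idx] <- .linear_predict(w, mdl$offset, X[idx, , drop = FALSE])
  }
  out
}

.match_leaf <- function(object, task) {
  if (is.character(task)) {
    leaf <- match(task, object$taxonomy$tip.label)
  } else {
    leaf <- match(as.integer(task), object$leaf_task)
  }
  if (is.na(leaf)) stop("unknown task: ", task)
  leaf
}

#' Per-node summary of a top-down model
#' @param model a `tdmt_model`.
#' @return A tibble with one row per taxonomy node: node id, label, parent,
#'   selected B and C, number of instances, whether inherited.
#' @export
tdmt_nodes <- function(model) {
  info <- model$info
  labels <- c(model$taxonomy$tip.label,
              paste0("node", seq_len(model$taxonomy$Nnode)))
  tibble::tibble(
    node = seq_along(model$nodes),
    label = labels[seq_along(model$nodes)],
    parent = info$parent[seq_along(model$nodes)],
    is_leaf = seq_along(model$nodes) <= info$n_tips,
    B = purrr::map_dbl(model$nodes, ~ .x$B %||% NA_real_),
    C = purrr::map_dbl(model$nodes, ~ .x$C %||% NA_real_),
    inherited = purrr::map_lgl(model$nodes, ~ isTRUE(.x$inherited))
  )
}

# node primal objective (Eq-15 form) for oracle/property checks
node_primal_objective <- function(w, dataset, parent_weight, B, C, epsilon,
                                  offset = mean(dataset$y)) {
  xi <- as.numeric(dataset$X %*% w)
  (1 - B) / 2 * sum(w^2) + B / 2 * sum((w - parent_weight)^2) +
    C * sum(eps_insensitive_loss(xi, dataset$y - offset, epsilon, 2))
}
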