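#' Multi-task regression dataset
#'
#' Container for a multi-target QSAR-style dataset: a set of triples
#' \eqn{(x_i, y_i, t_i)} where \eqn{x_i} is a (sparse, non-negative) feature
#' vector such as a hashed circular fingerprint, \eqn{y_i} a real-valued label
#' (typically a pIC50) and \eqn{t_i} the task (protein target) the instance
#' belongs to.
#'
#' @param X numeric matrix or [Matrix::sparseMatrix()] with one instance per
#'   row and one feature per column.
#' @param y numeric vector of labels, one per instance.
#' @param task task membership: integer codes in `1..T`, or a factor/character
#'   vector of task labels. May be omitted for single-task data (all
#'   instances are assigned task 1).
#' @param task_labels optional character vector naming tasks `1..T`; defaults
#'   to the factor levels of `task` or `"task<k>"`.
#' @param instance_id optional identifiers, one per instance.
#'
#' @return An object of class `mt_dataset` with elements `X` (a
#'   `dgCMatrix`, instances in rows), `y`, `task` (integer), `task_labels`
#'   and `instance_id`.
#' @seealso [read_mt_dataset()], [normalize_features()], [simulate_mt_tasks()]
#' @export
mt_dataset <- function(X, y, task = NULL, task_labels = NULL,
                       instance_id = NULL) {
  X <- methods::as(methods::as(methods::as(Matrix::Matrix(X, sparse = TRUE),
                                           "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  l <- nrow(X)
  stopifnot(length(y) == l, is.numeric(y))
  if (any(!is.finite(y))) stop("labels must be finite")
  if (length(X@x) && any(!is.finite(X@x))) stop("feature values must be finite")
  if (is.null(task)) task <- rep(1L, l)
  stopifnot(length(task) == l)
  if (is.character(task)) task <- factor(task, levels = unique(task))
  if (is.factor(task)) {
    if (is.null(task_labels)) task_labels <- levels(task)
    task <- as.integer(task)
  } else {
    task <- as.integer(task)
    if (any(task < 1L)) stop("task ids must be >= 1")
  }
  n_tasks <- max(task)
  if (is.null(task_labels)) task_labels <- paste0("task", seq_len(n_tasks))
  if (length(task_labels) < n_tasks)
    stop("fewer task labels than task ids")
  if (is.null(instance_id)) instance_id <- seq_len(l)
  structure(
    list(X = X, y = as.numeric(y), task = task,
         task_labels = as.character(task_labels),
         instance_id = instance_id),
    class = "mt_dataset"
  )
}

#' @export
print.mt_dataset <- function(x, ...) {
  cat(sprintf(
    "<mt_dataset> %d instances, %d features, %d task(s)\n",
    nrow(x$X), ncol(x$X), n_tasks(x)))
  tab <- table(factor(x$task, levels = seq_len(n_tasks(x)),
                      labels = x$task_labels))
  cat("  instances per task: ",
      paste(names(tab), unname(tab), sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Number of tasks / instances in a dataset
#' @param dataset an [mt_dataset()].
#' @return Integer scalar.
#' @export
n_tasks <- function(dataset) length(dataset$task_labels)

#' @export
length.mt_dataset <- function(x) nrow(x$X)

#' Subset instances of a multi-task dataset
#' @param x an [mt_dataset()].
#' @param i integer or logical index over instances.
#' @param ... unused.
#' @return An `mt_dataset` with the selected instances (task universe kept).
#' @export
`[.mt_dataset` <- function(x, i, ...) {
  mt_dataset(x$X[i, , drop = FALSE], x$y[i], x$task[i],
             task_labels = x$task_labels, instance_id = x$instance_id[i])
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.mt_dataset <- function(x, ...) {
  Xt <- Matrix::t(x$X)
  feats <- purrr::map(seq_len(nrow(x$X)), function(i) {
    col <- Xt[, i]
    nz <- which(col != 0)
    stats::setNames(as.numeric(col[nz]), nz - 1L)
  })
  tibble::tibble(
    instance_id = x$instance_id,
    task = x$task_labels[x$task],
    label = x$y,
    features = feats
  )
}

#' Normalize feature vectors to unit Euclidean norm
#'
#' Dividing every instance by its Euclidean norm makes the linear (dot
#' product) kernel equal to the cosine kernel, whose values for non-negative
#' fingerprints lie in \[0, 1\] and are independent of compound size.
#'
#' @param x an [mt_dataset()], a numeric matrix/sparseMatrix with instances in
#'   rows, or a single numeric vector.
#' @return The same type of object with every instance scaled to norm 1.
#'   Instances with all-zero features are an error (the cosine is undefined).
#' @examples
#' normalize_features(c(3, 4))
#' @export
normalize_features <- function(x) {
  if (inherits(x, "mt_dataset")) {
    x$X <- .normalize_rows(x$X)
    return(x)
  }
  if (is.null(dim(x))) {
    nrm <- sqrt(sum(x^2))
    if (nrm == 0) stop("cannot normalize an all-zero feature vector")
    return(x / nrm)
  }
  .normalize_rows(x)
}

.normalize_rows <- function(X) {
  nrm <- sqrt(Matrix::rowSums(X^2))
  if (any(nrm == 0)) stop("cannot normalize an all-zero feature vector")
  if (is.matrix(X)) return(X / nrm)
  methods::as(Matrix::Diagonal(x = 1 / nrm) %*% X, "CsparseMatrix")
}

# features x instances dgCMatrix for the coordinate-descent solver
.solver_matrix <- function(X) {
  methods::as(methods::as(methods::as(Matrix::t(X), "dMatrix"),
                          "generalMatrix"), "CsparseMatrix")
}

#' Read / write the delimited sparse multi-task dataset format
#'
#' A plain-text tab-separated format with columns `instance_id`, `task_id`,
#' `label` and `features`, where `features` is a space-separated list of
#' 0-based `index:value` pairs.
#'
#' @param path file path.
#' @param n_features optional total feature-space dimension; defaults to the
#'   largest index seen plus one.
#' @return `read_mt_dataset()` returns an [mt_dataset()]; `write_mt_dataset()`
#'   returns `path` invisibly.
#' @export
read_mt_dataset <- function(path, n_features = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "numeric", "character"),
                          quote = "", comment.char = "")
  stopifnot(all(c("instance_id", "task_id", "label", "features") %in%
                  names(df)))
  parsed <- strsplit(trimws(df$features), " +")
  idx <- purrr::map(parsed, function(p) {
    p <- p[nzchar(p)]
    if (!length(p)) return(integer())
    as.integer(sub(":.*$", "", p))
  })
  val <- purrr::map(parsed, function(p) {
    p <- p[nzchar(p)]
    if (!length(p)) return(numeric())
    as.numeric(sub("^[^:]*:", "", p))
  })
  if (is.null(n_features)) {
    mx <- suppressWarnings(max(unlist(idx), -1L))
    n_features <- mx + 1L
  }
  l <- nrow(df)
  X <- Matrix::sparseMatrix(
    i = rep.int(seq_len(l), lengths(idx)),
    j = unlist(idx) + 1L,
    x = unlist(val),
    dims = c(l, n_features)
  )
  mt_dataset(X, df$label, task = df$task_id, instance_id = df$instance_id)
}

#' @param dataset an [mt_dataset()].
#' @rdname read_mt_dataset
#' @export
write_mt_dataset <- function(dataset, path) {
  Xt <- .solver_matrix(dataset$X)
  p <- Xt@p
  feats <- vapply(seq_len(ncol(Xt)), function(i) {
    k <- if (p[i + 1L] > p[i]) seq.int(p[i] + 1L, p[i + 1L]) else integer()
    paste(sprintf("%d:%s", Xt@i[k], format(Xt@x[k], digits = 17)),
          collapse = " ")
  }, character(1))
  df <- data.frame(
    instance_id = dataset$instance_id,
    task_id = dataset$task_labels[dataset$task],
    label = format(dataset$y, digits = 17),
    features = feats
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a square task-similarity matrix
#'
#' Tab-separated square matrix with a header row (and first column) of task
#' labels. Decimal values round-trip exactly.
#'
#' @param path file path.
#' @return `read_similarity_matrix()` returns a named symmetric numeric
#'   matrix.
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  A <- as.matrix(df)
  storage.mode(A) <- "double"
  A
}

#' @param A symmetric numeric matrix with dimnames.
#' @rdname read_similarity_matrix
#' @export
write_similarity_matrix <- function(A, path) {
  df <- as.data.frame(apply(A, 2, format, digits = 17), optional = TRUE)
  rownames(df) <- rownames(A)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

# pooled dataset: single task view of a multi-task dataset
.pool_tasks <- function(dataset) {
  mt_dataset(dataset$X, dataset$y, rep(1L, length(dataset$y)),
             task_labels = "pooled", instance_id = dataset$instance_id)
}
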