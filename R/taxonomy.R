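#' Parse and write task taxonomies in Newick format
#'
#' A task taxonomy is a rooted tree whose leaves are learning tasks (protein
#' targets) and whose edge weights encode relatedness — e.g. the human kinome
#' tree with evolutionary branch lengths, or a star tree whose edge weights
#' are task-model similarities. Parsing is delegated to \pkg{ape}; the result
#' is an ape `phylo` object validated for taxonomy use (single root, unique
#' leaf labels, non-negative edge weights).
#'
#' In strict mode (default) a missing branch length is an error; with
#' `lenient = TRUE` missing lengths default to 1.0 (the convention used to
#' attach atypical kinases to the kinome tree root).
#'
#' @param text a Newick string, or the path of a file containing one.
#' @param lenient logical; fill missing branch lengths with 1.0 instead of
#'   failing.
#' @return `parse_newick()` returns a `phylo` object; `write_newick()`
#'   returns the Newick string (and writes it to `path` if given).
#' @examples
#' phy <- parse_newick("((A:0.1,B:0.1):0.2,C:0.5);")
#' pairwise_distances(phy)
#' @export
parse_newick <- function(text, lenient = FALSE) {
  is_file <- length(text) == 1 && !grepl("[(;]", text) && file.exists(text)
  if (is_file) text <- paste(readLines(text, warn = FALSE), collapse = "")
  text <- trimws(text)
  .newick_scan(text)
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w))
  )
  if (is.null(phy)) stop("Newick parse error: no tree found")
  if (is.null(phy$edge.length)) {
    if (!lenient)
      stop("taxonomy has no branch lengths (use lenient = TRUE to default ",
           "them to 1.0)")
    phy$edge.length <- rep(1.0, nrow(phy$edge))
  }
  if (anyNA(phy$edge.length)) {
    if (!lenient)
      stop("missing branch length at edge ",
           paste(which(is.na(phy$edge.length)), collapse = ", "),
           " (use lenient = TRUE to default to 1.0)")
    phy$edge.length[is.na(phy$edge.length)] <- 1.0
  }
  validate_taxonomy(phy)
}

# cheap structural scan so malformed input reports a character position
.newick_scan <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse error at position %d: unmatched ')'", k))
    }
  }
  if (depth != 0L)
    stop(sprintf(
      "Newick parse error at position %d: %d unclosed '('",
      length(chars), depth))
  if (!grepl(";\\s*$", text))
    stop(sprintf(
      "Newick parse error at position %d: missing terminal ';'",
      length(chars)))
  invisible(text)
}

#' @param taxonomy a `phylo` taxonomy.
#' @param path optional output file.
#' @param digits significant digits for branch lengths.
#' @rdname parse_newick
#' @export
write_newick <- function(taxonomy, path = NULL, digits = 10) {
  s <- ape::write.tree(taxonomy, digits = digits)
  if (!is.null(path)) writeLines(s, path)
  invisible(s)
}

#' Validate a phylo object as a task taxonomy
#'
#' @param taxonomy a `phylo` object.
#' @return The taxonomy, invisibly usable; errors on duplicate leaf labels or
#'   negative edge weights.
#' @export
validate_taxonomy <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "phylo"))
  if (anyDuplicated(taxonomy$tip.label))
    stop("leaf labels must be unique")
  if (!is.null(taxonomy$edge.length) && any(taxonomy$edge.length < 0))
    stop("edge weights must be non-negative")
  taxonomy
}

#' Scale taxonomy edge weights to \[0, 1\]
#'
#' Divides all edge weights by the maximum weight, so the scaled weights can
#' serve directly as the per-edge pull strengths B of top-down multi-task
#' training. A taxonomy whose weights already lie in \[0, 1\] is returned
#' unchanged.
#'
#' @param taxonomy a `phylo` taxonomy with at least one positive edge weight.
#' @return The taxonomy with `edge.length` in \[0, 1\].
#' @export
scale_weights <- function(taxonomy) {
  validate_taxonomy(taxonomy)
  w <- taxonomy$edge.length
  if (is.null(w) || all(w == 0)) stop("taxonomy has no positive edge weight")
  mx <- max(w)
  if (mx > 1) taxonomy$edge.length <- w / mx
  taxonomy
}

#' Leaf-to-leaf path distances of a taxonomy
#'
#' The distance between two tasks is the total weight of the (unique) path
#' between their leaves — the patristic distance, computed with
#' [ape::cophenetic.phylo()].
#'
#' @param taxonomy a `phylo` taxonomy with edge weights.
#' @return Symmetric `T x T` matrix with zero diagonal, labelled by leaf.
#' @export
pairwise_distances <- function(taxonomy) {
  validate_taxonomy(taxonomy)
  D <- stats::cophenetic(taxonomy)
  D[taxonomy$tip.label, taxonomy$tip.label]
}

#' Convert a distance matrix into a task-similarity matrix
#'
#' Distances are normalized by the maximum off-diagonal entry (so the most
#' distant pair gets similarity exactly 0) and transformed as
#' \eqn{s = 1 - d}. The diagonal is fixed to 1. Optionally, named tasks can
#' be forced to similarity 0 against all others regardless of their
#' distances — used for outlier tasks such as atypical kinases whose
#' tree placement does not reflect a meaningful similarity.
#'
#' @param D symmetric non-negative distance matrix.
#' @param zero_tasks character labels (or integer indices) whose off-diagonal
#'   similarities are overridden to 0.
#' @return Symmetric similarity matrix with entries in \[0, 1\] and unit
#'   diagonal.
#' @export
distances_to_similarity <- function(D, zero_tasks = NULL) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square")
  if (any(D < 0)) stop("distances must be non-negative")
  if (max(abs(D - t(D))) > 1e-9) stop("D must be symmetric")
  off <- D[row(D) != col(D)]
  if (!length(off) || max(off) == 0)
    stop("all distances are zero; similarity is undefined")
  A <- 1 - D / max(off)
  diag(A) <- 1
  A[A < 0] <- 0
  if (!is.null(zero_tasks)) {
    idx <- if (is.character(zero_tasks)) match(zero_tasks, rownames(D))
           else as.integer(zero_tasks)
    if (anyNA(idx)) stop("unknown task in zero_tasks")
    for (t in idx) {
      A[t, -t] <- 0
      A[-t, t] <- 0
    }
  }
  A
}

#' UPGMA taxonomy from a task-correlation matrix
#'
#' Agglomerates tasks by average linkage (UPGMA) on the distance
#' `1 - correlation`, yielding an ultrametric task taxonomy — the
#' construction used to build data-driven taxonomies from Spearman
#' correlations of shared-compound pIC50 profiles.
#'
#' @param corr symmetric correlation matrix with entries in \[-1, 1\].
#' @return An ultrametric `phylo` taxonomy whose leaves are the row names of
#'   `corr`.
#' @export
upgma_from_correlation <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) < 2)
    stop("need a correlation matrix over at least 2 tasks")
  if (any(corr < -1 - 1e-9 | corr > 1 + 1e-9))
    stop("correlations must lie in [-1, 1]")
  if (is.null(rownames(corr)))
    rownames(corr) <- colnames(corr) <- paste0("task", seq_len(nrow(corr)))
  d <- stats::as.dist(1 - corr)
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  validate_taxonomy(phy)
}

#' Star taxonomy with given edge weights
#'
#' A root directly connected to each task; edge weights typically encode the
#' similarity of each task model to the root (mean) model.
#'
#' @param task_labels character vector of leaf labels.
#' @param weights non-negative edge weight per task.
#' @return A `phylo` taxonomy.
#' @export
star_taxonomy <- function(task_labels, weights) {
  Tn <- length(task_labels)
  stopifnot(Tn >= 2, length(weights) == Tn)
  phy <- structure(
    list(edge = cbind(rep(Tn + 1L, Tn), seq_len(Tn)),
         edge.length = as.numeric(weights),
         tip.label = as.character(task_labels),
         Nnode = 1L),
    class = "phylo", order = "cladewise")
  validate_taxonomy(phy)
}

# internal: adjacency list of a phylo taxonomy, root first (breadth-first),
# with the incoming edge weight of every node
.taxonomy_nodes <- function(taxonomy) {
  ntip <- length(taxonomy$tip.label)
  root <- ntip + 1L
  edge <- taxonomy$edge
  wts <- taxonomy$edge.length
  if (is.null(wts)) wts <- rep(1.0, nrow(edge))
  parent_of <- integer(ntip + taxonomy$Nnode)
  weight_of <- numeric(ntip + taxonomy$Nnode)
  parent_of[] <- NA_integer_
  for (k in seq_len(nrow(edge))) {
    parent_of[edge[k, 2]] <- edge[k, 1]
    weight_of[edge[k, 2]] <- wts[k]
  }
  # BFS order from the root
  order <- root
  frontier <- root
  while (length(frontier)) {
    children <- edge[edge[, 1] %in% frontier, 2]
    order <- c(order, children)
    frontier <- children
  }
  # leaves under each node
  tips_under <- vector("list", ntip + taxonomy$Nnode)
  for (v in rev(order)) {
    if (v <= ntip) tips_under[[v]] <- v
    else tips_under[[v]] <- sort(unlist(
      tips_under[edge[edge[, 1] == v, 2]]))
  }
  list(root = root, order = order, parent = parent_of, weight = weight_of,
       tips_under = tips_under, n_tips = ntip)
}
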