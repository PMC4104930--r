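#' Curation rules for activity records
#'
#' Defaults reproduce a standard ChEMBL-style curation cascade for kinase
#' pIC50 data: assay confidence of at least 8, binding ("B") assays only,
#' wild-type targets only, exactly determined values (no "<"/">" relations),
#' IC50-to-pIC50 conversion, an activity floor of pIC50 5.00 (10 uM),
#' rejection of compounds whose repeated measurements on one target span
#' more than 1 log unit (otherwise aggregated by the geometric mean of the
#' pIC50 values), a drug-likeness window (90 < MW <= 900, -7 <= AlogP <= 9,
#' HBA <= 18, HBD <= 18, rotatable bonds <= 18), organic structures only,
#' and finally a per-target minimum of 15 compounds.
#'
#' @param min_confidence minimum assay confidence score.
#' @param assay_types accepted assay type codes.
#' @param wild_type_only drop records on mutant targets.
#' @param exact_only drop records whose value is a "<" or ">" bound.
#' @param min_pic50 activity floor on the pIC50 scale.
#' @param max_log_range maximal spread of repeated pIC50 values before the
#'   (compound, target) pair is rejected.
#' @param mw_range,alogp_range,max_hba,max_hbd,max_rotb physicochemical
#'   window (MW strictly greater than `mw_range[1]`).
#' @param organic_only drop structures with non-organic atoms.
#' @param min_compounds minimal compounds per retained target.
#' @return A list of thresholds for [curate_activities()].
#' @export
curation_rules <- function(min_confidence = 8L, assay_types = "B",
                           wild_type_only = TRUE, exact_only = TRUE,
                           min_pic50 = 5.00, max_log_range = 1.0,
                           mw_range = c(90, 900), alogp_range = c(-7, 9),
                           max_hba = 18, max_hbd = 18, max_rotb = 18,
                           organic_only = TRUE, min_compounds = 15L) {
  as.list(environment())
}

#' Curate raw activity records into a per-target pIC50 dataset
#'
#' Applies the rule cascade of [curation_rules()] in order, logging every
#' exclusion with the rule that caused it. Records are a tibble/data frame
#' with columns `compound_id`, `target_id`, `value`, `value_type`
#' (`"IC50"` in molar units, or `"pIC50"`), and optionally `relation`
#' (`"="`, `"<"`, `">"`), `confidence_score`, `assay_type`,
#' `target_is_mutant`, `mw`, `alogp`, `hba`, `hbd`, `rotb`, `organic`.
#' Missing optional columns skip the corresponding filter.
#'
#' @param records activity records (see above).
#' @param rules a [curation_rules()] list.
#' @return A list of class `curated_dataset`: `data` (tibble `target_id`,
#'   `compound_id`, `pic50`) and `log` (tibble `compound_id`, `target_id`,
#'   `rule` for every exclusion).
#' @export
curate_activities <- function(records, rules = curation_rules()) {
  df <- tibble::as_tibble(records)
  stopifnot(all(c("compound_id", "target_id", "value", "value_type") %in%
                  names(df)))
  if (!all(df$value_type %in% c("IC50", "pIC50")))
    stop("unknown value_type: ",
         paste(setdiff(unique(df$value_type), c("IC50", "pIC50")),
               collapse = ", "))
  log <- tibble::tibble(compound_id = character(), target_id = character(),
                        rule = character())
  drop_rows <- function(df, bad, rule) {
    if (any(bad)) {
      log <<- dplyr::bind_rows(log, tibble::tibble(
        compound_id = as.character(df$compound_id[bad]),
        target_id = as.character(df$target_id[bad]), rule = rule))
    }
    df[!bad, , drop = FALSE]
  }
  if (!is.null(df$confidence_score))
    df <- drop_rows(df, df$confidence_score < rules$min_confidence,
                    "confidence")
  if (!is.null(df$assay_type))
    df <- drop_rows(df, !(df$assay_type %in% rules$assay_types),
                    "assay_type")
  if (rules$wild_type_only && !is.null(df$target_is_mutant))
    df <- drop_rows(df, isTRUE(rules$wild_type_only) & df$target_is_mutant,
                    "mutant_target")
  if (rules$exact_only && !is.null(df$relation))
    df <- drop_rows(df, !(df$relation %in% c("=", "exact")), "relation")
  # unit conversion: IC50 in molar -> pIC50
  df$pic50 <- ifelse(df$value_type == "IC50", -log10(df$value), df$value)
  df <- drop_rows(df, df$pic50 < rules$min_pic50, "activity_floor")
  # per-(compound, target) multi-value resolution
  df <- df |>
    dplyr::group_by(.data$compound_id, .data$target_id) |>
    dplyr::mutate(.range = max(.data$pic50) - min(.data$pic50)) |>
    dplyr::ungroup()
  df <- drop_rows(df, df$.range > rules$max_log_range, "discordant_values")
  agg <- df |>
    dplyr::group_by(.data$compound_id, .data$target_id) |>
    dplyr::summarise(
      pic50 = exp(mean(log(.data$pic50))),  # geometric mean of the pIC50s
      dplyr::across(dplyr::any_of(c("mw", "alogp", "hba", "hbd", "rotb",
                                    "organic")), dplyr::first),
      .groups = "drop")
  if (!is.null(agg$mw))
    agg <- drop_rows(agg, !(agg$mw > rules$mw_range[1] &
                              agg$mw <= rules$mw_range[2]), "mw")
  if (!is.null(agg$alogp))
    agg <- drop_rows(agg, !(agg$alogp >= rules$alogp_range[1] &
                              agg$alogp <= rules$alogp_range[2]), "alogp")
  if (!is.null(agg$hba)) agg <- drop_rows(agg, agg$hba > rules$max_hba,
                                          "hba")
  if (!is.null(agg$hbd)) agg <- drop_rows(agg, agg$hbd > rules$max_hbd,
                                          "hbd")
  if (!is.null(agg$rotb)) agg <- drop_rows(agg, agg$rotb > rules$max_rotb,
                                           "rotatable_bonds")
  if (rules$organic_only && !is.null(agg$organic))
    agg <- drop_rows(agg, !agg$organic, "non_organic")
  # per-target minimum runs last
  sizes <- agg |> dplyr::count(.data$target_id)
  small <- sizes$target_id[sizes$n < rules$min_compounds]
  agg <- drop_rows(agg, agg$target_id %in% small, "target_too_small")
  structure(
    list(data = dplyr::select(agg, "target_id", "compound_id", "pic50"),
         log = log),
    class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat(sprintf(
    "<curated_dataset> %d records over %d target(s); %d exclusions logged\n",
    nrow(x$data), dplyr::n_distinct(x$data$target_id), nrow(x$log)))
  invisible(x)
}

#' Fold raw fingerprint feature ids into a fixed-size hash space
#'
#' Hashed circular fingerprints are generated in a large id space (up to
#' 2^32); folding maps each id to `id mod 2^bits`. Bins accumulate and are
#' then binarized (presence semantics). The collision fraction — the share
#' of distinct raw ids lost to shared bins — is reported, since excessive
#' folding degrades the fingerprint.
#'
#' @param raw_feature_ids non-negative feature ids (numeric to allow values
#'   beyond 2^31).
#' @param bits target hash-space size `2^bits` (bits <= 32).
#' @return A list with `indices` (sorted unique 0-based folded bins),
#'   `counts` (raw ids per bin) and `collision_fraction`.
#' @export
fold_fingerprint <- function(raw_feature_ids, bits = 20) {
  stopifnot(bits >= 1, bits <= 32, all(raw_feature_ids >= 0))
  ids <- unique(as.numeric(raw_feature_ids))
  folded <- ids %% 2^bits
  bins <- sort(unique(folded))
  counts <- as.integer(table(factor(folded, levels = bins)))
  list(indices = bins, counts = counts,
       collision_fraction = 1 - length(bins) / length(ids))
}

#' Remove features present in more than a given fraction of compounds
#'
#' Near-ubiquitous fingerprint features carry little information and inflate
#' similarity; features occurring in strictly more than `max_fraction` of
#' the compounds are removed. The kept-feature mapping is returned so the
#' identical reduction can be applied to held-out data.
#'
#' @param X binary/count feature matrix, compounds in rows (matrix or
#'   sparseMatrix), or an [mt_dataset()].
#' @param max_fraction occurrence threshold in (0, 1\].
#' @return A list with `X` (reduced), `kept` (column indices kept) and
#'   `removed`. For an `mt_dataset` input, `X` is an `mt_dataset`.
#' @export
filter_frequent_features <- function(X, max_fraction = 0.9) {
  stopifnot(max_fraction > 0, max_fraction <= 1)
  ds <- NULL
  if (inherits(X, "mt_dataset")) {
    ds <- X
    X <- ds$X
  }
  frac <- Matrix::colMeans(X != 0)
  kept <- which(frac <= max_fraction)
  out <- X[, kept, drop = FALSE]
  if (!is.null(ds)) {
    out <- mt_dataset(out, ds$y, ds$task, task_labels = ds$task_labels,
                      instance_id = ds$instance_id)
  }
  list(X = out, kept = kept, removed = which(frac > max_fraction))
}

#' @param filter result of [filter_frequent_features()].
#' @rdname filter_frequent_features
#' @export
apply_feature_filter <- function(X, filter) {
  if (inherits(X, "mt_dataset")) {
    return(mt_dataset(X$X[, filter$kept, drop = FALSE], X$y, X$task,
                      task_labels = X$task_labels,
                      instance_id = X$instance_id))
  }
  X[, filter$kept, drop = FALSE]
}

#' Tanimoto distance matrix of binary fingerprints
#'
#' \eqn{d(A, B) = 1 - |A \cap B| / |A \cup B|} on the on-bits of each
#' fingerprint. All-zero fingerprints are an error (the Tanimoto similarity
#' is undefined for them).
#'
#' @param fps binary matrix, fingerprints in rows.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
tanimoto_distance_matrix <- function(fps) {
  fps <- as.matrix(fps) != 0
  storage.mode(fps) <- "double"
  on <- rowSums(fps)
  if (any(on == 0)) stop("Tanimoto distance undefined for all-zero fingerprints")
  inter <- tcrossprod(fps)
  uni <- outer(on, on, "+") - inter
  d <- 1 - inter / uni
  diag(d) <- 0
  d
}

#' k-medians clustering on a precomputed distance matrix
#'
#' Lloyd-style alternation of nearest-medoid assignment and medoid updates
#' (each cluster's new medoid minimizes the within-cluster distance sum),
#' restarted `n_restarts` times from seeded random medoid sets; the solution
#' with the lowest total within-cluster distance is kept.
#'
#' @param dist symmetric distance matrix.
#' @param k number of clusters.
#' @param seed integer seed for the restarts.
#' @param n_restarts random restarts.
#' @return A list with `cluster` (labels 1..k), `medoids` (row indices) and
#'   `objective` (total within-cluster distance).
#' @export
kmedians <- function(dist, k, seed = 1L, n_restarts = 10L) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  stopifnot(k >= 1, k <= n)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    med <- .with_seed(.substream(seed, r), sample.int(n, k))
    for (it in 1:100) {
      assign <- apply(dist[, med, drop = FALSE], 1, which.min)
      new_med <- vapply(seq_len(k), function(c) {
        idx <- which(assign == c)
        if (!length(idx)) return(med[c])
        idx[which.min(colSums(dist[idx, idx, drop = FALSE]))]
      }, integer(1))
      if (identical(sort(new_med), sort(med))) break
      med <- new_med
    }
    assign <- apply(dist[, med, drop = FALSE], 1, which.min)
    obj <- sum(dist[cbind(seq_len(n), med[assign])])
    if (is.null(best) || obj < best$objective)
      best <- list(cluster = assign, medoids = med, objective = obj)
  }
  best
}

#' Choose the number of clusters from the within-cluster sum of squares
#'
#' Computes the within-cluster sum of squared distances to the medoid for
#' every `k` in `k_range` and returns the elbow, defined as the `k` with the
#' largest second difference of the curve.
#'
#' @param dist symmetric distance matrix.
#' @param k_range candidate cluster counts (at least 3 consecutive values).
#' @param seed integer seed.
#' @return A list with `k` (chosen), and `wcss` (tibble `k`, `wcss`).
#' @export
choose_k <- function(dist, k_range = 2:10, seed = 1L) {
  k_range <- sort(k_range)
  stopifnot(length(k_range) >= 3)
  dist <- as.matrix(dist)
  wcss <- vapply(k_range, function(k) {
    fit <- kmedians(dist, k, seed = seed)
    sum(dist[cbind(seq_len(nrow(dist)),
                   fit$medoids[fit$cluster])]^2)
  }, numeric(1))
  second_diff <- diff(wcss, differences = 2)
  k <- k_range[which.max(second_diff) + 1L]
  list(k = k, wcss = tibble::tibble(k = k_range, wcss = wcss))
}
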