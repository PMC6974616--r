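#' Tidy a tri-cluster set
#'
#' One row per tri-cluster, with set-valued columns flattened to
#' semicolon-joined strings and the per-dimension sizes made explicit.
#'
#' @param x A `tricluster_set`.
#' @param ... Unused.
#' @return A plain tibble: `cluster_id`, `n_marks`, `n_types`, `support`,
#'   `fold_enrichment`, `marks`, `cancer_types`.
#' @method tidy tricluster_set
#' @export
tidy.tricluster_set <- function(x, ...) {
  tibble(
    cluster_id = x$cluster_id,
    n_marks = lengths(x$marks),
    n_types = lengths(x$cancer_types),
    support = x$support,
    fold_enrichment = x$fold_enrichment,
    marks = join_set(x$marks),
    cancer_types = join_set(x$cancer_types)
  )
}

#' Glance at a tri-cluster set
#'
#' @param x A `tricluster_set`.
#' @param ... Unused.
#' @return One-row tibble: `n_triclusters`, `n_genes_covered` (genes in at
#'   least one cluster), `max_support`, `mean_fold_enrichment`,
#'   `max_n_marks`, `max_n_types`.
#' @method glance tricluster_set
#' @export
glance.tricluster_set <- function(x, ...) {
  tibble(
    n_triclusters = nrow(x),
    n_genes_covered = length(unique(unlist(x$genes))),
    max_support = if (nrow(x) > 0) max(x$support) else NA_integer_,
    mean_fold_enrichment = if (nrow(x) > 0) mean(x$fold_enrichment) else NA_real_,
    max_n_marks = if (nrow(x) > 0) max(lengths(x$marks)) else NA_integer_,
    max_n_types = if (nrow(x) > 0) max(lengths(x$cancer_types)) else NA_integer_
  )
}

#' Tidy a bi-cluster set
#'
#' @param x A `bicluster_set`.
#' @param ... Unused.
#' @return Tibble: `mark`, `mode`, `n_types`, `support`, `cancer_types`.
#' @method tidy bicluster_set
#' @export
tidy.bicluster_set <- function(x, ...) {
  tibble(
    mark = x$mark,
    mode = x$mode,
    n_types = lengths(x$cancer_types),
    support = x$support,
    cancer_types = join_set(x$cancer_types)
  )
}

#' Glance at a recovery scoring
#'
#' @param x A `recovery_scores` tibble from [score_recovery()].
#' @param ... Unused.
#' @return One-row tibble: `n_patterns`, `mean_score`, `min_score`.
#' @method glance recovery_scores
#' @export
glance.recovery_scores <- function(x, ...) {
  tibble(
    n_patterns = nrow(x),
    mean_score = attr(x, "mean_score"),
    min_score = if (nrow(x) > 0) min(x$score) else NA_real_
  )
}
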