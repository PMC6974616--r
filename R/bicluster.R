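#' Form bi-clusters from mined frequent itemsets
#'
#' Converts each frequent cancer-type itemset of one mark into a bi-cluster
#' (gene set, cancer-type set) by inverse gene-set mapping. Two gene rules
#' are available:
#'
#' * `"loose"` — a gene supports the itemset if its transaction contains
#'   every type; this reproduces the literal itemset construction, where a
#'   type enters a gene's transaction as soon as it is coherent with *some*
#'   other type there.
#' * `"clique"` (default) — the gene's coherent-pair set must additionally
#'   contain every pair within the itemset, so all member types are mutually
#'   coherent at that promoter. A bi-cluster whose clique-filtered gene count
#'   falls below the minimum support count is dropped entirely.
#'
#' For 2-type itemsets the two modes coincide. Clique-mode gene sets are
#' always subsets of loose-mode gene sets.
#'
#' @param itemsets Tibble from [mine_frequent_itemsets()] run on
#'   `transactions`.
#' @param transactions The `transaction_db` the itemsets were mined from.
#' @param min_support,min_count Minimum support (fraction of genes, or an
#'   absolute count overriding it) a clique-filtered bi-cluster must retain.
#' @param mode `"clique"` or `"loose"`.
#' @return A `bicluster_set`: tibble with columns `mark`, `mode`, list-column
#'   `cancer_types`, `support` (gene count) and list-column `genes`, ordered
#'   canonically (type-set size, then lexicographic).
#' @export
form_biclusters <- function(itemsets, transactions, min_support = 0.10,
                            min_count = NULL, mode = c("clique", "loose")) {
  mode <- match.arg(mode)
  stopifnot(inherits(transactions, "transaction_db"))
  if (is.null(min_count)) {
    min_count <- min_support_count(min_support, nrow(transactions))
  }
  mark <- attr(transactions, "mark")

  rows <- purrr::map(itemsets$items, function(ts) {
    genes <- cluster_genes(ts, transactions, mode)
    if (length(genes) < min_count) NULL else list(types = sort(ts), genes = genes)
  })
  rows <- purrr::compact(rows)
  out <- tibble(
    mark = rep(mark %||% NA_character_, length(rows)),
    mode = rep(mode, length(rows)),
    cancer_types = purrr::map(rows, "types"),
    support = purrr::map_int(rows, ~ length(.x$genes)),
    genes = purrr::map(rows, "genes")
  )
  key <- purrr::map_chr(out$cancer_types, paste, collapse = "\r")
  out <- out[order(lengths(out$cancer_types), key), ]
  structure(out,
    min_count = min_count,
    class = c("bicluster_set", class(tibble()))
  )
}

# gene rule shared by bi- and tri-cluster mining
cluster_genes <- function(type_set, transactions, mode) {
  if (mode == "loose") {
    return(supporting_genes(type_set, transactions))
  }
  need <- type_set_pairs(type_set)
  keep <- purrr::map_lgl(transactions$pairs, ~ all(need %in% .x))
  transactions$gene_id[keep]
}

#' Bi-cluster counts across coherence thresholds and support levels
#'
#' Re-runs transaction construction and frequent-itemset mining on one
#' profile matrix (or a named list of them, one per mark) for every
#' combination of correlation threshold and minimum support, and counts the
#' resulting bi-clusters. In loose mode the count is non-increasing in the
#' threshold and in the support level, which is the qualitative signature of
#' a threshold-sweep diagnostic.
#'
#' @param profiles A `profile_matrix` or a named list of them.
#' @param corr_thresholds Numeric vector of thresholds in (-1, 1].
#' @param min_support Numeric vector of support fractions in (0, 1].
#' @param mode Gene rule passed to [form_biclusters()].
#' @param min_profile_sd Passed to [build_transactions()].
#' @return A `sweep_result` tibble: `mark`, `corr_threshold`, `min_support`,
#'   `n_biclusters`.
#' @export
threshold_sweep <- function(profiles,
                            corr_thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9),
                            min_support = 0.10,
                            mode = c("loose", "clique"),
                            min_profile_sd = 0) {
  mode <- match.arg(mode)
  if (inherits(profiles, "profile_matrix")) {
    profiles <- stats::setNames(list(profiles), attr(profiles, "mark"))
  }
  grid <- tidyr::expand_grid(
    mark = names(profiles),
    corr_threshold = corr_thresholds,
    min_support = min_support
  )
  grid$n_biclusters <- purrr::pmap_int(grid, function(mark, corr_threshold,
                                                      min_support) {
    txn <- build_transactions(profiles[[mark]], corr_threshold = corr_threshold,
                              min_profile_sd = min_profile_sd)
    fis <- mine_frequent_itemsets(txn, min_support = min_support)
    nrow(form_biclusters(fis, txn, min_support = min_support, mode = mode))
  })
  structure(grid, mode = mode,
            class = c("sweep_result", class(tibble())))
}
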