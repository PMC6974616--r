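#' Genes supporting a cancer-type set under one mark
#'
#' Shared gene kernel of bi- and tri-cluster mining: the genes of `mark`
#' whose transaction (loose mode) or coherent-pair set (clique mode) covers
#' `type_set`. Pure in its inputs and memoizable; the result is anti-monotone
#' in the type set (growing the set can only shrink the gene set).
#'
#' @param type_set Character vector of >= 2 cancer types.
#' @param mark Mark identifier; must name an element of `transactions`.
#' @param transactions Named list of `transaction_db` objects, one per mark.
#' @param mode `"clique"` or `"loose"` (see [form_biclusters()]).
#' @param cache Optional environment used to memoize results across calls.
#' @return Character vector of gene ids in transaction order.
#' @export
genes_for <- function(type_set, mark, transactions,
                      mode = c("clique", "loose"), cache = NULL) {
  mode <- match.arg(mode)
  if (length(type_set) < 2) abort("`type_set` must contain at least 2 types.")
  if (!mark %in% names(transactions)) {
    abort(sprintf("Unknown mark: %s", mark))
  }
  key <- paste(mark, mode, paste(sort(type_set), collapse = "\r"), sep = "\r\r")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  res <- cluster_genes(sort(type_set), transactions[[mark]], mode)
  if (!is.null(cache)) cache[[key]] <- res
  res
}

#' Mine maximal tri-clusters across epigenetic marks
#'
#' Levelwise enumeration over mark-set size: candidate cancer-type sets are
#' the type sets frequent under every mark involved (by downward closure of
#' frequency this equals the closure of pairwise intersections of per-mark
#' frequent sets), gene sets are the intersections over the marks of the
#' per-mark supporting genes, and a candidate survives if it keeps at least
#' the minimum support count of genes. Because support is anti-monotone in
#' both the type set and the mark set, candidates at level `m + 1` are
#' generated only from survivors at level `m`, which prunes without changing
#' results. After enumeration only maximal tri-clusters are kept (see
#' [filter_maximal()]).
#'
#' @param transactions Named list of `transaction_db` objects, one per mark,
#'   all over the same gene universe.
#' @param min_support,min_count Minimum support as a fraction of genes, or an
#'   absolute count overriding it.
#' @param mode Gene rule, `"clique"` (default) or `"loose"`.
#' @param min_types Minimum cancer types per cluster (>= 2).
#' @param min_marks Minimum marks per cluster (>= 2).
#' @return A `tricluster_set`: tibble with `cluster_id`, list-columns `marks`,
#'   `cancer_types` and `genes`, `support` (= gene count) and
#'   `fold_enrichment` (= support / number of genes investigated), sorted by
#'   descending support. Attributes carry `n_genes`, `min_count` and `mode`.
#' @export
mine_triclusters <- function(transactions, min_support = 0.10,
                             min_count = NULL, mode = c("clique", "loose"),
                             min_types = 2L, min_marks = 2L) {
  mode <- match.arg(mode)
  if (length(transactions) < 2) abort("Need transactions for at least 2 marks.")
  if (is.null(names(transactions)) || any(!nzchar(names(transactions)))) {
    abort("`transactions` must be a named list (one element per mark).")
  }
  gene_sets <- purrr::map(transactions, "gene_id")
  if (!all(purrr::map_lgl(gene_sets, ~ setequal(.x, gene_sets[[1]])))) {
    abort("All marks must share the same gene universe.")
  }
  n_genes <- length(gene_sets[[1]])
  if (is.null(min_count)) min_count <- min_support_count(min_support, n_genes)
  marks <- sort(names(transactions))
  cache <- new.env(parent = emptyenv())

  # per-mark frequent type sets, keyed canonically
  freq <- purrr::map(transactions[marks], function(txn) {
    fis <- mine_frequent_itemsets(txn, min_count = min_count,
                                  min_size = min_types)
    stats::setNames(fis$items, purrr::map_chr(fis$items, paste, collapse = "\r"))
  })

  survivors <- list()   # key "m1,m2|types" -> list(marks, types, genes)
  results <- list()
  level <- list()
  if (length(marks) >= 2) {
    pairs <- combn(marks, 2, simplify = FALSE)
    for (mp in pairs) {
      shared <- intersect(names(freq[[mp[1]]]), names(freq[[mp[2]]]))
      for (tk in shared) {
        ts <- freq[[mp[1]]][[tk]]
        g <- intersect(
          genes_for(ts, mp[1], transactions, mode, cache),
          genes_for(ts, mp[2], transactions, mode, cache)
        )
        if (length(g) >= min_count) {
          level[[paste(paste(mp, collapse = "\r"), tk, sep = "\r\r")]] <-
            list(marks = mp, types = ts, genes = g)
        }
      }
    }
  }
  while (length(level) > 0) {
    results <- c(results, purrr::keep(level, ~ length(.x$marks) >= min_marks))
    nxt <- list()
    for (cand in level) {
      last <- cand$marks[length(cand$marks)]
      tk <- paste(cand$types, collapse = "\r")
      for (e in marks[marks > last]) {
        if (!tk %in% names(freq[[e]])) next
        g <- intersect(cand$genes, genes_for(cand$types, e, transactions,
                                             mode, cache))
        if (length(g) >= min_count) {
          ms <- c(cand$marks, e)
          nxt[[paste(paste(ms, collapse = "\r"), tk, sep = "\r\r")]] <-
            list(marks = ms, types = cand$types, genes = g)
        }
      }
    }
    level <- nxt
  }

  cand_tbl <- tibble(
    marks = unname(purrr::map(results, "marks")),
    cancer_types = unname(purrr::map(results, "types")),
    genes = unname(purrr::map(results, "genes"))
  )
  out <- filter_maximal(cand_tbl)
  out$support <- lengths(out$genes)
  out$fold_enrichment <- out$support / n_genes
  key <- paste(
    purrr::map_chr(out$marks, paste, collapse = "\r"),
    purrr::map_chr(out$cancer_types, paste, collapse = "\r")
  )
  out <- out[order(-out$support, key), ]
  out <- tibble(
    cluster_id = sprintf("TC%03d", seq_len(nrow(out))),
    marks = out$marks, cancer_types = out$cancer_types,
    support = as.integer(out$support), fold_enrichment = out$fold_enrichment,
    genes = out$genes
  )
  structure(out,
    n_genes = n_genes, min_count = min_count, mode = mode,
    class = c("tricluster_set", class(tibble()))
  )
}

#' Keep only maximal tri-cluster candidates
#'
#' A candidate `(T, E)` is discarded when another candidate `(T', E')`
#' satisfies `T` \eqn{\subseteq} `T'`, `E` \eqn{\subseteq} `E'` and
#' `(T, E) != (T', E')`. Gene sets are induced by `(T, E)`, so the kept
#' candidate's gene set is automatically a subset of the discarded one's.
#'
#' @param candidates Tibble with list-columns `marks` and `cancer_types`
#'   (additional columns pass through).
#' @return The maximal rows, in input order.
#' @export
filter_maximal <- function(candidates) {
  n <- nrow(candidates)
  if (n <= 1) return(candidates)
  ts <- candidates$cancer_types
  ms <- candidates$marks
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(ts[[i]] %in% ts[[j]]) && all(ms[[i]] %in% ms[[j]]) &&
          !(setequal(ts[[i]], ts[[j]]) && setequal(ms[[i]], ms[[j]]))) {
        keep[i] <- FALSE
        break
      }
    }
  }
  candidates[keep, ]
}

#' One-call tri-cluster mining from profile matrices
#'
#' Convenience wrapper running coherence-transaction construction for every
#' mark followed by [mine_triclusters()].
#'
#' @param profiles Named list of `profile_matrix` objects, one per mark (a
#'   `synthetic_stack` from [simulate_profiles()] is also accepted).
#' @inheritParams build_transactions
#' @inheritParams mine_triclusters
#' @return A `tricluster_set`.
#' @export
#' @examples
#' stack <- simulate_profiles(
#'   n_genes = 60, n_types = 4, n_marks = 3, profile_length = 20,
#'   patterns = list(planted_pattern(1:20, 1:3, 1:2)), seed = 7
#' )
#' tc <- mine_epitriclusters(stack)
#' tidy(tc)
mine_epitriclusters <- function(profiles, corr_threshold = 0.7,
                                min_support = 0.10, min_profile_sd = 0,
                                mode = c("clique", "loose"),
                                min_types = 2L, min_marks = 2L) {
  mode <- match.arg(mode)
  if (inherits(profiles, "synthetic_stack")) profiles <- profiles$profiles
  txn <- purrr::map(profiles, build_transactions,
                    corr_threshold = corr_threshold,
                    min_profile_sd = min_profile_sd)
  mine_triclusters(txn, min_support = min_support, mode = mode,
                   min_types = min_types, min_marks = min_marks)
}

#' @export
print.tricluster_set <- function(x, ...) {
  cat(sprintf(
    "<tricluster_set> %d maximal tri-cluster(s) over %d genes (min support %d, %s mode)\n",
    nrow(x), attr(x, "n_genes") %||% NA_integer_,
    attr(x, "min_count") %||% NA_integer_, attr(x, "mode") %||% "?"
  ))
  NextMethod()
}
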