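#' Build an FP-tree from a transaction database
#'
#' Compresses a transaction database into a frequent-pattern tree: items with
#' global support below the minimum count are discarded, each transaction's
#' surviving items are inserted along a root path in canonical item order
#' (descending global frequency, ties broken lexicographically), shared
#' prefixes are merged and their node counts incremented, and a header table
#' chains all nodes of each item.
#'
#' @param transactions A `transaction_db` from [build_transactions()], or a
#'   plain list of character vectors (one itemset per transaction).
#' @param min_support Minimum support as a fraction of transactions.
#' @param min_count Minimum support as an absolute transaction count;
#'   overrides `min_support` when given.
#' @return An `fptree` object (an environment) with fields `item`, `count`,
#'   `parent` (parallel node vectors; node 1 is the root with `NA` item),
#'   `children` (per-node named integer vectors), `header` (item -> node id
#'   chain) and `header_count` (item -> total support). An all-infrequent
#'   database yields a tree with only the root.
#' @seealso [mine_frequent_itemsets()]
#' @export
#' @examples
#' tr <- list(c("A", "B"), c("A", "B"), "A")
#' tree <- build_fptree(tr, min_count = 1)
#' fptree_header(tree)
build_fptree <- function(transactions, min_support = 0.10, min_count = NULL) {
  tx <- as_transaction_list(transactions)
  if (length(tx) == 0) abort("Transaction database is empty.")
  if (is.null(min_count)) min_count <- min_support_count(min_support, length(tx))
  fp_build(tx, rep(1, length(tx)), min_count)
}

# weighted FP-tree construction (weights carry conditional-pattern-base counts)
fp_build <- function(tx, weights, min_count) {
  t <- new.env(parent = emptyenv())
  t$item <- NA_character_
  t$count <- 0
  t$parent <- 0L
  t$children <- list(integer(0))
  t$header <- list()
  t$min_count <- min_count

  all_items <- unlist(tx, use.names = FALSE)
  if (length(all_items) == 0) {
    t$header_count <- numeric(0)
    t$item_order <- character(0)
    class(t) <- "fptree"
    return(t)
  }
  cnt <- tapply(rep(weights, lengths(tx)), all_items, sum)
  cnt <- cnt[cnt >= min_count]
  ord <- order(-cnt, names(cnt))
  ranked <- names(cnt)[ord]
  rank <- stats::setNames(seq_along(ranked), ranked)
  t$header_count <- stats::setNames(as.numeric(cnt[ranked]), ranked)
  t$item_order <- ranked

  for (i in seq_along(tx)) {
    its <- tx[[i]][tx[[i]] %in% ranked]
    if (length(its) == 0) next
    its <- its[order(rank[its])]
    w <- weights[i]
    cur <- 1L
    for (it in its) {
      nxt <- t$children[[cur]][it]
      if (is.na(nxt)) {
        id <- length(t$item) + 1L
        t$item[id] <- it
        t$count[id] <- 0
        t$parent[id] <- cur
        t$children[[id]] <- integer(0)
        ch <- t$children[[cur]]
        ch[[it]] <- id
        t$children[[cur]] <- ch
        t$header[[it]] <- c(t$header[[it]], id)
        cur <- id
      } else {
        cur <- unname(nxt)
      }
      t$count[cur] <- t$count[cur] + w
    }
  }
  class(t) <- "fptree"
  t
}

#' Header table of an FP-tree
#'
#' @param tree An `fptree`.
#' @return Tibble with one row per surviving item: `item`, `count` (total
#'   support), `n_nodes` (length of the node chain) and `chain_count` (sum of
#'   counts over the chain; equals `count` by construction).
#' @export
fptree_header <- function(tree) {
  stopifnot(inherits(tree, "fptree"))
  items <- tree$item_order
  tibble(
    item = items,
    count = unname(tree$header_count[items]),
    n_nodes = purrr::map_int(items, ~ length(tree$header[[.x]])),
    chain_count = purrr::map_dbl(items, ~ sum(tree$count[tree$header[[.x]]]))
  )
}

#' @export
print.fptree <- function(x, ...) {
  cat(sprintf("<fptree> %d item(s), %d node(s), min_count=%s\n",
              length(x$item_order), length(x$item) - 1L, format(x$min_count)))
  invisible(x)
}

#' Mine all frequent cancer-type itemsets with FP-growth
#'
#' Recursively mines an FP-tree by conditional-pattern-base projection: for
#' each item (ascending global frequency) the prefix paths co-occurring with
#' it form a weighted conditional database, a conditional FP-tree is built,
#' and mining recurses with the item appended to the suffix. Single-path
#' conditional trees are short-circuited by enumerating all subsets of the
#' path, as in the original algorithm. Returns exactly the itemsets of size
#' `>= min_size` whose support reaches the minimum count, each with its exact
#' support.
#'
#' @inheritParams build_fptree
#' @param min_size Minimum itemset size (default 2: a pattern over a single
#'   cancer type says nothing about cross-cancer similarity).
#' @return Tibble with list-column `items` (sorted character vectors),
#'   `support` (transaction count) and `support_frac`, in canonical order
#'   (size, then lexicographic).
#' @export
#' @examples
#' db <- list(c("A", "B", "C"), c("A", "B"), c("A", "C"), c("B", "C"))
#' mine_frequent_itemsets(db, min_count = 2)
mine_frequent_itemsets <- function(transactions, min_support = 0.10,
                                   min_count = NULL, min_size = 2L) {
  tx <- as_transaction_list(transactions)
  if (length(tx) == 0) abort("Transaction database is empty.")
  n <- length(tx)
  if (is.null(min_count)) min_count <- min_support_count(min_support, n)
  if (min_count < 1) abort("`min_count` must be at least 1.")

  acc <- new.env(parent = emptyenv())
  acc$res <- list()
  tree <- fp_build(tx, rep(1, n), min_count)
  fp_mine_rec(tree, character(0), min_count, min_size, acc)

  if (length(acc$res) == 0) {
    return(tibble(items = list(), support = integer(0),
                  support_frac = numeric(0)))
  }
  out <- tibble(
    items = purrr::map(acc$res, ~ sort(.x$items)),
    support = purrr::map_int(acc$res, ~ as.integer(.x$support))
  )
  key <- purrr::map_chr(out$items, paste, collapse = "\r")
  out <- out[order(lengths(out$items), key), ]
  out$support_frac <- out$support / n
  out
}

fp_mine_rec <- function(tree, suffix, min_count, min_size, acc) {
  items <- tree$item_order
  if (length(items) == 0) return(invisible())

  if (fp_single_path(tree)) {
    nodes <- fp_path_nodes(tree)
    k <- length(nodes)
    for (mask in seq_len(bitwShiftL(1L, k) - 1L)) {
      inc <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0L)
      pat <- c(tree$item[nodes[inc]], suffix)
      if (length(pat) >= min_size) {
        acc$res[[length(acc$res) + 1L]] <-
          list(items = pat, support = tree$count[nodes[max(inc)]])
      }
    }
    return(invisible())
  }

  # ascending frequency so each conditional base sees only more-frequent items
  for (it in rev(items)) {
    pat <- c(it, suffix)
    if (length(pat) >= min_size) {
      acc$res[[length(acc$res) + 1L]] <-
        list(items = pat, support = tree$header_count[[it]])
    }
    base_tx <- list()
    base_w <- numeric(0)
    for (id in tree$header[[it]]) {
      path <- character(0)
      p <- tree$parent[id]
      while (p > 1L) {
        path <- c(tree$item[p], path)
        p <- tree$parent[p]
      }
      if (length(path) > 0) {
        base_tx[[length(base_tx) + 1L]] <- path
        base_w <- c(base_w, tree$count[id])
      }
    }
    if (length(base_tx) > 0) {
      cond <- fp_build(base_tx, base_w, min_count)
      fp_mine_rec(cond, pat, min_count, min_size, acc)
    }
  }
  invisible()
}

fp_single_path <- function(tree) {
  all(lengths(tree$children) <= 1L)
}

# node ids along the single path, root excluded, top-down
fp_path_nodes <- function(tree) {
  nodes <- integer(0)
  cur <- 1L
  while (length(tree$children[[cur]]) == 1L) {
    cur <- unname(tree$children[[cur]][1L])
    nodes <- c(nodes, cur)
  }
  nodes
}

#' Genes supporting a cancer-type itemset
#'
#' Inverse gene-set mapping: the genes whose transaction contains every type
#' of the itemset, in input gene order. For an itemset mined by
#' [mine_frequent_itemsets()] the number of supporting genes equals the mined
#' support.
#'
#' @param itemset Character vector of cancer types (non-empty).
#' @param transactions A `transaction_db`.
#' @return Character vector of gene ids.
#' @export
supporting_genes <- function(itemset, transactions) {
  stopifnot(inherits(transactions, "transaction_db"))
  if (length(itemset) == 0) abort("`itemset` must be non-empty.")
  keep <- purrr::map_lgl(transactions$items, ~ all(itemset %in% .x))
  transactions$gene_id[keep]
}

as_transaction_list <- function(x) {
  if (inherits(x, "transaction_db")) {
    return(stats::setNames(x$items, x$gene_id))
  }
  if (is.list(x)) {
    return(purrr::map(x, as.character))
  }
  abort("Expected a transaction_db or a list of character vectors.")
}
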