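# walks every header chain and root-to-node path of a tree, asserting the
# structural FP-tree invariants
expect_valid_fptree <- function(tree) {
  hdr <- fptree_header(tree)
  # header-count conservation: chain counts sum to the header total
  expect_equal(hdr$chain_count, hdr$count)
  # every root-to-node path lists items in strictly decreasing frequency rank
  rank <- stats::setNames(seq_along(tree$item_order), tree$item_order)
  for (id in seq_along(tree$item)[-1]) {
    path <- character(0)
    p <- id
    while (p > 1) {
      path <- c(tree$item[p], path)
      p <- tree$parent[p]
    }
    expect_true(all(diff(rank[path]) > 0))
  }
  invisible(tree)
}

test_that("build_fptree compresses shared prefixes and filters rare items", {
  tree <- build_fptree(list(c("A", "B"), c("A", "B"), "A"), min_count = 1)
  hdr <- fptree_header(tree)
  expect_equal(hdr$item, c("A", "B"))
  expect_equal(hdr$count, c(3, 2))
  expect_equal(hdr$n_nodes, c(1, 1))          # root -> A(3) -> B(2)
  expect_equal(length(tree$item) - 1, 2)      # two nodes besides the root
  b <- tree$header[["B"]]
  expect_equal(tree$item[tree$parent[b]], "A")
  expect_valid_fptree(tree)

  pruned <- build_fptree(list(c("A", "B"), c("A", "B"), "A"), min_count = 3)
  expect_equal(fptree_header(pruned)$item, "A")
  expect_equal(length(pruned$item) - 1, 1)

  empty <- build_fptree(list(character(0), character(0)), min_count = 1)
  expect_equal(nrow(fptree_header(empty)), 0)
  expect_equal(length(empty$item), 1)         # root only, not an error
})

test_that("mine_frequent_itemsets returns exact supports on hand-checked DBs", {
  db <- list(c("A", "B", "C"), c("A", "B"), c("A", "C"), c("B", "C"))
  got <- mine_frequent_itemsets(db, min_count = 2)
  expect_equal(
    itemset_keys(got$items, got$support),
    c("A,B=2", "A,C=2", "B,C=2")              # {A,B,C} has support 1 only
  )

  uni <- mine_frequent_itemsets(rep(list(c("A", "B", "C")), 10),
                                min_count = 10)
  expect_equal(
    itemset_keys(uni$items, uni$support),
    c("A,B,C=10", "A,B=10", "A,C=10", "B,C=10")
  )
  expect_equal(nrow(mine_frequent_itemsets(db, min_count = 5)), 0)
  # min_size = 1 also surfaces the singletons
  singles <- mine_frequent_itemsets(db, min_count = 2, min_size = 1)
  expect_true(all(c("A=3", "B=3", "C=3") %in%
                    itemset_keys(singles$items, singles$support)))
})

test_that("FP-growth equals exhaustive enumeration on random databases", {
  withr::with_seed(2024, {
    for (rep in 1:40) {
      db <- random_db(n_items = sample(3:8, 1), n_tx = sample(5:60, 1),
                      density = runif(1, 0.2, 0.8))
      min_count <- sample(1:5, 1)
      got <- mine_frequent_itemsets(db, min_count = min_count)
      expect_identical(
        itemset_keys(got$items, got$support),
        oracle_keys(oracle_frequent_itemsets(db, min_count))
      )
      expect_valid_fptree(build_fptree(db, min_count = min_count))
    }
  })
})

test_that("mined itemsets are anti-monotone and canonically ordered", {
  withr::with_seed(7, {
    db <- random_db(6, 40, 0.5)
  })
  got <- mine_frequent_itemsets(db, min_count = 4)
  keys <- purrr::map_chr(got$items, paste, collapse = ",")
  sup <- stats::setNames(got$support, keys)
  for (i in seq_len(nrow(got))) {
    S <- got$items[[i]]
    if (length(S) <= 2) next
    for (sub in combn(S, length(S) - 1, simplify = FALSE)) {
      k <- paste(sub, collapse = ",")
      expect_true(k %in% keys)
      expect_gte(sup[[k]], got$support[i])
    }
  }
  # canonical serialization order: by size then lexicographic; rerun identical
  expect_identical(got, mine_frequent_itemsets(db, min_count = 4))
  expect_true(!is.unsorted(lengths(got$items)))
})

test_that("supporting_genes inverts itemsets back to gene lists", {
  txn <- toy_transactions(
    gene_items = list(g1 = c("A", "B"), g2 = c("A", "B", "C"), g3 = "A",
                      g4 = character(0)),
    gene_pairs = list(g1 = "A|B", g2 = c("A|B", "A|C", "B|C"),
                      g3 = character(0), g4 = character(0))
  )
  expect_equal(supporting_genes("A", txn), c("g1", "g2", "g3"))
  expect_equal(supporting_genes(c("A", "B"), txn), c("g1", "g2"))
  expect_equal(supporting_genes(c("A", "D"), txn), character(0))

  # |supporting_genes| equals the mined support, on random DBs
  withr::with_seed(33, {
    for (rep in 1:10) {
      db <- random_db(5, 30, 0.5)
      names(db) <- sprintf("g%02d", seq_along(db))
      txn <- toy_transactions(db, purrr::map(db, ~ character(0)))
      got <- mine_frequent_itemsets(txn, min_count = 3)
      for (i in seq_len(nrow(got))) {
        expect_length(supporting_genes(got$items[[i]], txn), got$support[i])
      }
    }
  })
})
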