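make_mark_transactions <- function(dbs_by_mark) {
  pairs_of <- function(its) {
    if (length(its) < 2) return(character(0))
    cm <- combn(sort(its), 2)
    paste(cm[1, ], cm[2, ], sep = "|")
  }
  purrr::imap(dbs_by_mark, function(db, mk) {
    toy_transactions(db, purrr::map(db, pairs_of), mark = mk)
  })
}

test_that("genes_for is anti-monotone, memoizable, and matches bi-clusters", {
  withr::with_seed(55, {
    db <- random_db(5, 40, 0.6)
    names(db) <- sprintf("g%02d", seq_along(db))
  })
  txn <- make_mark_transactions(list(m1 = db))
  expect_error(genes_for(c("A", "B"), "zzz", txn), "Unknown mark")
  expect_error(genes_for("A", "m1", txn), "at least 2")

  # growing the type set never grows the gene set
  g_ab <- genes_for(c("A", "B"), "m1", txn, mode = "loose")
  g_abc <- genes_for(c("A", "B", "C"), "m1", txn, mode = "loose")
  expect_true(all(g_abc %in% g_ab))

  # memoized and direct calls agree
  cache <- new.env()
  expect_identical(genes_for(c("A", "B"), "m1", txn, cache = cache),
                   genes_for(c("A", "B"), "m1", txn))
  expect_identical(genes_for(c("A", "B"), "m1", txn, cache = cache),
                   genes_for(c("A", "B"), "m1", txn))

  # agrees with form_biclusters gene lists on mined itemsets, both modes
  fis <- mine_frequent_itemsets(txn$m1, min_count = 4)
  for (mode in c("loose", "clique")) {
    bc <- form_biclusters(fis, txn$m1, min_count = 4, mode = mode)
    for (i in seq_len(nrow(bc))) {
      expect_identical(
        genes_for(bc$cancer_types[[i]], "m1", txn, mode = mode),
        bc$genes[[i]]
      )
    }
  }
})

test_that("identical transactions across marks reproduce the per-mark patterns", {
  withr::with_seed(8, {
    db <- random_db(4, 30, 0.6)
    names(db) <- sprintf("g%02d", seq_along(db))
  })
  txn <- make_mark_transactions(list(m1 = db, m2 = db))
  tc <- mine_triclusters(txn, min_count = 5, mode = "loose")
  expect_true(all(purrr::map_lgl(tc$marks, ~ setequal(.x, c("m1", "m2")))))
  # gene sets unchanged by intersecting a mark with itself
  for (i in seq_len(nrow(tc))) {
    expect_identical(tc$genes[[i]],
                     genes_for(tc$cancer_types[[i]], "m1", txn, "loose"))
  }

  # an all-empty second mark kills every cross-mark intersection
  empty_db <- purrr::map(db, ~ character(0))
  txn2 <- make_mark_transactions(list(m1 = db, m2 = empty_db))
  expect_equal(nrow(mine_triclusters(txn2, min_count = 5, mode = "loose")), 0)
})

test_that("a planted block is recovered exactly at zero noise", {
  stack <- simulate_profiles(
    n_genes = 150, n_types = 5, n_marks = 4, profile_length = 20,
    patterns = list(planted_pattern(1:40, 1:3, 1:3, noise_sd = 0)),
    seed = 77
  )
  tc <- mine_epitriclusters(stack, min_support = 0.10)
  rec <- score_recovery(tc, stack)
  expect_equal(rec$score, 1.0)
  expect_equal(nrow(tc), 1)
  expect_setequal(tc$genes[[1]], stack$truth$genes[[1]])
  expect_setequal(tc$cancer_types[[1]], stack$truth$cancer_types[[1]])
  expect_setequal(tc$marks[[1]], stack$truth$marks[[1]])
  expect_equal(tc$fold_enrichment[1], 40 / 150)
})

test_that("filter_maximal keeps exactly the non-contained candidates", {
  single <- tibble::tibble(marks = list(c("m1", "m2")),
                           cancer_types = list(c("A", "B")))
  expect_identical(filter_maximal(single), single)

  pair <- tibble::tibble(
    marks = list(c("m1", "m2"), c("m1", "m2")),
    cancer_types = list(c("A", "B"), c("A", "B", "C"))
  )
  kept <- filter_maximal(pair)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$cancer_types[[1]], c("A", "B", "C"))

  # random candidate lists against the brute-force containment oracle
  withr::with_seed(303, {
    for (rep in 1:25) {
      n <- sample(2:12, 1)
      cand <- tibble::tibble(
        marks = purrr::map(seq_len(n), ~ sample(paste0("m", 1:4),
                                                sample(2:4, 1))),
        cancer_types = purrr::map(seq_len(n), ~ sample(LETTERS[1:5],
                                                       sample(2:5, 1)))
      )
      got <- filter_maximal(cand)
      want <- cand[oracle_maximal_idx(cand$cancer_types, cand$marks), ]
      expect_identical(got, want)
    }
  })
})

test_that("tri-cluster mining is order-invariant and support is anti-monotone", {
  stack <- simulate_profiles(
    n_genes = 100, n_types = 5, n_marks = 3, profile_length = 20,
    patterns = list(
      planted_pattern(1:35, 1:3, 1:3, noise_sd = 0.25),
      planted_pattern(50:75, c(2, 4, 5), 2:3, noise_sd = 0.25)
    ),
    seed = 5150
  )
  txn <- purrr::map(stack$profiles, build_transactions)
  tc <- mine_triclusters(txn, min_support = 0.10)

  # result invariant to the order marks are supplied in
  tc_rev <- mine_triclusters(rev(txn), min_support = 0.10)
  expect_identical(as.data.frame(tc), as.data.frame(tc_rev))

  # every returned gene list equals direct recomputation across its marks
  for (i in seq_len(nrow(tc))) {
    direct <- Reduce(intersect, purrr::map(
      tc$marks[[i]], ~ genes_for(tc$cancer_types[[i]], .x, txn, "clique")
    ))
    expect_setequal(tc$genes[[i]], direct)
  }

  # support(T', E') >= support(T, E) for every sub-pattern with |.| >= 2
  for (i in seq_len(nrow(tc))) {
    Tset <- tc$cancer_types[[i]]
    Eset <- tc$marks[[i]]
    for (nt in 2:length(Tset)) {
      for (Tsub in combn(Tset, nt, simplify = FALSE)) {
        for (ne in 2:length(Eset)) {
          for (Esub in combn(Eset, ne, simplify = FALSE)) {
            sub_genes <- Reduce(intersect, purrr::map(
              Esub, ~ genes_for(Tsub, .x, txn, "clique")
            ))
            expect_gte(length(sub_genes), tc$support[i])
          }
        }
      }
    }
  }

  # no returned cluster contained in another
  expect_equal(oracle_maximal_idx(tc$cancer_types, tc$marks),
               seq_len(nrow(tc)))
})
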