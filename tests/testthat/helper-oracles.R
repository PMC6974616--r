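# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately brute-force / closed-form so it cannot
# share a code path with the implementation it checks.

# textbook two-pass Pearson: means first, then cov/(sd*sd)
oracle_pearson <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# exhaustive frequent-itemset enumeration over all 2^|items| subsets
oracle_frequent_itemsets <- function(tx, min_count, min_size = 2) {
  items <- sort(unique(unlist(tx)))
  out <- list()
  if (length(items) >= min_size) {
    for (k in seq(min_size, length(items))) {
      for (S in combn(items, k, simplify = FALSE)) {
        sup <- sum(vapply(tx, function(t) all(S %in% t), logical(1)))
        if (sup >= min_count) {
          out[[length(out) + 1]] <- list(items = S, support = sup)
        }
      }
    }
  }
  out
}

# canonical "items=support" keys, sorted, for set comparison
itemset_keys <- function(items_list, supports) {
  sort(sprintf("%s=%d",
               vapply(items_list, function(s) paste(sort(s), collapse = ","),
                      character(1)),
               as.integer(supports)))
}

oracle_keys <- function(oracle) {
  itemset_keys(lapply(oracle, `[[`, "items"),
               vapply(oracle, `[[`, numeric(1), "support"))
}

# random transaction DB: n_tx itemsets over an item alphabet
random_db <- function(n_items, n_tx, density) {
  items <- LETTERS[seq_len(n_items)]
  lapply(seq_len(n_tx), function(i) {
    keep <- runif(n_items) < density
    items[keep]
  })
}

# profile matrix built directly from per-gene, per-type vectors:
# vecs = list(gene_id = list(type = numeric(L)))
toy_profile <- function(vecs, mark = "H3K4me3") {
  df <- purrr::imap_dfr(vecs, function(types, g) {
    tibble::tibble(gene_id = g, cancer_type = names(types),
                   profile = unname(types))
  })
  profile_matrix(df, mark = mark)
}

# hand-built transaction_db, bypassing the coherence stage
toy_transactions <- function(gene_items, gene_pairs, mark = "H3K4me3",
                             cancer_types = NULL) {
  structure(
    tibble::tibble(
      gene_id = names(gene_items),
      items = unname(gene_items),
      pairs = unname(gene_pairs)
    ),
    mark = mark,
    cancer_types = cancer_types %||% sort(unique(unlist(gene_items))),
    corr_threshold = 0.7,
    class = c("transaction_db", class(tibble::tibble()))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent pairwise-containment scan for maximality
oracle_maximal_idx <- function(types_list, marks_list) {
  n <- length(types_list)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !keep[i]) next
      sub_t <- all(types_list[[i]] %in% types_list[[j]])
      sub_m <- all(marks_list[[i]] %in% marks_list[[j]])
      same <- setequal(types_list[[i]], types_list[[j]]) &&
        setequal(marks_list[[i]], marks_list[[j]])
      if (sub_t && sub_m && !same) keep[i] <- FALSE
    }
  }
  which(keep)
}

# three vectors with r(A,B) > 0.7, r(B,C) > 0.7, r(A,C) < 0.7, built from
# an exactly orthogonal sine/cosine pair: A = x, C = 0.5 x + z, B = A + C
# gives r(A,B) = 1.5/sqrt(3.25) ~ 0.832, r(B,C) ~ 0.868, r(A,C) ~ 0.447
abc_vectors <- function() {
  i <- 0:19
  x <- sin(2 * pi * i / 20)
  z <- cos(2 * pi * i / 20)
  y <- 0.5 * x + z
  list(A = x, B = x + y, C = y)
}
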