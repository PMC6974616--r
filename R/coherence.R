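#' Pearson correlation with a zero-variance sentinel
#'
#' Sample Pearson correlation of two equal-length vectors. If either vector
#' has zero variance the correlation is undefined; `NA_real_` is returned so
#' the pair can never pass a coherence threshold, letting all-flat promoter
#' profiles degrade gracefully instead of erroring.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return The correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
#' @examples
#' pearson_cor(1:4, c(2, 4, 5, 4))
#' pearson_cor(rep(1, 5), rnorm(5))  # NA: zero variance
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) {
    abort(sprintf("Vector lengths differ: %d vs %d.", length(x), length(y)))
  }
  if (length(x) < 2) abort("Need vectors of length >= 2.")
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Per-gene coherence transactions for one epigenetic mark
#'
#' For every gene, computes the Pearson correlation between the promoter
#' profiles of each unordered pair of cancer types. A pair with
#' `r > corr_threshold` (strict) is a *coherent pair*; the gene's
#' *transaction* is the union of all cancer types occurring in at least one
#' coherent pair. Genes with no coherent pair are retained with empty sets,
#' so the transaction database always covers the full gene universe.
#'
#' Both the transactions (the itemsets mined by FP-growth) and the underlying
#' coherent-pair sets are kept: the pair sets provide the pairwise evidence
#' needed by clique-mode bi-cluster finalization.
#'
#' @param profile A [profile_matrix()].
#' @param corr_threshold Coherence threshold `theta` in (-1, 1] (default 0.7).
#' @param min_profile_sd Profiles with standard deviation `<=` this value are
#'   excluded from all pairs (default 0, i.e. only zero-variance profiles are
#'   excluded).
#' @return A `transaction_db`: tibble with columns `gene_id`, list-column
#'   `items` (character vector of cancer types) and list-column `pairs`
#'   (coherent pairs encoded `"a|b"` with `a < b`), plus attributes `mark`,
#'   `cancer_types` and `corr_threshold`.
#' @export
build_transactions <- function(profile, corr_threshold = 0.7,
                               min_profile_sd = 0) {
  stopifnot(inherits(profile, "profile_matrix"))
  if (corr_threshold <= -1 || corr_threshold > 1) {
    abort("`corr_threshold` must lie in (-1, 1].")
  }
  genes <- attr(profile, "genes")
  types <- attr(profile, "cancer_types")
  if (length(types) < 2) abort("Need at least 2 cancer types.")

  per_gene <- purrr::map(genes, function(g) {
    m <- profile_gene_matrix(profile, g)
    sds <- apply(m, 2, sd)
    ok <- sds > 0 & sds >= min_profile_sd
    use <- colnames(m)[ok]
    if (length(use) < 2) {
      return(list(items = character(0), pairs = character(0)))
    }
    cc <- suppressWarnings(cor(m[, use, drop = FALSE]))
    idx <- which(upper.tri(cc) & cc > corr_threshold, arr.ind = TRUE)
    if (nrow(idx) == 0) {
      return(list(items = character(0), pairs = character(0)))
    }
    a <- use[idx[, 1]]
    b <- use[idx[, 2]]
    pairs <- pair_key(a, b)
    list(items = sort(unique(c(a, b))), pairs = sort(pairs))
  })

  structure(
    tibble(
      gene_id = genes,
      items = purrr::map(per_gene, "items"),
      pairs = purrr::map(per_gene, "pairs")
    ),
    mark = attr(profile, "mark"), cancer_types = types,
    corr_threshold = corr_threshold,
    class = c("transaction_db", class(tibble()))
  )
}

# canonical unordered-pair encoding "a|b", a < b lexicographically
pair_key <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  paste(lo, hi, sep = "|")
}

# all pair keys within a type set
type_set_pairs <- function(types) {
  if (length(types) < 2) return(character(0))
  cm <- combn(sort(types), 2)
  pair_key(cm[1, ], cm[2, ])
}

#' @export
print.transaction_db <- function(x, ...) {
  cat(sprintf(
    "<transaction_db> mark=%s  %d genes, %d cancer types, theta=%s\n",
    attr(x, "mark"), nrow(x), length(attr(x, "cancer_types")),
    format(attr(x, "corr_threshold"))
  ))
  NextMethod()
}
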