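test_that("bin_track assigns intervals by midpoint and conserves mass", {
  sizes <- c(chr1 = 1000)

  empty <- bin_track(tibble::tibble(chrom = character(0), start = numeric(0),
                                    end = numeric(0)), sizes, 200)
  expect_equal(nrow(empty), 5)
  expect_true(all(empty$value == 0))
  expect_equal(attr(empty, "total_reads"), 0)

  one <- bin_track(tibble::tibble(chrom = "chr1", start = 250, end = 300,
                                  count = 3), sizes, 200)
  expect_equal(one$value, c(0, 3, 0, 0, 0))  # midpoint 275 -> bin 1

  two <- bin_track(tibble::tibble(chrom = "chr1", start = c(40, 198),
                                  end = c(60, 200), count = c(2, 5)),
                   sizes, 200)
  expect_equal(two$value[1], 7)  # midpoints 50 and 199 both in bin 0

  withr::with_seed(11, {
    iv <- tibble::tibble(
      chrom = "chr1",
      start = sample(0:900, 50),
      count = sample(1:10, 50, replace = TRUE)
    )
    iv$end <- iv$start + sample(1:80, 50, replace = TRUE)
    iv$end <- pmin(iv$end, 1000)
    tr <- bin_track(iv, sizes, 200)
    expect_equal(sum(tr$value), sum(iv$count))
    expect_equal(attr(tr, "total_reads"), sum(iv$count))
  })
})

test_that("bin_track rejects bad intervals", {
  sizes <- c(chr1 = 1000)
  expect_error(
    bin_track(tibble::tibble(chrom = "chrX", start = 0, end = 10), sizes, 200),
    "chrX"
  )
  expect_error(
    bin_track(tibble::tibble(chrom = "chr1", start = 0, end = 10, count = -1),
              sizes, 200),
    "Negative"
  )
  expect_error(
    bin_track(tibble::tibble(chrom = "chr1", start = 10, end = 10), sizes, 200),
    "start < end"
  )
})

test_that("normalize_track matches the asinh closed form and its invariances", {
  sizes <- c(chr1 = 1000)
  mk <- function(vals, total) {
    iv <- tibble::tibble(chrom = "chr1", start = seq(0, by = 200,
                                                     length.out = 5) + 10,
                         end = seq(0, by = 200, length.out = 5) + 30,
                         count = vals)
    tr <- bin_track(iv, sizes, 200)
    stopifnot(attr(tr, "total_reads") == total)
    tr
  }

  # zero fixed point
  z <- bin_track(tibble::tibble(chrom = "chr1", start = 0, end = 10,
                                count = 0), sizes, 200)
  expect_error(normalize_track(z), "zero total reads")

  tr <- mk(c(10, 0, 5, 0, 5), 20)
  nt <- normalize_track(tr, scale = 20)  # v * scale/total = v
  expect_equal(nt$value[2], 0)
  # bin with v = total/scale: asinh(1) = log(1 + sqrt(2))
  expect_equal(normalize_track(mk(c(1, 0, 9, 0, 10), 20), scale = 20)$value[1],
               log(1 + sqrt(2)))

  # invariance to uniform rescaling of counts and depth
  a <- normalize_track(mk(c(10, 0, 5, 0, 5), 20))
  b <- normalize_track(mk(c(20, 0, 10, 0, 10), 40))
  expect_equal(a$value, b$value, tolerance = 1e-12)

  # monotone in the raw count
  vals <- normalize_track(mk(c(1, 2, 4, 8, 5), 20))$value
  expect_true(all(diff(vals[1:4]) > 0))

  expect_error(normalize_track(a), "already normalized")
})

test_that("promoter_windows is strand-aware and drops clipped genes", {
  sizes <- c(chr1 = 10000)
  ann <- tibble::tibble(
    gene_id = c("gPlus", "gMinus", "gEdge"),
    chrom = "chr1",
    tss = c(5000, 5000, 500),
    strand = c("+", "-", "+")
  )
  expect_warning(w <- promoter_windows(ann, sizes), "gEdge")
  expect_equal(w$start[w$gene_id == "gPlus"], 3000)
  expect_equal(w$end[w$gene_id == "gPlus"], 7000)
  # same coordinates on - strand; orientation handled at profile extraction
  expect_equal(w$start[w$gene_id == "gMinus"], 3000)
  expect_equal(w$end[w$gene_id == "gMinus"], 7000)
  expect_false("gEdge" %in% w$gene_id)
  expect_equal(attr(w, "dropped"), "gEdge")

  expect_error(
    promoter_windows(dplyr::mutate(ann, gene_id = "dup"), sizes),
    "Duplicate"
  )
  expect_error(
    promoter_windows(dplyr::mutate(ann, strand = "."), sizes),
    "strand"
  )
})

test_that("build_profile_matrix extracts windows, reverses - strand, checks tracks", {
  sizes <- c(chr1 = 12000)
  ann <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    chrom = "chr1", tss = c(3000, 6000, 9000), strand = c("+", "+", "-")
  )
  w <- promoter_windows(ann, sizes)

  mktrack <- function(counts, ct) {
    iv <- tibble::tibble(
      chrom = "chr1",
      start = seq(0, by = 200, length.out = length(counts)) + 50,
      end = seq(0, by = 200, length.out = length(counts)) + 150,
      count = counts
    )
    bin_track(iv, sizes, 200, cancer_type = ct, mark = "H3K27ac") |>
      normalize_track()
  }
  withr::with_seed(5, {
    t1 <- mktrack(sample(1:50, 60, replace = TRUE), "T01")
    t2 <- mktrack(sample(1:50, 60, replace = TRUE), "T02")
  })
  pm <- build_profile_matrix(list(t1, t2), w)
  expect_s3_class(pm, "profile_matrix")
  expect_equal(nrow(pm), 6)                       # 2 types x 3 genes
  expect_true(all(lengths(pm$profile) == 20))     # 4000 / 200

  # minus-strand profile is the reverse of the same window read forward
  fwd_ann <- dplyr::mutate(ann, strand = "+")
  pm_fwd <- build_profile_matrix(list(t1, t2), promoter_windows(fwd_ann, sizes))
  p_rev <- pm$profile[[which(pm$gene_id == "g3" & pm$cancer_type == "T01")]]
  p_fwd <- pm_fwd$profile[[which(pm_fwd$gene_id == "g3" &
                                   pm_fwd$cancer_type == "T01")]]
  expect_equal(rev(p_rev), p_fwd)
  expect_equal(rev(rev(p_rev)), p_rev)

  # a single nonzero bin inside exactly one window shows up in one profile
  spike <- bin_track(
    tibble::tibble(chrom = "chr1", start = 2100, end = 2120, count = 7),
    sizes, 200, cancer_type = "T01", mark = "H3K27ac"
  ) |> normalize_track()
  spike2 <- bin_track(
    tibble::tibble(chrom = "chr1", start = 2100, end = 2120, count = 7),
    sizes, 200, cancer_type = "T02", mark = "H3K27ac"
  ) |> normalize_track()
  pm_sp <- build_profile_matrix(list(spike, spike2), w)
  nz <- purrr::map_lgl(pm_sp$profile, ~ any(.x != 0))
  expect_equal(sort(unique(pm_sp$gene_id[nz])), "g1")  # bin 10 in [1000,5000)

  # constant track value -> every profile constant
  const <- purrr::map(c("T01", "T02"), function(ct) {
    tr <- mktrack(rep(10, 60), ct)
    tr
  })
  pm_c <- build_profile_matrix(const, w)
  expect_true(all(purrr::map_lgl(pm_c$profile, ~ length(unique(.x)) == 1)))

  # declared type with no track errors with the missing pair
  expect_error(
    build_profile_matrix(list(t1, t2), w, cancer_types = c("T01", "T02", "T03")),
    "T03"
  )
})

test_that("profile matrices are invariant to gene input order", {
  sizes <- c(chr1 = 12000)
  ann <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    chrom = "chr1", tss = c(3000, 6000, 9000), strand = "+"
  )
  mktrack <- function(ct, seed) {
    withr::with_seed(seed, {
      iv <- tibble::tibble(
        chrom = "chr1", start = seq(0, by = 200, length.out = 60) + 50,
        end = seq(0, by = 200, length.out = 60) + 150,
        count = sample(1:50, 60, replace = TRUE)
      )
    })
    bin_track(iv, sizes, 200, cancer_type = ct, mark = "m") |> normalize_track()
  }
  tracks <- list(mktrack("T01", 1), mktrack("T02", 2))
  a <- build_profile_matrix(tracks, promoter_windows(ann, sizes))
  b <- build_profile_matrix(tracks, promoter_windows(ann[c(3, 1, 2), ], sizes))
  ka <- paste(a$gene_id, a$cancer_type)
  kb <- paste(b$gene_id, b$cancer_type)
  expect_setequal(ka, kb)
  expect_equal(a$profile[order(ka)], b$profile[order(kb)])
})
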