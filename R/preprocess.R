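#' Bin a signal track into fixed-width genomic segments
#'
#' Divides each chromosome into consecutive segments of `bin_size` bp and sums
#' the read/interval counts falling in each segment. An interval is assigned
#' to exactly one bin, the one containing its midpoint `floor((start+end)/2)`,
#' so mass is conserved and nothing is double counted.
#'
#' @param intervals A data frame with columns `chrom`, `start`, `end`
#'   (0-based, half-open) and optionally `count` (default 1 per interval).
#' @param chrom_sizes Named numeric vector or two-column data frame
#'   (`chrom`, `size`) giving chromosome lengths in bp.
#' @param bin_size Segment size in bp (default 200).
#' @param cancer_type,mark Identifiers attached to the track.
#'
#' @return A `signal_track`: a tibble with columns `chrom`, `bin` (0-based
#'   index) and `value`, one row per bin of every chromosome in
#'   `chrom_sizes`, carrying `cancer_type`, `mark`, `bin_size`,
#'   `total_reads`, `normalized` and `chrom_sizes` as attributes.
#' @export
#' @examples
#' iv <- tibble::tibble(chrom = "chr1", start = 250, end = 300, count = 3)
#' tr <- bin_track(iv, c(chr1 = 1000), bin_size = 200)
#' tr$value  # midpoint 275 falls in bin 1
bin_track <- function(intervals, chrom_sizes, bin_size = 200L,
                      cancer_type = NA_character_, mark = NA_character_) {
  bin_size <- as.integer(bin_size)
  if (bin_size <= 0L) abort("`bin_size` must be positive.")
  sizes <- as_chrom_sizes(chrom_sizes)
  intervals <- as_tibble(intervals)
  if (!all(c("chrom", "start", "end") %in% names(intervals))) {
    abort("`intervals` needs columns chrom, start, end.")
  }
  if (!"count" %in% names(intervals)) intervals$count <- 1
  if (nrow(intervals) > 0) {
    unknown <- setdiff(unique(intervals$chrom), names(sizes))
    if (length(unknown) > 0) {
      abort(sprintf("Interval(s) on unknown chromosome(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    if (any(intervals$count < 0)) abort("Negative interval counts are not allowed.")
    if (any(intervals$start < 0) || any(intervals$end <= intervals$start)) {
      abort("Intervals must satisfy 0 <= start < end.")
    }
    too_far <- intervals$end > sizes[intervals$chrom]
    if (any(too_far)) {
      abort(sprintf("%d interval(s) extend beyond their chromosome.",
                    sum(too_far)))
    }
  }

  grid <- purrr::map2_dfr(names(sizes), unname(sizes), function(ch, len) {
    tibble(chrom = ch, bin = seq_len(ceiling(len / bin_size)) - 1L, value = 0)
  })
  if (nrow(intervals) > 0) {
    mid <- (intervals$start + intervals$end) %/% 2L
    hits <- tibble(chrom = intervals$chrom, bin = as.integer(mid %/% bin_size),
                   count = intervals$count) |>
      dplyr::group_by(.data$chrom, .data$bin) |>
      dplyr::summarise(add = sum(.data$count), .groups = "drop")
    grid <- dplyr::left_join(grid, hits, by = c("chrom", "bin")) |>
      dplyr::mutate(value = .data$value + dplyr::coalesce(.data$add, 0)) |>
      dplyr::select(-"add")
  }
  new_signal_track(grid,
    cancer_type = cancer_type, mark = mark, bin_size = bin_size,
    total_reads = sum(intervals$count), normalized = FALSE,
    chrom_sizes = sizes
  )
}

new_signal_track <- function(df, cancer_type, mark, bin_size, total_reads,
                             normalized, chrom_sizes) {
  structure(
    as_tibble(df),
    cancer_type = cancer_type, mark = mark, bin_size = bin_size,
    total_reads = total_reads, normalized = normalized,
    chrom_sizes = chrom_sizes,
    class = c("signal_track", class(tibble()))
  )
}

as_chrom_sizes <- function(x) {
  if (is.data.frame(x)) {
    sizes <- stats::setNames(as.numeric(x[[2]]), as.character(x[[1]]))
  } else {
    sizes <- x
  }
  if (is.null(names(sizes)) || any(!nzchar(names(sizes)))) {
    abort("Chromosome sizes must be named by chromosome.")
  }
  if (any(sizes <= 0)) abort("Chromosome sizes must be positive.")
  sizes
}

#' Depth-normalize a binned track
#'
#' Scales each bin value by `scale / total_reads` and applies the inverse
#' hyperbolic sine `asinh(x) = log(x + sqrt(x^2 + 1))`, a variance-stabilizing
#' transform that is defined for all non-negative scaled counts and leaves
#' zero bins at zero. The result is invariant to uniformly rescaling counts
#' and sequencing depth together.
#'
#' @param track A raw (un-normalized) [bin_track()] result with
#'   `total_reads > 0`.
#' @param scale Reads-per-scale factor (default 1e7).
#' @return A `signal_track` marked normalized.
#' @export
normalize_track <- function(track, scale = 1e7) {
  stopifnot(inherits(track, "signal_track"))
  if (isTRUE(attr(track, "normalized"))) {
    abort("Track is already normalized.")
  }
  total <- attr(track, "total_reads")
  if (is.null(total) || total <= 0) {
    abort("Cannot normalize a track with zero total reads.")
  }
  if (scale <= 0) abort("`scale` must be positive.")
  out <- track
  out$value <- asinh(track$value * scale / total)
  attr(out, "normalized") <- TRUE
  out
}

#' Promoter windows around transcription start sites
#'
#' For a `+` strand gene the promoter is `[TSS - upstream, TSS + downstream)`;
#' for a `-` strand gene `[TSS - downstream, TSS + upstream)`, so the window
#' always extends `upstream` bp in the direction transcription comes from.
#' Windows are clipped to chromosome bounds and genes whose clipped window is
#' shorter than the full window are dropped (with a warning naming them), so
#' every retained promoter yields a profile of identical length.
#'
#' @param annotation Data frame with columns `gene_id`, `chrom`, `tss`
#'   (0-based position) and `strand` (`+` or `-`). See [read_annotation()].
#' @param chrom_sizes Named vector or two-column data frame of chromosome
#'   lengths.
#' @param upstream,downstream Window extents in bp (defaults 2000/2000).
#' @return A tibble `gene_id`, `chrom`, `start`, `end`, `strand` (0-based,
#'   half-open), with dropped gene ids in attribute `"dropped"`.
#' @export
promoter_windows <- function(annotation, chrom_sizes,
                             upstream = 2000L, downstream = 2000L) {
  sizes <- as_chrom_sizes(chrom_sizes)
  ann <- as_tibble(annotation)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(ann))) {
    abort(sprintf("`annotation` needs columns: %s.", paste(need, collapse = ", ")))
  }
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate gene id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  bad_strand <- setdiff(unique(ann$strand), c("+", "-"))
  if (length(bad_strand) > 0) {
    abort(sprintf("Unknown strand symbol(s): %s (promoters need '+' or '-').",
                  paste(bad_strand, collapse = ", ")))
  }
  unknown <- setdiff(unique(ann$chrom), names(sizes))
  if (length(unknown) > 0) {
    abort(sprintf("Gene(s) on unknown chromosome(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  len <- sizes[ann$chrom]
  if (any(ann$tss < 0 | ann$tss >= len)) {
    abort("TSS positions must lie within chromosome bounds.")
  }
  win <- upstream + downstream
  start_raw <- ifelse(ann$strand == "+", ann$tss - upstream, ann$tss - downstream)
  end_raw <- start_raw + win
  start <- pmax(start_raw, 0)
  end <- pmin(end_raw, len)
  keep <- (end - start) == win
  if (any(!keep)) {
    warn(sprintf(
      "Dropped %d gene(s) with clipped promoter window: %s",
      sum(!keep), paste(ann$gene_id[!keep], collapse = ", ")
    ))
  }
  out <- tibble(
    gene_id = ann$gene_id, chrom = ann$chrom,
    start = as.numeric(start), end = as.numeric(end), strand = ann$strand
  )[keep, ]
  attr(out, "dropped") <- ann$gene_id[!keep]
  out
}

#' Assemble the per-mark promoter profile matrix
#'
#' For one epigenetic mark, collects from each cancer type's normalized track
#' the `L = window / bin_size` consecutive bin values covering every gene's
#' promoter window. Profiles of `-` strand genes are reversed so position 1 is
#' always most upstream; reversing twice is the identity.
#'
#' @param tracks List of normalized `signal_track`s for one mark, one per
#'   cancer type (type taken from each track's `cancer_type` attribute, or
#'   from list names).
#' @param windows Promoter windows from [promoter_windows()].
#' @param cancer_types Optional character vector declaring the expected types;
#'   any declared type without a track is an error listing the missing pairs.
#' @return A `profile_matrix`: tibble with columns `gene_id`, `cancer_type`
#'   and list-column `profile` (numeric length `L`), plus attributes `mark`,
#'   `bin_size`, `profile_length`, `cancer_types` and `genes`.
#' @export
build_profile_matrix <- function(tracks, windows, cancer_types = NULL) {
  if (length(tracks) == 0) abort("No tracks supplied.")
  types <- purrr::imap_chr(tracks, function(tr, nm) {
    ct <- attr(tr, "cancer_type")
    if (is.null(ct) || is.na(ct)) {
      if (is.character(nm) && nzchar(nm)) nm else
        abort("Each track needs a cancer_type attribute or a list name.")
    } else ct
  })
  if (anyDuplicated(types)) abort("Duplicate cancer types among tracks.")
  if (!is.null(cancer_types)) {
    missing <- setdiff(cancer_types, types)
    if (length(missing) > 0) {
      mk <- attr(tracks[[1]], "mark") %||% NA_character_
      abort(sprintf("Missing track(s) for (type, mark) pair(s): %s",
                    paste(sprintf("(%s, %s)", missing, mk), collapse = ", ")))
    }
    keep <- types %in% cancer_types
    tracks <- tracks[keep]
    types <- types[keep]
  }
  marks <- unique(purrr::map_chr(tracks, ~ attr(.x, "mark") %||% NA_character_))
  if (length(marks) > 1) abort("All tracks must carry the same mark.")
  bss <- unique(purrr::map_int(tracks, ~ as.integer(attr(.x, "bin_size"))))
  if (length(bss) > 1) abort("All tracks must share the same bin_size.")
  if (!all(purrr::map_lgl(tracks, ~ isTRUE(attr(.x, "normalized"))))) {
    abort("All tracks must be normalized (see normalize_track()).")
  }
  bin_size <- bss
  win_len <- unique(windows$end - windows$start)
  if (length(win_len) != 1) abort("Promoter windows must share one length.")
  L <- as.integer(win_len %/% bin_size)
  if (L <= 1L) abort("Profiles must have length > 1; shrink bin_size or widen the window.")

  rows <- purrr::map2_dfr(tracks, types, function(tr, ct) {
    vecs <- split(tr$value, tr$chrom)
    prof <- purrr::pmap(
      list(windows$chrom, windows$start, windows$strand),
      function(ch, st, strand) {
        first <- as.integer(st %/% bin_size)
        v <- vecs[[ch]][(first + 1L):(first + L)]
        if (strand == "-") rev(v) else v
      }
    )
    tibble(gene_id = windows$gene_id, cancer_type = ct, profile = prof)
  })
  profile_matrix(rows, mark = marks, bin_size = bin_size)
}

#' Construct a profile matrix from a tidy tibble
#'
#' Lower-level constructor used by [build_profile_matrix()], the simulator and
#' the TSV reader. Validates that every (gene, type) pair is present exactly
#' once and that all profiles share one length.
#'
#' @param df Tibble with columns `gene_id`, `cancer_type` and list-column
#'   `profile` of equal-length numeric vectors.
#' @param mark Mark identifier.
#' @param bin_size Bin size in bp the profiles were computed at (NA if
#'   simulated directly at profile level).
#' @return A `profile_matrix`.
#' @export
profile_matrix <- function(df, mark, bin_size = NA_integer_) {
  df <- as_tibble(df)
  stopifnot(all(c("gene_id", "cancer_type", "profile") %in% names(df)))
  lens <- unique(lengths(df$profile))
  if (length(lens) != 1 || lens <= 1) {
    abort("All profiles must share one length L > 1.")
  }
  genes <- unique(df$gene_id)
  types <- unique(df$cancer_type)
  if (length(types) < 2) abort("A profile matrix needs at least 2 cancer types.")
  if (nrow(df) != length(genes) * length(types) ||
      anyDuplicated(paste(df$gene_id, df$cancer_type))) {
    abort("Need exactly one profile per (gene, cancer type) pair.")
  }
  structure(
    df[c("gene_id", "cancer_type", "profile")],
    mark = mark, bin_size = bin_size, profile_length = as.integer(lens),
    cancer_types = types, genes = genes,
    class = c("profile_matrix", class(tibble()))
  )
}

# L x n_types numeric matrix of one gene's profiles, columns named by type
profile_gene_matrix <- function(profile, gene) {
  sub <- profile[profile$gene_id == gene, ]
  m <- do.call(cbind, sub$profile)
  colnames(m) <- sub$cancer_type
  m
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf(
    "<profile_matrix> mark=%s  %d genes x %d cancer types, L=%d\n",
    attr(x, "mark"), length(attr(x, "genes")),
    length(attr(x, "cancer_types")), attr(x, "profile_length")
  ))
  NextMethod()
}
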