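#' Read a UCSC-style chromosome sizes file
#'
#' @param path Two-column TSV: chromosome name, length in bp.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "size"),
                        col_types = "cd", progress = FALSE)
  as_chrom_sizes(df)
}

#' Read a bedGraph signal file
#'
#' Four tab-separated columns (chrom, start, end, value) with 0-based
#' half-open coordinates. `track`, `browser` and `#` comment lines are
#' skipped. Malformed lines (wrong field count, non-numeric value,
#' `end <= start`, negative start) raise an error naming the line number.
#'
#' @param path Path to the bedGraph file.
#' @return Tibble `chrom`, `start`, `end`, `count`, ready for [bin_track()].
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lineno <- seq_along(lines)
  skip <- grepl("^(track|browser)\\b", lines) | grepl("^#", lines) |
    !nzchar(trimws(lines))
  lines <- lines[!skip]
  lineno <- lineno[!skip]
  if (length(lines) == 0) {
    return(tibble(chrom = character(0), start = numeric(0),
                  end = numeric(0), count = numeric(0)))
  }
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf != 4)) {
    abort(sprintf("Malformed bedGraph line %d: expected 4 tab-separated fields, got %d.",
                  lineno[which(nf != 4)[1]], nf[which(nf != 4)[1]]))
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  val <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(val))[1]
  if (!is.na(bad)) {
    abort(sprintf("Malformed bedGraph line %d: non-numeric field.", lineno[bad]))
  }
  bad <- which(end <= start | start < 0)[1]
  if (!is.na(bad)) {
    abort(sprintf("Malformed bedGraph line %d: need 0 <= start < end.", lineno[bad]))
  }
  tibble(chrom = m[, 1], start = start, end = end, count = val)
}

#' Read a gene annotation as TSS records
#'
#' Supports BED6 (0-based half-open; the TSS is `start` on the `+` strand and
#' `end - 1` on the `-` strand) and GFF3 `gene` records (1-based inclusive,
#' converted to 0-based on read; imported via rtracklayer).
#'
#' @param path Annotation file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return Tibble `gene_id`, `chrom`, `tss` (0-based), `strand`, for
#'   [promoter_windows()].
#' @export
read_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3"
      else "bed"
  }
  if (format == "bed") {
    df <- readr::read_tsv(path,
      col_names = c("chrom", "start", "end", "name", "score", "strand"),
      col_types = "cddccc", comment = "#", progress = FALSE
    )
    return(tibble(
      gene_id = df$name, chrom = df$chrom,
      tss = ifelse(df$strand == "-", df$end - 1, df$start),
      strand = df$strand
    ))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("GFF3 input needs the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  md <- as.data.frame(gr)
  id <- md$ID %||% md$gene_id %||% md$Name
  if (is.null(id)) abort("GFF3 gene records carry no ID/gene_id/Name attribute.")
  strand <- as.character(md$strand)
  tibble(
    gene_id = as.character(id), chrom = as.character(md$seqnames),
    tss = ifelse(strand == "-", md$end - 1, md$start - 1),
    strand = strand
  )
}

join_set <- function(x) purrr::map_chr(x, paste, collapse = ";")
split_set <- function(x) {
  purrr::map(x, ~ if (is.na(.x) || !nzchar(.x)) character(0)
             else strsplit(.x, ";", fixed = TRUE)[[1]])
}

#' Write / read a profile matrix as TSV
#'
#' One row per (gene, cancer type): `gene_id`, `cancer_type`, then the `L`
#' signal values as columns `b1..bL`. A JSON sidecar (`<path>.json`) records
#' the mark, bin size and profile length so the reader can rebuild the exact
#' in-memory object.
#'
#' @param profile A `profile_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly (writer); a `profile_matrix` (reader).
#' @export
write_profile_matrix <- function(profile, path) {
  stopifnot(inherits(profile, "profile_matrix"))
  L <- attr(profile, "profile_length")
  vals <- do.call(rbind, profile$profile)
  colnames(vals) <- sprintf("b%d", seq_len(L))
  df <- dplyr::bind_cols(
    tibble(gene_id = profile$gene_id, cancer_type = profile$cancer_type),
    as_tibble(vals)
  )
  readr::write_tsv(df, path, progress = FALSE)
  jsonlite::write_json(
    list(mark = attr(profile, "mark"),
         bin_size = attr(profile, "bin_size"),
         profile_length = L),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", cancer_type = "c", .default = "d"
  ), progress = FALSE)
  bcols <- setdiff(names(df), c("gene_id", "cancer_type"))
  m <- as.matrix(df[bcols])
  prof <- purrr::map(seq_len(nrow(m)), ~ unname(m[.x, ]))
  profile_matrix(
    tibble(gene_id = df$gene_id, cancer_type = df$cancer_type, profile = prof),
    mark = meta$mark,
    bin_size = meta$bin_size %||% NA_integer_
  )
}

#' Write / read a transaction database as TSV
#'
#' Columns: `gene_id`, `mark`, semicolon-joined coherent type list,
#' semicolon-joined coherent pair list (pairs encoded `a|b`).
#'
#' @param transactions A `transaction_db`.
#' @param path TSV path.
#' @param cancer_types,corr_threshold Optional metadata for the reader; when
#'   omitted, the type universe is reconstructed from the items.
#' @return `path`, invisibly (writer); a `transaction_db` (reader).
#' @export
write_transactions <- function(transactions, path) {
  stopifnot(inherits(transactions, "transaction_db"))
  readr::write_tsv(tibble(
    gene_id = transactions$gene_id,
    mark = attr(transactions, "mark") %||% NA_character_,
    items = join_set(transactions$items),
    pairs = join_set(transactions$pairs)
  ), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_transactions
#' @export
read_transactions <- function(path, cancer_types = NULL,
                              corr_threshold = NA_real_) {
  df <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  items <- split_set(df$items)
  structure(
    tibble(gene_id = df$gene_id, items = items, pairs = split_set(df$pairs)),
    mark = df$mark[1] %||% NA_character_,
    cancer_types = cancer_types %||% sort(unique(unlist(items))),
    corr_threshold = corr_threshold,
    class = c("transaction_db", class(tibble()))
  )
}

#' Write / read frequent itemsets as TSV
#'
#' Columns: `mark`, semicolon-joined cancer types, `support`, `support_frac`.
#'
#' @param itemsets Tibble from [mine_frequent_itemsets()].
#' @param mark Mark identifier recorded with each row.
#' @param path TSV path.
#' @return `path`, invisibly (writer); the itemsets tibble with a `mark`
#'   column dropped back into attributes (reader).
#' @export
write_itemsets <- function(itemsets, mark, path) {
  readr::write_tsv(tibble(
    mark = rep(mark, nrow(itemsets)),
    cancer_types = join_set(itemsets$items),
    support = itemsets$support,
    support_frac = itemsets$support_frac
  ), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_itemsets
#' @export
read_itemsets <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccid", progress = FALSE)
  tibble(items = split_set(df$cancer_types), support = df$support,
         support_frac = df$support_frac)
}

#' Write / read bi-clusters as TSV
#'
#' Columns: `mark`, `mode`, semicolon-joined types, `support`,
#' semicolon-joined gene ids.
#'
#' @param biclusters A `bicluster_set`.
#' @param path TSV path.
#' @return `path`, invisibly (writer); a `bicluster_set` (reader).
#' @export
write_biclusters <- function(biclusters, path) {
  readr::write_tsv(tibble(
    mark = biclusters$mark,
    mode = biclusters$mode,
    cancer_types = join_set(biclusters$cancer_types),
    support = biclusters$support,
    genes = join_set(biclusters$genes)
  ), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_biclusters
#' @export
read_biclusters <- function(path) {
  df <- readr::read_tsv(path, col_types = "cccic", progress = FALSE)
  structure(
    tibble(mark = df$mark, mode = df$mode,
           cancer_types = split_set(df$cancer_types),
           support = df$support, genes = split_set(df$genes)),
    class = c("bicluster_set", class(tibble()))
  )
}

#' Write / read tri-clusters as TSV
#'
#' Columns: `cluster_id`, semicolon-joined marks, semicolon-joined types,
#' `support`, `fold_enrichment`, semicolon-joined gene ids.
#'
#' @param triclusters A `tricluster_set`.
#' @param path TSV path.
#' @return `path`, invisibly (writer); a `tricluster_set` (reader).
#' @export
write_triclusters <- function(triclusters, path) {
  readr::write_tsv(tibble(
    cluster_id = triclusters$cluster_id,
    marks = join_set(triclusters$marks),
    cancer_types = join_set(triclusters$cancer_types),
    support = triclusters$support,
    fold_enrichment = triclusters$fold_enrichment,
    genes = join_set(triclusters$genes)
  ), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_triclusters
#' @export
read_triclusters <- function(path) {
  df <- readr::read_tsv(path, col_types = "cccidc", progress = FALSE)
  structure(
    tibble(cluster_id = df$cluster_id, marks = split_set(df$marks),
           cancer_types = split_set(df$cancer_types), support = df$support,
           fold_enrichment = df$fold_enrichment, genes = split_set(df$genes)),
    class = c("tricluster_set", class(tibble()))
  )
}

#' Export one plain-text gene list per tri-cluster
#'
#' Writes `<cluster_id>.txt` files (one gene id per line) suitable for
#' external enrichment tools.
#'
#' @param triclusters A `tricluster_set`.
#' @param dir Output directory (created if needed).
#' @return The written paths, invisibly.
#' @export
write_gene_lists <- function(triclusters, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map2_chr(
    triclusters$cluster_id, triclusters$genes,
    function(id, genes) {
      p <- file.path(dir, paste0(id, ".txt"))
      readr::write_lines(genes, p)
      p
    }
  )
  invisible(paths)
}

#' Write a synthetic stack in pipeline format
#'
#' Serializes each mark's profile matrix with [write_profile_matrix()] into
#' `dir/profiles/` and the planted truth (with the generation seed) as
#' `truth.json`.
#'
#' @param stack A `synthetic_stack`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "synthetic_stack"))
  pdir <- file.path(dir, "profiles")
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  for (mk in names(stack$profiles)) {
    write_profile_matrix(stack$profiles[[mk]], file.path(pdir, paste0(mk, ".tsv")))
  }
  truth <- stack$truth
  jsonlite::write_json(
    list(
      seed = attr(stack, "seed"),
      n_genes = attr(stack, "n_genes"),
      n_types = attr(stack, "n_types"),
      n_marks = attr(stack, "n_marks"),
      profile_length = attr(stack, "profile_length"),
      background_sd = attr(stack, "background_sd"),
      patterns = purrr::pmap(
        truth,
        function(pattern_id, genes, cancer_types, marks, noise_sd) {
          list(pattern_id = pattern_id, genes = genes,
               cancer_types = cancer_types, marks = marks, noise_sd = noise_sd)
        }
      )
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read the profile matrices of a serialized stack or pipeline run
#'
#' @param dir Directory containing `<mark>.tsv` + `<mark>.tsv.json` pairs
#'   (e.g. the `profiles/` directory written by [run_pipeline()] or
#'   [write_synthetic_stack()]).
#' @return Named list of `profile_matrix` objects.
#' @export
read_profile_dir <- function(dir) {
  paths <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(paths) == 0) abort(sprintf("No profile TSVs found in %s", dir))
  profs <- purrr::map(paths, read_profile_matrix)
  stats::setNames(profs, purrr::map_chr(profs, ~ attr(.x, "mark")))
}
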