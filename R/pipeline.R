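#' Run the full tri-clustering pipeline
#'
#' Executes preprocess (bin, normalize, promoter extraction), coherence
#' transaction construction, per-mark frequent-itemset mining and bi-cluster
#' formation, and cross-mark tri-cluster mining, writing every intermediate
#' stage to `outdir` together with a provenance JSON. The run is a pure
#' function of (inputs, config): re-running with identical inputs produces
#' byte-identical outputs.
#'
#' Inputs can be supplied at either of two levels:
#'
#' * raw tracks — `manifest` (tibble `cancer_type`, `mark`, `path` of
#'   bedGraph files), `annotation` (path or TSS tibble) and `chrom_sizes`
#'   (path or named vector); the manifest is validated up front so a missing
#'   track fails before any computation;
#' * pre-built profiles — `profiles`, a named list of [profile_matrix()]
#'   objects (e.g. from [read_profile_dir()] or [simulate_profiles()]),
#'   skipping the preprocess stage.
#'
#' @param outdir Output directory (created if needed).
#' @param config An [run_config()] list.
#' @param manifest,annotation,chrom_sizes Raw-track inputs (see above).
#' @param profiles Pre-built per-mark profile matrices (see above).
#' @return Invisibly, a list with the in-memory stage results (`profiles`,
#'   `transactions`, `itemsets`, `biclusters`, `triclusters`) and `outdir`.
#' @export
run_pipeline <- function(outdir, config = run_config(), manifest = NULL,
                         annotation = NULL, chrom_sizes = NULL,
                         profiles = NULL) {
  validate_config(config)
  if (is.null(profiles) == is.null(manifest)) {
    abort("Supply exactly one of `profiles` or `manifest`.")
  }

  if (!is.null(manifest)) {
    manifest <- as_tibble(manifest)
    need <- c("cancer_type", "mark", "path")
    if (!all(need %in% names(manifest))) {
      abort("`manifest` needs columns cancer_type, mark, path.")
    }
    gone <- manifest$path[!file.exists(manifest$path)]
    if (length(gone) > 0) {
      abort(sprintf("Manifest track file(s) not found: %s",
                    paste(gone, collapse = ", ")))
    }
    pairs <- tidyr::expand_grid(cancer_type = unique(manifest$cancer_type),
                                mark = unique(manifest$mark))
    have <- paste(manifest$cancer_type, manifest$mark)
    missing <- pairs[!paste(pairs$cancer_type, pairs$mark) %in% have, ]
    if (nrow(missing) > 0) {
      abort(sprintf("Manifest incomplete; missing (type, mark) pair(s): %s",
                    paste(sprintf("(%s, %s)", missing$cancer_type,
                                  missing$mark), collapse = ", ")))
    }
    if (is.null(annotation) || is.null(chrom_sizes)) {
      abort("Raw-track runs need `annotation` and `chrom_sizes`.")
    }
    sizes <- if (is.character(chrom_sizes)) read_chrom_sizes(chrom_sizes)
      else as_chrom_sizes(chrom_sizes)
    ann <- if (is.character(annotation)) read_annotation(annotation)
      else as_tibble(annotation)
    windows <- promoter_windows(ann, sizes,
                                upstream = config$promoter_upstream,
                                downstream = config$promoter_downstream)
    profiles <- purrr::map(split(manifest, manifest$mark), function(mf) {
      tracks <- purrr::pmap(mf, function(cancer_type, mark, path, ...) {
        read_bedgraph(path) |>
          bin_track(sizes, bin_size = config$bin_size,
                    cancer_type = cancer_type, mark = mark) |>
          normalize_track(scale = config$normalization_scale)
      })
      build_profile_matrix(tracks, windows,
                           cancer_types = unique(manifest$cancer_type))
    })
  }
  if (inherits(profiles, "synthetic_stack")) profiles <- profiles$profiles
  if (length(profiles) < 2) abort("Need profile matrices for at least 2 marks.")

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("profiles", "transactions", "itemsets", "biclusters")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  }

  for (mk in names(profiles)) {
    write_profile_matrix(profiles[[mk]],
                         file.path(outdir, "profiles", paste0(mk, ".tsv")))
  }

  txn <- purrr::map(profiles, build_transactions,
                    corr_threshold = config$corr_threshold,
                    min_profile_sd = config$min_profile_sd)
  for (mk in names(txn)) {
    write_transactions(txn[[mk]],
                       file.path(outdir, "transactions", paste0(mk, ".tsv")))
  }

  itemsets <- purrr::map(txn, mine_frequent_itemsets,
                         min_support = config$min_support,
                         min_size = config$min_types)
  for (mk in names(itemsets)) {
    write_itemsets(itemsets[[mk]], mk,
                   file.path(outdir, "itemsets", paste0(mk, ".tsv")))
  }

  biclusters <- purrr::map2(itemsets, txn, form_biclusters,
                            min_support = config$min_support,
                            mode = config$mode)
  for (mk in names(biclusters)) {
    write_biclusters(biclusters[[mk]],
                     file.path(outdir, "biclusters", paste0(mk, ".tsv")))
  }

  triclusters <- mine_triclusters(txn, min_support = config$min_support,
                                  mode = config$mode,
                                  min_types = config$min_types,
                                  min_marks = config$min_marks)
  write_triclusters(triclusters, file.path(outdir, "triclusters.tsv"))
  write_gene_lists(triclusters, file.path(outdir, "genelists"))

  size_counts <- triclusters |>
    as_tibble() |>
    dplyr::mutate(n_types = lengths(.data$cancer_types),
                  n_marks = lengths(.data$marks)) |>
    dplyr::count(.data$n_types, .data$n_marks, name = "n_clusters")
  jsonlite::write_json(
    list(n_triclusters = nrow(triclusters),
         by_shape = size_counts),
    file.path(outdir, "triclusters_summary.json"),
    auto_unbox = TRUE, digits = NA
  )

  jsonlite::write_json(
    list(
      package = "epitriclust",
      version = as.character(utils::packageVersion("epitriclust")),
      config = unclass(config),
      seed = config$seed,
      counts = list(
        n_genes = length(attr(profiles[[1]], "genes")),
        n_cancer_types = length(attr(profiles[[1]], "cancer_types")),
        n_marks = length(profiles),
        itemsets_per_mark = purrr::map_int(itemsets, nrow),
        biclusters_per_mark = purrr::map_int(biclusters, nrow),
        n_triclusters = nrow(triclusters)
      )
    ),
    file.path(outdir, "provenance.json"), auto_unbox = TRUE, digits = NA
  )

  invisible(list(profiles = profiles, transactions = txn,
                 itemsets = itemsets, biclusters = biclusters,
                 triclusters = triclusters, outdir = outdir))
}
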