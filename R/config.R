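#' Assemble and validate a pipeline configuration
#'
#' Collects every tunable of the pipeline into a single validated list:
#' binning and promoter extraction, depth normalization, the coherence
#' threshold, and the frequent-itemset mining controls. The defaults are the
#' package's reference settings: 200 bp bins, a TSS +/- 2 kb promoter window,
#' a Pearson threshold of 0.7 and a minimum support of 10% of genes.
#'
#' @param bin_size Genomic segment size in bp used for binning signal tracks.
#' @param promoter_upstream,promoter_downstream Promoter window extent in bp
#'   on either side of the TSS (strand-aware). Their sum must be divisible by
#'   `bin_size` so all promoter profiles share one length.
#' @param normalization_scale Reads-per-scale factor of the depth
#'   normalization; bin values become `asinh(value * scale / total_reads)`.
#'   Pearson correlation downstream is insensitive to this constant.
#' @param corr_threshold Pearson coherence threshold `theta` in (-1, 1]; a
#'   cancer-type pair is coherent at a promoter iff `r > theta` (strict).
#' @param min_profile_sd Optional noise floor: promoter profiles with standard
#'   deviation below this never enter coherent pairs. 0 disables the floor
#'   (zero-variance profiles are always excluded).
#' @param min_support Minimum support as a fraction of genes in (0, 1]; the
#'   support count is `ceiling(min_support * n_genes)`.
#' @param min_types Minimum number of cancer types in a mined pattern (>= 2).
#' @param min_marks Minimum number of epigenetic marks in a tri-cluster (>= 2).
#' @param mode `"clique"` (default) requires every type pair of a cluster to
#'   be coherent at each supporting gene; `"loose"` only requires the gene's
#'   transaction to contain the type set. See [form_biclusters()].
#' @param seed Integer seed recorded in provenance and used by any stochastic
#'   step invoked through the pipeline.
#'
#' @return A named list with class `"etc_config"`.
#' @seealso [read_run_config()] to load the same fields from a YAML file.
#' @export
#' @examples
#' cfg <- run_config(corr_threshold = 0.8)
#' cfg$corr_threshold
run_config <- function(bin_size = 200L,
                       promoter_upstream = 2000L,
                       promoter_downstream = 2000L,
                       normalization_scale = 1e7,
                       corr_threshold = 0.7,
                       min_profile_sd = 0,
                       min_support = 0.10,
                       min_types = 2L,
                       min_marks = 2L,
                       mode = c("clique", "loose"),
                       seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(
    bin_size = as.integer(bin_size),
    promoter_upstream = as.integer(promoter_upstream),
    promoter_downstream = as.integer(promoter_downstream),
    normalization_scale = as.numeric(normalization_scale),
    corr_threshold = as.numeric(corr_threshold),
    min_profile_sd = as.numeric(min_profile_sd),
    min_support = as.numeric(min_support),
    min_types = as.integer(min_types),
    min_marks = as.integer(min_marks),
    mode = mode,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "etc_config")
}

validate_config <- function(cfg) {
  if (cfg$bin_size <= 0L) abort("`bin_size` must be a positive integer.")
  if (cfg$promoter_upstream <= 0L || cfg$promoter_downstream <= 0L) {
    abort("Promoter window extents must be positive.")
  }
  win <- cfg$promoter_upstream + cfg$promoter_downstream
  if (win %% cfg$bin_size != 0L) {
    abort(sprintf(
      "Promoter window length (%d bp) must be divisible by bin_size (%d bp).",
      win, cfg$bin_size
    ))
  }
  if (cfg$normalization_scale <= 0) abort("`normalization_scale` must be positive.")
  if (cfg$corr_threshold <= -1 || cfg$corr_threshold > 1) {
    abort("`corr_threshold` must lie in (-1, 1].")
  }
  if (cfg$min_profile_sd < 0) abort("`min_profile_sd` must be non-negative.")
  if (cfg$min_support <= 0 || cfg$min_support > 1) {
    abort("`min_support` must be a fraction in (0, 1].")
  }
  if (cfg$min_types < 2L) abort("`min_types` must be at least 2.")
  if (cfg$min_marks < 2L) abort("`min_marks` must be at least 2.")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so typos fail loudly; absent keys fall back to
#' the [run_config()] defaults.
#'
#' @param path Path to a flat YAML file whose keys match [run_config()]
#'   arguments.
#' @return An `"etc_config"` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(run_config, raw)
}

#' Minimum support count for a transaction database
#'
#' @param min_support Fraction of genes in (0, 1].
#' @param n_genes Number of transactions (genes).
#' @return `ceiling(min_support * n_genes)`, at least 1.
#' @export
min_support_count <- function(min_support, n_genes) {
  if (min_support <= 0 || min_support > 1) {
    abort("`min_support` must be a fraction in (0, 1].")
  }
  max(1L, as.integer(ceiling(min_support * n_genes)))
}
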