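default_params <- function() {
  list(seed = 1L, n_shuffles = 15L, min_frac = 0.1, flank_bp = 1e5,
       universe_bp = 1e6, q_cutoff = 0.05, min_catalog = 100L,
       min_score = 0.7, max_dist = 1e4, threshold_frac = 0.8,
       fdr_method = "BH", min_fraction_with = 0.75,
       promoter_upstream = 5000L, promoter_downstream = 1000L,
       n_components = 2L, log_level = "info")
}

param_ranges <- list(
  n_shuffles = c(1, Inf), min_frac = c(0, 1), flank_bp = c(0, Inf),
  universe_bp = c(0, Inf), q_cutoff = c(0, 1), min_catalog = c(0, Inf),
  min_score = c(0, Inf), max_dist = c(0, Inf), threshold_frac = c(0, 1),
  min_fraction_with = c(0, 1), promoter_upstream = c(0, Inf),
  promoter_downstream = c(0, Inf), n_components = c(1, Inf))

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML config (or takes a list), fills defaults for every
#' unspecified parameter (15 shuffles, 10% minimal overlap, 0/100-kb
#' flanks against a 1-Mb universe, score threshold 0.7, 10-kb proximity,
#' motif hit threshold 0.8), rejects unknown keys, and range-checks
#' values. Normalization is idempotent.
#'
#' @param config Path to a YAML file, or a list. May contain an `inputs`
#'   sub-list of file paths (`chrom_sizes`, `query_peaks`, `catalogs_dir`,
#'   `atac`, `tss`, `re_table`, `re_pairs`, `de_genes`, `motifs`,
#'   `motif_query`, `motif_control`).
#' @return A normalized list of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defaults <- default_params()
  known <- c(names(defaults), "inputs")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, config[setdiff(names(config), "inputs")])
  for (key in names(param_ranges)) {
    r <- param_ranges[[key]]
    v <- out[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < r[1] || v > r[2])
      stop("config value out of range for key '", key, "'")
  }
  if (out$n_shuffles < 1) stop("config value out of range for key 'n_shuffles'")
  if (!out$fdr_method %in% stats::p.adjust.methods)
    stop("config value out of range for key 'fdr_method'")
  out$seed <- as.integer(out$seed)
  out$n_shuffles <- as.integer(out$n_shuffles)
  out$inputs <- config$inputs
  class(out) <- "run_config"
  out
}

pipeline_stages <- c("simulate", "coloc", "annotate", "re-pair",
                     "tf-enrich", "motif-enrich")

log_msg <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message("[chromcoloc] ", ...)
}

# write a data.frame as TSV with a '#' metadata block, atomically
write_stage_tsv <- function(df, path, meta = list()) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, "w")
  for (k in names(meta)) writeLines(paste0("# ", k, "=", meta[[k]]), con)
  close(con)
  suppressWarnings(data.table::fwrite(df, tmp, sep = "\t", append = TRUE,
                                      col.names = TRUE))
  file.rename(tmp, path)
  invisible(path)
}

#' Read a stage TSV (skipping the metadata block)
#' @param path Path to a pipeline output TSV.
#' @return A `data.frame`.
#' @export
read_stage_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  skip = "\t"))
}

require_inputs <- function(config, keys) {
  for (k in keys) {
    p <- config$inputs[[k]]
    if (is.null(p) || !file.exists(p))
      stop("missing input '", k, "' (", if (is.null(p)) "not set" else p, ")")
  }
}

read_catalog_dir <- function(dir, genome) {
  files <- sort(list.files(dir, pattern = "\\.bed$", full.names = TRUE))
  if (length(files) == 0) stop("no catalog BED files in ", dir)
  stats::setNames(lapply(files, read_bed, genome = genome),
                  sub("\\.bed$", "", basename(files)))
}

config_hash <- function(config) {
  flat <- config[setdiff(names(config), "inputs")]
  substr(digest_params(flat), 1, 12)
}

digest_params <- function(x) {
  s <- paste(names(x), vapply(x, function(v) paste(format(v), collapse = ","),
                              ""), sep = "=", collapse = ";")
  # small deterministic hex digest (polynomial rolling hash of the
  # serialized params; doubles stay exact below 2^53)
  h1 <- 0; h2 <- 0
  for (b in utf8ToInt(s)) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

append_manifest <- function(out_dir, stage, config, outputs) {
  sums <- tools::md5sum(outputs)
  names(sums) <- basename(outputs)  # keep the manifest path-independent
  entry <- list(stage = stage, config_hash = config_hash(config),
                seed = config$seed,
                outputs = as.list(sums))
  path <- file.path(out_dir, "run_manifest.jsonl")
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      sep = "", file = path, append = TRUE)
  invisible(entry)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (generate a synthetic dataset and point the config's
#' inputs at it), `coloc` (multi-scale shuffle-null enrichment),
#' `annotate` (feature distribution, TSS-distance bins, open-chromatin
#' fraction), `re-pair` (DE-connected RE selection and peak-proximity
#' split), `tf-enrich` (dual-background TF enrichment, presence matrix,
#' PCA, clustering), `motif-enrich` (PWM fold enrichment). Outputs are
#' written atomically and a `run_manifest.jsonl` entry is appended with
#' the config hash and output checksums.
#'
#' @param stage Stage name.
#' @param config A `run_config` (or anything [validate_config()] accepts).
#' @param out_dir Output directory.
#' @return The (possibly updated) `run_config`, invisibly.
#' @export
run_stage <- function(stage, config, out_dir) {
  if (!stage %in% pipeline_stages)
    stop("unknown stage '", stage, "'; stages: ",
         paste(pipeline_stages, collapse = ", "))
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(config_hash = config_hash(config), seed = config$seed)
  log_msg(config, "stage ", stage)

  if (stage == "simulate") {
    data_dir <- file.path(out_dir, "data")
    generate_dataset(synthetic_spec(seed = config$seed), data_dir)
    config$inputs <- list(
      chrom_sizes = file.path(data_dir, "chrom.sizes"),
      catalogs_dir = file.path(data_dir, "catalogs"),
      query_peaks = file.path(data_dir, "query_peaks.bed"),
      atac = file.path(data_dir, "atac.bed"),
      tss = file.path(data_dir, "tss.bed"),
      re_table = file.path(data_dir, "re_table.tsv"),
      re_pairs = file.path(data_dir, "re_pairs.tsv"),
      de_genes = file.path(data_dir, "de_genes.txt"),
      motifs = file.path(data_dir, "motifs.jaspar"),
      motif_query = file.path(data_dir, "motif_query.fa"),
      motif_control = file.path(data_dir, "motif_control.fa"))
    append_manifest(out_dir, stage, config,
                    file.path(data_dir, "manifest.json"))
    return(invisible(config))
  }

  require_inputs(config, "chrom_sizes")
  genome <- read_chrom_sizes(config$inputs$chrom_sizes)

  if (stage == "coloc") {
    require_inputs(config, c("query_peaks", "catalogs_dir"))
    peaks <- read_bed(config$inputs$query_peaks, genome)
    catalogs <- read_catalog_dir(config$inputs$catalogs_dir, genome)
    cfg <- shuffle_config(n_shuffles = config$n_shuffles, seed = config$seed)
    tab <- multiscale_enrichment(peaks, catalogs, min_frac = config$min_frac,
                                 cfg = cfg, flank_bp = config$flank_bp,
                                 universe_bp = config$universe_bp,
                                 q_cutoff = config$q_cutoff,
                                 min_catalog = config$min_catalog)
    out <- file.path(out_dir, "coloc.tsv")
    write_stage_tsv(tab, out, meta)
    append_manifest(out_dir, stage, config, out)
  } else if (stage == "annotate") {
    require_inputs(config, c("query_peaks", "tss", "atac", "re_table"))
    peaks <- read_bed(config$inputs$query_peaks, genome)
    tss <- read_bed(config$inputs$tss, genome)
    atac <- read_bed(config$inputs$atac, genome)
    res <- read_re_table(config$inputs$re_table, genome)
    feats <- list(
      promoter = make_promoters(tss, config$promoter_upstream,
                                config$promoter_downstream),
      enhancer = merge_intervals(re_granges(res, genome)),
      open_chromatin = merge_intervals(atac))
    dist_tab <- feature_distribution(peaks, feats, genome)
    bins <- table(bin_tss_distance(nearest_tss_distance(peaks, tss)))
    bin_tab <- data.frame(bin = names(bins),
                          n_peaks = as.integer(bins),
                          fraction = as.numeric(bins) / length(peaks))
    oc <- open_chromatin_fraction(peaks, atac, config$max_dist)
    outs <- file.path(out_dir, c("feature_distribution.tsv",
                                 "tss_distance_bins.tsv",
                                 "open_chromatin.tsv"))
    write_stage_tsv(dist_tab, outs[1], meta)
    write_stage_tsv(bin_tab, outs[2], meta)
    write_stage_tsv(data.frame(max_dist = config$max_dist,
                               fraction_near_open_chromatin = oc),
                    outs[3], meta)
    append_manifest(out_dir, stage, config, outs)
  } else if (stage == "re-pair") {
    require_inputs(config, c("re_table", "re_pairs", "de_genes",
                             "query_peaks", "tss"))
    res <- read_re_table(config$inputs$re_table, genome)
    pairs <- read_pairs_table(config$inputs$re_pairs)
    de <- readLines(config$inputs$de_genes)
    peaks <- read_bed(config$inputs$query_peaks, genome)
    tss <- read_bed(config$inputs$tss, genome)
    sel <- select_connected_res(res, pairs, de, config$min_score)
    split <- split_by_proximity(sel, peaks, genome, config$max_dist)
    cov <- compare_covariates(split, tss, genome)
    outs <- file.path(out_dir, c("re_with_peaks.bed", "re_without_peaks.bed",
                                 "re_covariates.tsv", "re_split.tsv"))
    write_bed(re_granges(split$with_peaks, genome), outs[1])
    write_bed(re_granges(split$without_peaks, genome), outs[2])
    write_stage_tsv(cov, outs[3], meta)
    write_stage_tsv(data.frame(group = c("with_peaks", "without_peaks",
                                         "selected_total"),
                               n = c(nrow(split$with_peaks),
                                     nrow(split$without_peaks), nrow(sel))),
                    outs[4], meta)
    append_manifest(out_dir, stage, config, outs)
  } else if (stage == "tf-enrich") {
    require_inputs(config, c("catalogs_dir", "re_table", "re_pairs",
                             "de_genes", "query_peaks"))
    catalogs <- read_catalog_dir(config$inputs$catalogs_dir, genome)
    res <- read_re_table(config$inputs$re_table, genome)
    pairs <- read_pairs_table(config$inputs$re_pairs)
    de <- readLines(config$inputs$de_genes)
    peaks <- read_bed(config$inputs$query_peaks, genome)
    sel <- select_connected_res(res, pairs, de, config$min_score)
    split <- split_by_proximity(sel, peaks, genome, config$max_dist)
    enr <- tf_dual_enrichment(catalogs, split, genome,
                              fdr_method = config$fdr_method)
    tfs <- select_abundant_tfs(enr, config$min_fraction_with)
    outs <- file.path(out_dir, "tf_enrichment.tsv")
    write_stage_tsv(enr, outs, meta)
    if (length(tfs) >= 2 && nrow(split$with_peaks) >= 2) {
      pm <- build_presence_matrix(split$with_peaks, catalogs, tfs, genome)
      if (nrow(pm) >= 2) {
        k <- min(config$n_components, dim(pm))
        pca <- pca_svd_impute(pm, k)
        pm_df <- data.frame(re_id = rownames(pm), pm, check.names = FALSE)
        sc_df <- data.frame(re_id = rownames(pca$scores), pca$scores,
                            check.names = FALSE)
        ld_df <- data.frame(tf = rownames(pca$loadings), pca$loadings,
                            check.names = FALSE)
        ord_rows <- hcluster(pca$imputed, "rows", "euclidean")$order
        ord_cols <- if (ncol(pm) >= 2)
          hcluster(pca$imputed, "cols", "canberra")$order else colnames(pm)
        more <- file.path(out_dir, c("presence_matrix.tsv", "pca_scores.tsv",
                                     "pca_loadings.tsv", "cluster_order.tsv"))
        write_stage_tsv(pm_df, more[1], meta)
        write_stage_tsv(sc_df, more[2], meta)
        write_stage_tsv(ld_df, more[3], meta)
        write_stage_tsv(data.frame(
          axis = c(rep("re", length(ord_rows)), rep("tf", length(ord_cols))),
          label = c(ord_rows, ord_cols)), more[4], meta)
        outs <- c(outs, more)
      }
    }
    append_manifest(out_dir, stage, config, outs)
  } else if (stage == "motif-enrich") {
    require_inputs(config, c("motifs", "motif_query", "motif_control"))
    pwms <- read_jaspar(config$inputs$motifs)
    qs <- Biostrings::readDNAStringSet(config$inputs$motif_query)
    cs <- Biostrings::readDNAStringSet(config$inputs$motif_control)
    tab <- motif_enrichment(qs, cs, pwms, config$threshold_frac)
    out <- file.path(out_dir, "motif_enrichment.tsv")
    write_stage_tsv(tab, out, meta)
    append_manifest(out_dir, stage, config, out)
  }
  invisible(config)
}

#' Run the full pipeline
#'
#' Executes `simulate`, `coloc`, `annotate`, `re-pair`, `tf-enrich` and
#' `motif-enrich` in order from one config, threading the simulated
#' dataset's paths into the later stages.
#'
#' @param config A `run_config` or anything [validate_config()] accepts.
#' @param out_dir Output directory.
#' @return The final `run_config`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  for (stage in pipeline_stages)
    config <- run_stage(stage, config, out_dir)
  invisible(config)
}
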