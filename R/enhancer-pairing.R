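#' Read a regulatory-element table
#'
#' Tab-separated with header `re_id, chrom, start, end, gh_score`
#' (coordinates BED-style 0-based half-open; `gh_score` is the element's
#' confidence score).
#'
#' @param path Path to the TSV.
#' @param genome A `Seqinfo` genome for coordinate validation.
#' @return A `data.frame` with the table columns.
#' @export
read_re_table <- function(path, genome) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("re_id", "chrom", "start", "end", "gh_score")
  if (!all(need %in% names(dt)))
    stop("RE table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(dt$re_id)) stop("re_id values must be unique")
  interval_set(dt$chrom, dt$start, dt$end, genome)  # validates coordinates
  dt[need]
}

#' Read an RE-gene pairs table
#'
#' Tab-separated with header `re_id, gene, pair_score` (the likelihood
#' score of the enhancer-gene pairing).
#'
#' @param path Path to the TSV.
#' @return A `data.frame`.
#' @export
read_pairs_table <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("re_id", "gene", "pair_score")
  if (!all(need %in% names(dt)))
    stop("pairs table must have columns: ", paste(need, collapse = ", "))
  dt[need]
}

# RE table rows as a GRanges, names = re_id
re_granges <- function(res, genome) {
  gr <- interval_set(res$chrom, res$start, res$end, genome, name = res$re_id)
  gr[match(res$re_id, gr$name)]
}

#' Select regulatory elements connected to differentially expressed genes
#'
#' Keeps REs whose score exceeds `min_score` and that are paired to at
#' least one gene on the DE list; gene symbols are compared
#' case-insensitively, and the result is deduplicated by `re_id`.
#'
#' @param res RE table (`data.frame`, see [read_re_table()]).
#' @param pairs Pairs table (`data.frame`, see [read_pairs_table()]).
#' @param de_genes Character vector of differentially expressed gene symbols.
#' @param min_score Score threshold, strict (default 0.7).
#' @return The selected subset of `res`, ordered by `re_id`.
#' @export
select_connected_res <- function(res, pairs, de_genes, min_score = 0.7) {
  unknown <- setdiff(unique(pairs$re_id), res$re_id)
  if (length(unknown) > 0) {
    warning("skipping pairs with unknown re_id: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) " ..." else "")
    pairs <- pairs[pairs$re_id %in% res$re_id, , drop = FALSE]
  }
  de <- unique(toupper(de_genes))
  connected <- unique(pairs$re_id[toupper(pairs$gene) %in% de])
  keep <- res$re_id %in% connected & res$gh_score > min_score
  out <- res[keep, , drop = FALSE]
  out <- out[order(out$re_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split regulatory elements by proximity to peaks
#'
#' Partitions an RE table into elements within `max_dist` bp (edge-to-edge;
#' overlap counts as 0, the cutoff is inclusive) of any peak, and the rest.
#'
#' @param res RE table (`data.frame`).
#' @param peaks `GRanges` of peaks.
#' @param genome A `Seqinfo` genome.
#' @param max_dist Distance cutoff in bp (default 10 kb).
#' @return A list of class `re_split` with `with_peaks`, `without_peaks`
#'   (both `data.frame`s) and `max_dist`.
#' @export
split_by_proximity <- function(res, peaks, genome, max_dist = 1e4) {
  if (nrow(res) == 0) stop("RE table is empty")
  gr <- re_granges(res, genome)
  d <- nearest_tss_distance(gr, peaks)
  near <- d <= max_dist
  structure(list(with_peaks = res[near, , drop = FALSE],
                 without_peaks = res[!near, , drop = FALSE],
                 max_dist = max_dist),
            class = "re_split")
}

#' Compare covariates between the two RE groups
#'
#' For element score, element length, and distance to the nearest TSS,
#' reports group medians and a two-sided Mann-Whitney U p-value, to check
#' that peak-associated and peak-free REs are comparable populations.
#'
#' @param split An `re_split` from [split_by_proximity()].
#' @param tss `GRanges` of TSS positions.
#' @param genome A `Seqinfo` genome.
#' @return A `data.frame` with one row per covariate: `covariate`,
#'   `median_with`, `median_without`, `p_mwu`.
#' @export
compare_covariates <- function(split, tss, genome) {
  if (nrow(split$with_peaks) == 0) stop("group 'with_peaks' is empty")
  if (nrow(split$without_peaks) == 0) stop("group 'without_peaks' is empty")
  vals <- function(res) {
    gr <- re_granges(res, genome)
    list(gh_score = res$gh_score,
         length = res$end - res$start,
         tss_distance = nearest_tss_distance(gr, tss))
  }
  a <- vals(split$with_peaks)
  b <- vals(split$without_peaks)
  rows <- lapply(names(a), function(cv) {
    x <- a[[cv]]; y <- b[[cv]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    p <- if (length(x) == 0 || length(y) == 0) NA_real_ else
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    data.frame(covariate = cv,
               median_with = stats::median(x),
               median_without = stats::median(y),
               p_mwu = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
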