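#' Fisher exact test on a 2x2 interval-overlap table
#'
#' @param n11,n12,n21,n22 Non-negative cell counts.
#' @return A list (`fisher_result`) with the table, the sample odds ratio
#'   (`Inf` allowed) and the two-tailed hypergeometric p-value.
#' @export
fisher_test_table <- function(n11, n12, n21, n22) {
  tab <- matrix(c(n11, n21, n12, n22), nrow = 2)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- (n11 * n22) / (n12 * n21)
  if (is.nan(or)) or <- NA_real_
  structure(list(n11 = n11, n12 = n12, n21 = n21, n22 = n22,
                 odds_ratio = or, p_two_tailed = p),
            class = "fisher_result")
}

#' Fisher exact overlap test between two interval sets
#'
#' Builds the contingency table from interval counts: `n11` query intervals
#' overlapping the other set, `n12` not overlapping, `n21` subject intervals
#' not overlapped, and `n22` estimated as `round(G / Lbar)` minus the other
#' cells, where `G` is the genome length and `Lbar` the mean length of all
#' intervals in both sets (the bedtools-fisher convention). The raw table is
#' returned so the estimate can be audited.
#'
#' @param a,b `GRanges` on a shared genome; `a` is flanked before testing.
#' @param genome A `Seqinfo` genome.
#' @param flank_bp Flank applied to `a` (default 0).
#' @return A `fisher_result` list, see [fisher_test_table()].
#' @export
fisher_overlap <- function(a, b, genome, flank_bp = 0) {
  if (length(a) == 0 || length(b) == 0) stop("both interval sets must be non-empty")
  af <- flank_intervals(a, flank_bp)
  n11 <- sum(IRanges::overlapsAny(af, b, ignore.strand = TRUE))
  n12 <- length(af) - n11
  n_b_hit <- sum(IRanges::overlapsAny(b, af, ignore.strand = TRUE))
  n21 <- length(b) - n_b_hit
  lbar <- mean(c(GenomicRanges::width(af), GenomicRanges::width(b)))
  n22 <- max(0, round(genome_size(genome) / lbar) - n11 - n12 - n21)
  fisher_test_table(n11, n12, n21, n22)
}

#' Distribution of peaks across genomic feature classes
#'
#' For each feature class, the fraction of (flanked) peaks touching the
#' class with at least 1 bp, the fraction of the genome the class covers,
#' their ratio, and a Fisher exact overlap test.
#'
#' @param peaks Non-empty `GRanges` of peaks.
#' @param features Named list of `GRanges`, one per feature class.
#' @param genome A `Seqinfo` genome.
#' @param flank_bp Flank applied to the peaks before overlap (default 0).
#' @return A `data.frame` with one row per class: `feature`,
#'   `fraction_of_peaks`, `fraction_of_genome`, `enrichment_ratio` (`NA`
#'   when both fractions are 0), `fisher_p`, `odds_ratio`.
#' @export
feature_distribution <- function(peaks, features, genome, flank_bp = 0) {
  if (length(peaks) == 0) stop("peaks must be non-empty")
  if (length(features) == 0 || is.null(names(features)))
    stop("features must be a named list of GRanges")
  pf <- flank_intervals(peaks, flank_bp)
  gsize <- genome_size(genome)
  rows <- lapply(names(features), function(nm) {
    f <- features[[nm]]
    frac_peaks <- if (length(f) == 0) 0 else
      mean(IRanges::overlapsAny(pf, f, ignore.strand = TRUE))
    frac_genome <- coverage_bp(f) / gsize
    ratio <- if (frac_genome == 0) {
      if (frac_peaks == 0) NA_real_ else Inf
    } else frac_peaks / frac_genome
    fis <- if (length(f) == 0)
      list(p_two_tailed = NA_real_, odds_ratio = NA_real_)
    else fisher_overlap(pf, f, genome, flank_bp = 0)
    data.frame(feature = nm, fraction_of_peaks = frac_peaks,
               fraction_of_genome = frac_genome, enrichment_ratio = ratio,
               fisher_p = fis$p_two_tailed, odds_ratio = fis$odds_ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build promoter regions around TSS positions
#'
#' Each promoter spans `upstream` bp before and `downstream` bp after the
#' TSS (lower coordinates are upstream; the pipeline is strand-agnostic),
#' clipped to the chromosome and merged.
#'
#' @param tss `GRanges` of 1-bp TSS positions.
#' @param upstream,downstream Pad sizes in bp (defaults 5000 and 1000).
#' @return A merged `GRanges` of promoter blocks.
#' @export
make_promoters <- function(tss, upstream = 5000, downstream = 1000) {
  out <- tss
  IRanges::start(out) <- pmax(1L, GenomicRanges::start(tss) - as.integer(upstream))
  lens <- GenomeInfoDb::seqlengths(out)[as.character(GenomicRanges::seqnames(out))]
  IRanges::end(out) <- pmin(lens, GenomicRanges::end(tss) + as.integer(downstream) - 1L)
  merge_intervals(out)
}

#' Fraction of peaks near open chromatin
#'
#' Fraction of peaks whose edge-to-edge distance to the nearest
#' open-chromatin (ATAC) interval is at most `max_dist` bp; overlap counts
#' as distance 0.
#'
#' @param peaks,atac `GRanges` on a shared genome.
#' @param max_dist Distance cutoff in bp (default 10 kb).
#' @return Numeric fraction in \[0, 1\]; 0 when `atac` is empty.
#' @export
open_chromatin_fraction <- function(peaks, atac, max_dist = 1e4) {
  if (length(peaks) == 0) return(NA_real_)
  if (length(atac) == 0) return(0)
  d <- nearest_tss_distance(peaks, atac)
  mean(d <= max_dist)
}
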