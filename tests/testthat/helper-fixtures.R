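suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

toy_genome <- function(sizes = c(chrA = 10000, chrB = 8000)) {
  make_genome(sizes)
}

# n random intervals with lengths in [1, max_len], BED-style placement
rand_gr <- function(n, genome, max_len = 100) {
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- GenomeInfoDb::seqlengths(genome)
  ch <- sample(chroms, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(lens[[ch[i]]] - len[i] + 1L, 1L) - 1L, 0L)
  interval_set(ch, start, start + len, genome)
}

# BED-style (chrom, start, end) data.frame from a GRanges
bed_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

toy_pwms <- function() {
  read_jaspar(system.file("extdata", "synthetic_motifs.jaspar",
                          package = "chromcoloc"))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

consensus_of <- function(p) {
  paste(c("A", "C", "G", "T")[apply(p$counts, 2, which.max)], collapse = "")
}

revcomp <- function(s) chartr("ACGT", "TGCA",
                              paste(rev(strsplit(s, "")[[1]]), collapse = ""))

# a scaled-down synthetic spec for fast tests
small_spec <- function(seed = 1L, ...) {
  synthetic_spec(
    n_chroms = 2, chrom_length = 2e6,
    tf_specs = data.frame(
      name = c("IRF1_like", "SMAD3_like", "TF_null_1", "TF_null_2"),
      n_sites = 150, site_length = 200, stringsAsFactors = FALSE),
    query_spec = list(n_peaks = 200, peak_length = 400,
                      coloc_targets = data.frame(
                        tf_name = c("IRF1_like", "SMAD3_like"),
                        probability = c(0.6, 0.6),
                        max_offset_bp = c(500, 500),
                        stringsAsFactors = FALSE)),
    atac_spec = list(n_sites = 300, site_length = 500,
                     prox_rate = 0.25, max_dist = 1e4),
    re_spec = list(n_res = 200, length_min = 500, length_max = 3000,
                   score_meanlog = 0.2, score_sdlog = 1,
                   n_genes = 100, de_fraction = 0.25, k_nearest = 3,
                   prox_rate = 0.12, prox_max_dist = 1e4),
    motif_spec = list(pwm_file = system.file("extdata",
                                             "synthetic_motifs.jaspar",
                                             package = "chromcoloc"),
                      planted_motif = "IRF1_like",
                      insertion_rate = 0.3, seq_length = 500,
                      n_query = 50, n_control = 50),
    seed = seed, ...)
}
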