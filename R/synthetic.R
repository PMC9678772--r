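#' Specification for a synthetic chromatin dataset
#'
#' Describes every input the pipeline consumes: a multi-chromosome genome,
#' TF binding-site catalogs, query peaks planted to colocalize with chosen
#' catalogs at stated probabilities, open-chromatin sites planted near a
#' stated fraction of peaks, a regulatory-element table with scores and
#' gene links (a stated fraction of REs placed near peaks), a DE gene list,
#' and motif-bearing sequence sets.
#'
#' Defaults describe the study conditions the package is exercised under:
#' 3 chromosomes of 10 Mb, 8 TF catalogs of 600 x 200-bp sites of which
#' two ("IRF1_like", "SMAD3_like") attract query peaks with probability
#' 0.6 within 500 bp, 1000 peaks of 400 bp, an RE-near-peak rate of 0.12
#' within 10 kb, an ATAC-near-peak rate of 0.25 within 10 kb, and a motif
#' insertion rate of 0.3 in 200 query sequences of 500 bp.
#'
#' @param n_chroms,chrom_length Genome shape.
#' @param tf_specs `data.frame` with columns `name`, `n_sites`,
#'   `site_length`.
#' @param query_spec List: `n_peaks`, `peak_length`, `coloc_targets` (a
#'   `data.frame` with `tf_name`, `probability`, `max_offset_bp`).
#' @param atac_spec List: `n_sites`, `site_length`, `prox_rate`,
#'   `max_dist` (fraction of peaks given a planted nearby site).
#' @param re_spec List: `n_res`, `length_min`, `length_max`, `score_meanlog`,
#'   `score_sdlog`, `n_genes`, `de_fraction`, `k_nearest`, `prox_rate`,
#'   `prox_max_dist`.
#' @param motif_spec List: `pwm_file` (JASPAR text), `planted_motif`
#'   (motif id inserted into query sequences), `insertion_rate`,
#'   `seq_length`, `n_query`, `n_control`.
#' @param seed Integer master seed; all randomness flows from it through
#'   named substreams, one per artifact class.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(
    n_chroms = 3, chrom_length = 1e7,
    tf_specs = data.frame(
      name = c("IRF1_like", "SMAD3_like", paste0("TF_null_", 1:6)),
      n_sites = 600, site_length = 200, stringsAsFactors = FALSE),
    query_spec = list(
      n_peaks = 1000, peak_length = 400,
      coloc_targets = data.frame(
        tf_name = c("IRF1_like", "SMAD3_like"),
        probability = c(0.6, 0.6), max_offset_bp = c(500, 500),
        stringsAsFactors = FALSE)),
    atac_spec = list(n_sites = 2000, site_length = 500,
                     prox_rate = 0.25, max_dist = 1e4),
    re_spec = list(n_res = 1000, length_min = 500, length_max = 5000,
                   score_meanlog = 0.2, score_sdlog = 1,
                   n_genes = 400, de_fraction = 0.25, k_nearest = 3,
                   prox_rate = 0.12, prox_max_dist = 1e4),
    motif_spec = list(pwm_file = system.file("extdata",
                                             "synthetic_motifs.jaspar",
                                             package = "chromcoloc"),
                      planted_motif = "IRF1_like",
                      insertion_rate = 0.3, seq_length = 500,
                      n_query = 200, n_control = 200),
    seed = 1L) {
  probs <- query_spec$coloc_targets$probability
  if (any(probs < 0 | probs > 1)) stop("coloc probabilities must be in [0, 1]")
  if (!all(query_spec$coloc_targets$tf_name %in% tf_specs$name))
    stop("coloc target names must be TF catalog names")
  if (any(tf_specs$site_length > chrom_length) ||
      query_spec$peak_length > chrom_length)
    stop("interval lengths exceed chromosome length")
  structure(list(n_chroms = n_chroms, chrom_length = chrom_length,
                 tf_specs = tf_specs, query_spec = query_spec,
                 atac_spec = atac_spec, re_spec = re_spec,
                 motif_spec = motif_spec, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Derive a deterministic substream seed from the master seed and a label,
# kept inside the 32-bit integer range.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1000003 + h * 7919) %% 2147483647)
}

# n intervals of length len placed uniformly on a genome (vectorized)
random_intervals <- function(n, len, genome, sorted = TRUE) {
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- GenomeInfoDb::seqlengths(genome)
  if (n == 0) return(GenomicRanges::GRanges(seqinfo = genome))
  ch <- sample(chroms, n, replace = TRUE,
               prob = as.numeric(lens) / sum(as.numeric(lens)))
  len <- rep_len(len, n)
  start <- 1L + as.integer(floor(stats::runif(n) * (lens[ch] - len + 1)))
  gr <- GenomicRanges::GRanges(
    ch, IRanges::IRanges(start = start, width = len), seqinfo = genome)
  if (sorted) GenomicRanges::sort(gr) else gr
}

# place intervals of lengths len near anchor intervals (vectors recycled):
# each start is uniform in [anchor_start - max_offset - len + 1,
# anchor_end + max_offset], clipped to the chromosome, so the edge-to-edge
# gap to the anchor is <= max_offset
place_near <- function(anchor_start, anchor_end, len, max_offset, chrom_len) {
  lo <- pmax(1, anchor_start - max_offset - len + 1)
  hi <- pmin(chrom_len - len + 1, anchor_end + max_offset)
  as.integer(lo + floor(stats::runif(length(anchor_start)) * (hi - lo + 1)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample a realization of a PWM column-by-column from its count frequencies
sample_motif_instance <- function(p) {
  freq <- sweep(p$counts, 2, colSums(p$counts), `/`)
  paste(apply(freq, 2, function(f)
    sample(c("A", "C", "G", "T"), 1, prob = f)), collapse = "")
}

#' Generate a complete synthetic dataset
#'
#' Writes every pipeline input to `out_dir` and returns (and writes as
#' `manifest.json`) a manifest recording the spec, the seed, and the
#' planted truth: which peaks were anchored to which TF, which REs and
#' which peaks received planted proximity, and how many query sequences
#' carry an inserted motif. Running twice with the same spec and seed
#' produces byte-identical files.
#'
#' Files written: `chrom.sizes`, `catalogs/<tf>.bed`, `query_peaks.bed`,
#' `atac.bed`, `tss.bed`, `re_table.tsv`, `re_pairs.tsv`, `de_genes.txt`,
#' `motifs.jaspar`, `motif_query.fa`, `motif_control.fa`, `manifest.json`.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly.
#' @export
generate_dataset <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "catalogs"), showWarnings = FALSE)
  genome <- make_genome(stats::setNames(rep(spec$chrom_length, spec$n_chroms),
                                        paste0("chr", seq_len(spec$n_chroms))))
  lens <- GenomeInfoDb::seqlengths(genome)
  write_chrom_sizes(genome, file.path(out_dir, "chrom.sizes"))

  # TF catalogs
  catalogs <- list()
  for (i in seq_len(nrow(spec$tf_specs))) {
    nm <- spec$tf_specs$name[i]
    catalogs[[nm]] <- with_seed(substream_seed(spec$seed, paste0("tf:", nm)), {
      random_intervals(spec$tf_specs$n_sites[i],
                       spec$tf_specs$site_length[i], genome)
    })
    write_bed(catalogs[[nm]], file.path(out_dir, "catalogs",
                                        paste0(nm, ".bed")))
  }

  # query peaks: each peak is flagged for each coloc target independently;
  # if several targets flag it, one is chosen uniformly; the chosen target
  # anchors the peak within max_offset_bp of one of its sites
  qs <- spec$query_spec
  targets <- qs$coloc_targets
  peaks_truth <- with_seed(substream_seed(spec$seed, "peaks"), {
    n <- qs$n_peaks
    flags <- matrix(stats::runif(n * nrow(targets)), n) <
      matrix(targets$probability, n, nrow(targets), byrow = TRUE)
    anchor <- rep("none", n)
    for (k in which(rowSums(flags) > 0)) {
      f <- targets$tf_name[flags[k, ]]
      anchor[k] <- if (length(f) == 1) f else sample(f, 1)
    }
    ch <- character(n); st <- integer(n)
    for (t in seq_len(nrow(targets))) {
      tf <- targets$tf_name[t]
      idx <- which(anchor == tf)
      if (length(idx) == 0) next
      sites <- catalogs[[tf]]
      j <- sample.int(length(sites), length(idx), replace = TRUE)
      ch[idx] <- as.character(GenomicRanges::seqnames(sites))[j]
      st[idx] <- place_near(GenomicRanges::start(sites)[j],
                            GenomicRanges::end(sites)[j], qs$peak_length,
                            targets$max_offset_bp[t], lens[ch[idx]])
    }
    free <- which(anchor == "none")
    if (length(free) > 0) {
      bg <- random_intervals(length(free), qs$peak_length, genome,
                             sorted = FALSE)
      ch[free] <- as.character(GenomicRanges::seqnames(bg))
      st[free] <- GenomicRanges::start(bg)
    }
    list(gr = GenomicRanges::GRanges(
           ch, IRanges::IRanges(start = st, width = qs$peak_length),
           seqinfo = genome),
         anchor = anchor)
  })
  peaks <- GenomicRanges::sort(peaks_truth$gr)
  write_bed(peaks, file.path(out_dir, "query_peaks.bed"))

  # open chromatin: a planted fraction of peaks gets a nearby ATAC site,
  # the rest of the catalog is uniform
  as_ <- spec$atac_spec
  atac <- with_seed(substream_seed(spec$seed, "atac"), {
    n_planted <- round(as_$prox_rate * qs$n_peaks)
    idx <- sample.int(length(peaks), n_planted)
    ch <- as.character(GenomicRanges::seqnames(peaks))[idx]
    st <- place_near(GenomicRanges::start(peaks)[idx],
                     GenomicRanges::end(peaks)[idx], as_$site_length,
                     as_$max_dist, lens[ch])
    planted <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(start = st, width = as_$site_length),
      seqinfo = genome)
    rest <- random_intervals(max(0, as_$n_sites - n_planted),
                             as_$site_length, genome, sorted = FALSE)
    list(gr = GenomicRanges::sort(c(planted, rest)), n_planted = n_planted)
  })
  write_bed(atac$gr, file.path(out_dir, "atac.bed"))

  # genes / TSS / DE list
  rs <- spec$re_spec
  genes <- with_seed(substream_seed(spec$seed, "genes"), {
    tss <- random_intervals(rs$n_genes, 1, genome)
    tss$name <- sprintf("GENE%04d", seq_len(rs$n_genes))
    de <- sort(sample(tss$name, round(rs$de_fraction * rs$n_genes)))
    list(tss = tss, de = de)
  })
  write_bed(genes$tss, file.path(out_dir, "tss.bed"))
  writeLines(genes$de, file.path(out_dir, "de_genes.txt"))

  # regulatory elements: planted fraction near peaks, scored, linked to
  # their k nearest genes with distance-decaying pair scores
  res_truth <- with_seed(substream_seed(spec$seed, "res"), {
    n_planted <- round(rs$prox_rate * rs$n_res)
    near <- c(rep(TRUE, n_planted), rep(FALSE, rs$n_res - n_planted))
    lens_re <- sample(seq(rs$length_min, rs$length_max), rs$n_res,
                      replace = TRUE)
    ch <- character(rs$n_res); st <- integer(rs$n_res)
    if (n_planted > 0) {
      j <- sample.int(length(peaks), n_planted, replace = TRUE)
      ch[near] <- as.character(GenomicRanges::seqnames(peaks))[j]
      st[near] <- place_near(GenomicRanges::start(peaks)[j],
                             GenomicRanges::end(peaks)[j], lens_re[near],
                             rs$prox_max_dist, lens[ch[near]])
    }
    bg <- random_intervals(rs$n_res - n_planted, lens_re[!near], genome,
                           sorted = FALSE)
    ch[!near] <- as.character(GenomicRanges::seqnames(bg))
    st[!near] <- GenomicRanges::start(bg)
    ord <- order(ch, st)
    data.frame(re_id = sprintf("RE%05d", seq_len(rs$n_res)),
               chrom = ch[ord], start = st[ord] - 1L,
               end = st[ord] - 1L + lens_re[ord],
               gh_score = round(stats::rlnorm(rs$n_res, rs$score_meanlog,
                                              rs$score_sdlog), 3),
               planted_near_peak = near[ord], stringsAsFactors = FALSE)
  })
  re_table <- res_truth[, c("re_id", "chrom", "start", "end", "gh_score")]
  data.table::fwrite(re_table, file.path(out_dir, "re_table.tsv"), sep = "\t")

  pairs <- local({
    tss_chrom <- as.character(GenomicRanges::seqnames(genes$tss))
    tss_pos <- GenomicRanges::start(genes$tss)
    mid <- (re_table$start + re_table$end) / 2
    out <- lapply(unique(re_table$chrom), function(c0) {
      gidx <- which(tss_chrom == c0)
      ridx <- which(re_table$chrom == c0)
      if (length(gidx) == 0 || length(ridx) == 0) return(NULL)
      d <- abs(outer(mid[ridx], tss_pos[gidx], "-"))
      take <- t(apply(d, 1, function(row)
        utils::head(order(row, tss_pos[gidx]), rs$k_nearest)))
      k_eff <- ncol(take)
      data.frame(re_id = rep(re_table$re_id[ridx], each = k_eff),
                 gene = genes$tss$name[gidx][as.vector(t(take))],
                 pair_score = round(1 / (1 + d[cbind(rep(seq_along(ridx),
                                                         each = k_eff),
                                                     as.vector(t(take)))] /
                                           1e4), 4),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out[order(out$re_id, -out$pair_score, out$gene), , drop = FALSE]
  })
  data.table::fwrite(pairs, file.path(out_dir, "re_pairs.tsv"), sep = "\t")

  # motif sequence sets
  ms <- spec$motif_spec
  pwms <- read_jaspar(ms$pwm_file)
  file.copy(ms$pwm_file, file.path(out_dir, "motifs.jaspar"),
            overwrite = TRUE)
  motifs <- with_seed(substream_seed(spec$seed, "motifs"), {
    planted <- pwms[[ms$planted_motif]]
    if (is.null(planted)) stop("planted motif not in PWM file: ",
                               ms$planted_motif)
    inserted <- stats::runif(ms$n_query) < ms$insertion_rate
    qseq <- vapply(seq_len(ms$n_query), function(k) {
      s <- random_dna(ms$seq_length)
      if (inserted[k]) {
        inst <- sample_motif_instance(planted)
        at <- sample.int(ms$seq_length - nchar(inst) + 1L, 1L)
        substr(s, at, at + nchar(inst) - 1L) <- inst
      }
      s
    }, "")
    cseq <- vapply(seq_len(ms$n_control), function(k)
      random_dna(ms$seq_length), "")
    list(query = qseq, control = cseq, n_inserted = sum(inserted))
  })
  qset <- Biostrings::DNAStringSet(motifs$query)
  names(qset) <- sprintf("query_%03d", seq_along(qset))
  cset <- Biostrings::DNAStringSet(motifs$control)
  names(cset) <- sprintf("control_%03d", seq_along(cset))
  Biostrings::writeXStringSet(qset, file.path(out_dir, "motif_query.fa"))
  Biostrings::writeXStringSet(cset, file.path(out_dir, "motif_control.fa"))

  manifest <- list(
    seed = spec$seed,
    genome = list(n_chroms = spec$n_chroms, chrom_length = spec$chrom_length),
    tf_catalogs = spec$tf_specs,
    planted = list(
      coloc_targets = targets,
      peak_anchor_counts = as.list(table(peaks_truth$anchor)),
      atac_prox_rate = as_$prox_rate, atac_n_planted = atac$n_planted,
      re_prox_rate = rs$prox_rate,
      re_n_planted = sum(res_truth$planted_near_peak),
      re_planted_ids = res_truth$re_id[res_truth$planted_near_peak],
      motif = ms$planted_motif, motif_insertion_rate = ms$insertion_rate,
      motif_n_inserted = motifs$n_inserted),
    files = list(
      chrom_sizes = "chrom.sizes", catalogs_dir = "catalogs",
      query_peaks = "query_peaks.bed", atac = "atac.bed", tss = "tss.bed",
      re_table = "re_table.tsv", re_pairs = "re_pairs.tsv",
      de_genes = "de_genes.txt", motifs = "motifs.jaspar",
      motif_query = "motif_query.fa", motif_control = "motif_control.fa"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles each sequence while preserving its exact dinucleotide counts
#' (Altschul-Erickson Euler-path shuffle), a standard recipe for building
#' a randomized background from real sequence.
#'
#' @param seqs Character vector (or `DNAStringSet`) of sequences over
#'   A, C, G, T, N.
#' @param seed Integer seed.
#' @return Character vector of shuffled sequences.
#' @export
dinuc_shuffle <- function(seqs, seed = 1L) {
  seqs <- as.character(seqs)
  with_seed(seed, vapply(seqs, dinuc_shuffle_one, "", USE.NAMES = FALSE))
}

# Euler-path shuffle of a single sequence
dinuc_shuffle_one <- function(s) {
  chars <- strsplit(toupper(s), "")[[1]]
  n <- length(chars)
  if (n < 3) return(s)
  verts <- unique(chars)
  from <- chars[-n]
  to <- chars[-1]
  edges <- split(to, factor(from, levels = verts))
  last_v <- chars[n]
  for (attempt in 1:1000) {
    # pick a random terminal edge for every vertex except the path's end
    term <- list()
    ok <- TRUE
    for (v in verts) {
      if (v == last_v || length(edges[[v]]) == 0) next
      term[[v]] <- sample(edges[[v]], 1)
    }
    # chosen terminal edges must form a tree pointing to last_v
    for (v in names(term)) {
      cur <- v; steps <- 0
      while (cur != last_v && steps <= length(verts)) {
        if (is.null(term[[cur]])) { cur <- NA; break }
        cur <- term[[cur]]; steps <- steps + 1
      }
      if (is.na(cur) || steps > length(verts)) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) return(s)  # fully connected failure is not reachable in practice
  # permute the remaining edges, appending each terminal edge last
  pool <- lapply(stats::setNames(verts, verts), function(v) {
    e <- edges[[v]]
    if (!is.null(term[[v]])) {
      i <- match(term[[v]], e)
      e <- e[-i]
    }
    c(if (length(e) > 1) sample(e) else e,
      if (!is.null(term[[v]])) term[[v]])
  })
  out <- character(n)
  out[1] <- chars[1]
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  cur <- chars[1]
  for (i in 2:n) {
    nxt <- pool[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}
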