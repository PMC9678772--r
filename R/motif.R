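#' Construct a position weight matrix object
#'
#' @param motif_id Motif accession/label.
#' @param counts 4 x L non-negative count matrix with rows A, C, G, T.
#' @param background Length-4 background frequencies summing to 1
#'   (default uniform).
#' @param pseudocount Positive pseudocount added to every cell before
#'   normalization (default 0.5).
#' @param name Optional TF name.
#' @return An object of class `pwm`.
#' @export
pwm <- function(motif_id, counts, background = rep(0.25, 4),
                pseudocount = 0.5, name = motif_id) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4) stop("motif width must be >= 4")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) <= 0)) stop("every column must have positive total count")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6)
    stop("background must be 4 frequencies summing to 1")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, name = name, counts = counts,
                 background = stats::setNames(as.numeric(background),
                                              c("A", "C", "G", "T")),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR 2016+ PFM text format: a `>ID NAME` header followed by
#' four rows `A [ counts ]`, `C [...]`, `G [...]`, `T [...]`.
#'
#' @param path Path to the PFM text file.
#' @param background,pseudocount Passed to [pwm()] for every motif.
#' @return A named list of `pwm` objects (names = motif ids).
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.5) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0) stop("no JASPAR records found (missing '>' header)")
  if (starts[1] != 1) stop("file must start with a '>' header")
  out <- list()
  for (k in seq_along(starts)) {
    i <- starts[k]
    j <- if (k < length(starts)) starts[k + 1] - 1 else length(lines)
    body <- lines[(i + 1):j]
    if (length(body) != 4)
      stop("record ", lines[i], " must have exactly 4 count rows, got ",
           length(body))
    hdr <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]]
    id <- hdr[1]
    nm <- if (length(hdr) > 1) hdr[2] else id
    rows <- lapply(body, function(l) {
      nums <- gsub("^[ACGTacgt]\\s*\\[?|\\]$", "", l)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    bases <- toupper(substr(body, 1, 1))
    if (!identical(sort(bases), c("A", "C", "G", "T")))
      stop("record ", id, ": rows must be labelled A, C, G, T")
    counts <- do.call(rbind, rows[order(match(bases, c("A", "C", "G", "T")))])
    out[[id]] <- pwm(id, counts, background = background,
                     pseudocount = pseudocount, name = nm)
  }
  out
}

#' Write PWMs in JASPAR PFM text format
#' @param pwms A list of `pwm` objects.
#' @param path Output path.
#' @export
write_jaspar <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$motif_id, " ", p$name),
      vapply(c("A", "C", "G", "T"), function(b)
        paste0(b, "  [ ", paste(format(p$counts[b, ], trim = TRUE),
                                collapse = " "), " ]"), ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

# Per-position log2-odds score matrix (4 x L) of a pwm
pwm_score_matrix <- function(p) {
  freq <- sweep(p$counts + p$pseudocount, 2,
                colSums(p$counts + p$pseudocount), `/`)
  log2(freq / p$background)
}

#' Maximum (consensus) log-odds score of a PWM
#' @param p A `pwm` object.
#' @return Numeric scalar.
#' @export
pwm_max_score <- function(p) {
  sum(apply(pwm_score_matrix(p), 2, max))
}

#' Scan a sequence with a PWM
#'
#' Scores every window of motif width on both strands with the log2-odds
#' score and reports windows scoring at least `threshold_frac` of the
#' consensus (maximum) score. Windows containing N are skipped. Positions
#' are 0-based starts on the forward strand for both strand hits.
#'
#' @param seq A DNA string over A, C, G, T, N (character or
#'   [Biostrings::DNAString]).
#' @param p A `pwm` object.
#' @param threshold_frac Hit threshold as a fraction of the consensus score
#'   (default 0.8).
#' @return A `data.frame` with `position`, `strand` (`"+"`/`"-"`), `score`;
#'   zero rows when the sequence is shorter than the motif.
#' @export
scan_pwm <- function(seq, p, threshold_frac = 0.8) {
  s <- toupper(as.character(seq))
  L <- ncol(p$counts)
  n <- nchar(s)
  empty <- data.frame(position = integer(0), strand = character(0),
                      score = numeric(0))
  if (n < L) return(empty)
  code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))  # NA for N
  sm <- pwm_score_matrix(p)
  # reverse strand scored with the reverse-complement score matrix
  sm_rc <- sm[4:1, L:1]
  n_win <- n - L + 1
  idx <- outer(seq_len(n_win) - 1L, seq_len(L), `+`)  # windows x positions
  b <- matrix(code[idx], nrow = n_win)
  valid <- rowSums(is.na(b)) == 0
  score_with <- function(mat) {
    cell <- mat[cbind(as.vector(b), rep(seq_len(L), each = n_win))]
    rowSums(matrix(cell, nrow = n_win))
  }
  fwd <- score_with(sm)
  rev_ <- score_with(sm_rc)
  thr <- threshold_frac * pwm_max_score(p)
  hit_f <- which(valid & fwd >= thr)
  hit_r <- which(valid & rev_ >= thr)
  out <- rbind(
    data.frame(position = hit_f - 1L, strand = rep("+", length(hit_f)),
               score = fwd[hit_f]),
    data.frame(position = hit_r - 1L, strand = rep("-", length(hit_r)),
               score = rev_[hit_r]))
  out[order(out$position, out$strand), , drop = FALSE]
}

# valid (N-free) window count of one sequence for a motif width
n_valid_windows <- function(seq, L) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n < L) return(0L)
  code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  isn <- is.na(code)
  if (!any(isn)) return(n - L + 1L)
  bad <- stats::filter(as.numeric(isn), rep(1, L), sides = 1)[L:n]
  sum(bad == 0)
}

#' Motif enrichment of query sequences against a control set
#'
#' Counts hit windows (not sequences) for each PWM in both sets, converts
#' them to rates per kb of scanned windows, and reports the fold enrichment
#' `rate_query / rate_control` (with 0.5 pseudo-hits per set) and a
#' two-sided binomial p-value for the query hit count given the control
#' hit probability.
#'
#' @param query_seqs,control_seqs Character vectors or
#'   [Biostrings::DNAStringSet]s of sequences.
#' @param pwms A list of `pwm` objects.
#' @param threshold_frac Hit threshold, see [scan_pwm()].
#' @return A `data.frame` with one row per motif: `motif_id`,
#'   `n_hits_query`, `n_hits_control`, `rate_query`, `rate_control`
#'   (hits per kb of windows), `fold_enrichment`, `p_value`.
#' @export
motif_enrichment <- function(query_seqs, control_seqs, pwms,
                             threshold_frac = 0.8) {
  qs <- as.character(query_seqs)
  cs <- as.character(control_seqs)
  if (length(qs) == 0 || length(cs) == 0)
    stop("query and control sequence sets must be non-empty")
  rows <- lapply(pwms, function(p) {
    L <- ncol(p$counts)
    nq <- sum(vapply(qs, function(s)
      nrow(scan_pwm(s, p, threshold_frac)), 0L))
    nc <- sum(vapply(cs, function(s)
      nrow(scan_pwm(s, p, threshold_frac)), 0L))
    wq <- sum(vapply(qs, n_valid_windows, 0L, L = L))
    wc <- sum(vapply(cs, n_valid_windows, 0L, L = L))
    rate_q <- (nq + 0.5) / (wq / 1000)
    rate_c <- (nc + 0.5) / (wc / 1000)
    p_ctrl <- min(1, max(.Machine$double.xmin, (nc + 0.5) / wc))
    pv <- stats::binom.test(nq, wq, p = p_ctrl,
                            alternative = "two.sided")$p.value
    data.frame(motif_id = p$motif_id, n_hits_query = nq, n_hits_control = nc,
               rate_query = rate_q, rate_control = rate_c,
               fold_enrichment = rate_q / rate_c, p_value = pv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract interval sequences from a genome FASTA
#'
#' @param gr `GRanges` of intervals.
#' @param fasta A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param flank Symmetric flank in bp, clipped at chromosome ends.
#' @return A `DNAStringSet`, uppercase, in interval order; names are
#'   `chrom:start-end` in BED coordinates.
#' @export
extract_sequences <- function(gr, fasta, flank = 0) {
  seqs <- if (is.character(fasta)) Biostrings::readDNAStringSet(fasta) else fasta
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                     names(seqs))
  if (length(missing) > 0)
    stop("chromosome missing from FASTA: ", paste(missing, collapse = ", "))
  if (flank > 0) gr <- flank_intervals(gr, flank)
  out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    ch <- as.character(GenomicRanges::seqnames(gr))[i]
    toupper(as.character(Biostrings::subseq(
      seqs[[ch]], start = GenomicRanges::start(gr)[i],
      end = GenomicRanges::end(gr)[i])))
  }, ""))
  names(out) <- sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
                        GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  out
}
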