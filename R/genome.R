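#' Construct a genome from chromosome sizes
#'
#' A genome is represented as a [GenomeInfoDb::Seqinfo] object carrying
#' chromosome names and lengths. Every interval set in the package is a
#' [GenomicRanges::GRanges] bound to such a genome, so out-of-bounds
#' coordinates are caught at construction time.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @return A `Seqinfo` object.
#' @export
make_genome <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector of chromosome lengths")
  if (anyDuplicated(names(chrom_sizes)))
    stop("chromosome names must be unique")
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0))
    stop("all chromosome lengths must be positive")
  GenomeInfoDb::Seqinfo(seqnames = names(chrom_sizes),
                        seqlengths = as.integer(chrom_sizes))
}

#' Read a chrom.sizes table
#'
#' Two-column tab-separated file (chromosome name, length in bp), no header.
#'
#' @param path Path to the chrom.sizes file.
#' @return A `Seqinfo` genome.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("chrom.sizes must have two columns: name, length")
  sizes <- as.numeric(dt[[2]])
  names(sizes) <- dt[[1]]
  make_genome(sizes)
}

#' Total genome length in bp
#' @param genome A `Seqinfo` genome.
#' @return Numeric scalar, sum of chromosome lengths.
#' @export
genome_size <- function(genome) {
  sum(as.numeric(GenomeInfoDb::seqlengths(genome)))
}

#' Write a genome as a chrom.sizes file
#' @param genome A `Seqinfo` genome.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  dt <- data.table::data.table(chrom = GenomeInfoDb::seqnames(genome),
                               size = GenomeInfoDb::seqlengths(genome))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Build an interval set from BED-style coordinates
#'
#' Coordinates follow the BED convention: 0-based, half-open `[start, end)`.
#' The returned `GRanges` uses the usual 1-based closed representation
#' internally; all I/O converts back to BED.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, 0-based half-open.
#' @param genome A `Seqinfo` genome the intervals are validated against.
#' @param name,score Optional per-interval label and score.
#' @return A sorted `GRanges`.
#' @export
interval_set <- function(chrom, start, end, genome, name = NULL, score = NULL) {
  if (any(start < 0)) stop("start must be >= 0")
  if (any(end <= start)) stop("interval end must exceed start")
  bad <- !(chrom %in% GenomeInfoDb::seqnames(genome))
  if (any(bad)) stop("unknown chromosome: ", paste(unique(chrom[bad]), collapse = ", "))
  lens <- GenomeInfoDb::seqlengths(genome)[chrom]
  if (any(end > lens)) {
    i <- which(end > lens)[1]
    stop(sprintf("interval %s:%d-%d exceeds chromosome length %d",
                 chrom[i], start[i], end[i], lens[i]))
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start + 1, end = end),
                               seqinfo = genome)
  if (!is.null(name)) gr$name <- name
  if (!is.null(score)) gr$score <- score
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Read a BED file into an interval set
#'
#' BED3+ dialect, tab-separated, no header. Columns beyond the third are
#' kept as `name` (4th) and `score` (5th) where present.
#'
#' @param path Path to the BED file.
#' @param genome A `Seqinfo` genome; coordinates are validated against it.
#' @return A sorted `GRanges` bound to `genome`.
#' @export
read_bed <- function(path, genome) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) return(GenomicRanges::GRanges(seqinfo = genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinates")
  bad <- start >= end | start < 0
  if (any(bad))
    stop("malformed BED line ", which(bad)[1], ": start >= end or negative start")
  name <- if (min(nf) >= 4) vapply(fields, `[[`, "", 4L) else NULL
  score <- if (min(nf) >= 5)
    suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L))) else NULL
  interval_set(chrom, start, end, genome, name = name, score = score)
}

#' Write an interval set as a BED file
#'
#' Emits BED3 (or BED4/BED5 if `name`/`score` metadata columns are present),
#' converting back to 0-based half-open coordinates.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  if (!is.null(gr$name)) {
    dt$name <- gr$name
    if (!is.null(gr$score)) dt$score <- gr$score
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Merge overlapping intervals
#'
#' Intervals sharing at least one nucleotide are unioned into a single
#' interval. Bookended intervals (one ending exactly where the next starts)
#' share zero nucleotides and are kept separate.
#'
#' @param gr A `GRanges`.
#' @return A sorted `GRanges` of disjoint intervals covering the same bases.
#' @export
merge_intervals <- function(gr) {
  GenomicRanges::reduce(gr, min.gapwidth = 0L, ignore.strand = TRUE)
}

#' Extend intervals by a symmetric flank
#'
#' Each interval grows by `pad` bp on both sides and is clipped to its
#' chromosome. The result is not merged; callers decide whether overlaps
#' introduced by flanking should be collapsed.
#'
#' @param gr A `GRanges` with a bound genome (seqlengths set).
#' @param pad Non-negative flank size in bp.
#' @return A `GRanges` of the same length, metadata preserved.
#' @export
flank_intervals <- function(gr, pad) {
  if (length(pad) != 1 || is.na(pad) || pad < 0) stop("pad must be a single value >= 0")
  if (pad == 0) return(gr)
  out <- gr
  IRanges::start(out) <- pmax(1L, GenomicRanges::start(gr) - as.integer(pad))
  lens <- GenomeInfoDb::seqlengths(out)[as.character(GenomicRanges::seqnames(out))]
  IRanges::end(out) <- pmin(lens, GenomicRanges::end(gr) + as.integer(pad))
  out
}

#' Count reciprocal-fraction overlap events
#'
#' A query interval is an overlap event when some catalog interval
#' intersects it and the intersection length reaches `min_frac` of the
#' interval lengths. By default the fraction is required on both the query
#' and the catalog interval; `mode` relaxes this to one side.
#'
#' @param query,catalog `GRanges` on a shared genome.
#' @param min_frac Minimal overlap fraction in \[0, 1\] (default 0.1).
#' @param mode One of `"both"`, `"query"`, `"catalog"`: which interval's
#'   length the fraction is measured against.
#' @return A list with `count` (number of flagged query intervals) and
#'   `flags` (logical per query interval).
#' @export
overlap_events <- function(query, catalog, min_frac = 0.1,
                           mode = c("both", "query", "catalog")) {
  mode <- match.arg(mode)
  if (length(min_frac) != 1 || is.na(min_frac) || min_frac < 0 || min_frac > 1)
    stop("min_frac must be in [0, 1]")
  flags <- logical(length(query))
  if (length(query) > 0 && length(catalog) > 0) {
    hits <- GenomicRanges::findOverlaps(query, catalog, ignore.strand = TRUE)
    if (length(hits) > 0) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      ov <- pmin(GenomicRanges::end(query)[q], GenomicRanges::end(catalog)[s]) -
        pmax(GenomicRanges::start(query)[q], GenomicRanges::start(catalog)[s]) + 1
      ok <- switch(mode,
        both = ov >= min_frac * GenomicRanges::width(query)[q] &
               ov >= min_frac * GenomicRanges::width(catalog)[s],
        query = ov >= min_frac * GenomicRanges::width(query)[q],
        catalog = ov >= min_frac * GenomicRanges::width(catalog)[s])
      flags[unique(q[ok])] <- TRUE
    }
  }
  list(count = sum(flags), flags = flags)
}

#' Distance from each peak to its nearest TSS
#'
#' Unsigned edge-to-edge distance in bp from each peak to the closest TSS on
#' the same chromosome; 0 when a TSS falls inside the peak, `Inf` when the
#' peak's chromosome carries no TSS.
#'
#' @param peaks A `GRanges` of peaks.
#' @param tss A `GRanges` of 1-bp TSS positions.
#' @return Numeric vector of distances, one per peak.
#' @export
nearest_tss_distance <- function(peaks, tss) {
  d <- rep(Inf, length(peaks))
  if (length(peaks) == 0 || length(tss) == 0) return(d)
  hits <- GenomicRanges::distanceToNearest(peaks, tss, ignore.strand = TRUE)
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  d
}

#' Bin TSS distances into the standard report classes
#'
#' Classes: overlap (0), (0, 10 kb\], (10 kb, 100 kb\], (100 kb, 1 Mb\],
#' beyond 1 Mb (including chromosomes with no TSS).
#'
#' @param d Numeric vector of distances from [nearest_tss_distance()].
#' @return Factor with five ordered levels.
#' @export
bin_tss_distance <- function(d) {
  cut(d, breaks = c(-1, 0, 1e4, 1e5, 1e6, Inf),
      labels = c("0", "(0,10kb]", "(10kb,100kb]", "(100kb,1Mb]", ">1Mb"),
      ordered_result = TRUE)
}

#' Total bases covered by an interval set
#'
#' @param gr A `GRanges`; overlaps are collapsed before counting.
#' @return Numeric scalar, covered bp.
#' @export
coverage_bp <- function(gr) {
  sum(as.numeric(GenomicRanges::width(merge_intervals(gr))))
}
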