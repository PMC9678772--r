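#' Shuffle configuration for colocalization nulls
#'
#' Bundles the permutation-null parameters: number of shuffles (default 15,
#' the maximum the enrichment screen uses per dataset), per-chromosome
#' placement, an optional universe restricting where shuffled intervals may
#' land, and the seed.
#'
#' @param n_shuffles Number of shuffled replicates (>= 1; >= 2 for
#'   enrichment, where a null sd is needed).
#' @param by_chrom Keep each shuffled interval on its original chromosome.
#' @param universe Optional `GRanges`; shuffled intervals must lie entirely
#'   inside it. `NULL` means whole chromosomes.
#' @param seed Integer seed driving all shuffling.
#' @return A list of class `shuffle_config`.
#' @export
shuffle_config <- function(n_shuffles = 15, by_chrom = TRUE,
                           universe = NULL, seed = 1L) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  structure(list(n_shuffles = as.integer(n_shuffles),
                 by_chrom = isTRUE(by_chrom),
                 universe = universe,
                 seed = as.integer(seed)),
            class = "shuffle_config")
}

# Run code with a local RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Universe segments per chromosome as a list of (start, end) matrices
# (1-based closed). Falls back to whole chromosomes when universe is NULL.
universe_segments <- function(genome, universe = NULL) {
  chroms <- GenomeInfoDb::seqnames(genome)
  if (is.null(universe)) {
    lens <- GenomeInfoDb::seqlengths(genome)
    segs <- lapply(chroms, function(ch) cbind(start = 1, end = unname(lens[ch])))
  } else {
    u <- merge_intervals(universe)
    segs <- lapply(chroms, function(ch) {
      on_ch <- u[as.character(GenomicRanges::seqnames(u)) == ch]
      cbind(start = GenomicRanges::start(on_ch), end = GenomicRanges::end(on_ch))
    })
  }
  names(segs) <- chroms
  segs
}

# Uniform placement of intervals of given widths into segments, vectorized
# by unique width: each interval picks a segment with probability
# proportional to the number of feasible start positions, then a start
# uniformly within it.
place_uniform <- function(widths, segs, chrom_label) {
  n <- length(widths)
  starts <- integer(n)
  seg_w <- if (nrow(segs) > 0) segs[, "end"] - segs[, "start"] + 1 else integer(0)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    slots <- pmax(0, seg_w - w + 1)
    total <- sum(slots)
    if (total <= 0)
      stop("cannot place interval of length ", w,
           " inside the universe on chromosome ", chrom_label)
    j <- if (nrow(segs) == 1) rep(1L, length(idx)) else
      sample.int(nrow(segs), length(idx), replace = TRUE,
                 prob = slots / total)
    starts[idx] <- as.integer(segs[j, "start"] +
                                floor(stats::runif(length(idx)) * slots[j]))
  }
  starts
}

# Place n_reps independent shuffled replicates of gr in one pass; returns a
# GRanges of length n_reps * length(gr) with a 'rep' metadata column.
shuffle_replicates <- function(gr, cfg, n_reps) {
  genome <- GenomeInfoDb::seqinfo(gr)
  segs <- universe_segments(genome, cfg$universe)
  w <- rep(GenomicRanges::width(gr), n_reps)
  rep_id <- rep(seq_len(n_reps), each = length(gr))
  new_start <- integer(length(w))
  if (cfg$by_chrom) {
    ch <- rep(as.character(GenomicRanges::seqnames(gr)), n_reps)
    for (c0 in unique(ch)) {
      idx <- which(ch == c0)
      new_start[idx] <- place_uniform(w[idx], segs[[c0]], c0)
    }
    new_chrom <- ch
  } else {
    all_segs <- do.call(rbind, segs)
    seg_chrom <- rep(names(segs), vapply(segs, nrow, 0L))
    seg_w <- all_segs[, "end"] - all_segs[, "start"] + 1
    new_chrom <- character(length(w))
    for (w0 in unique(w)) {
      idx <- which(w == w0)
      slots <- pmax(0, seg_w - w0 + 1)
      if (sum(slots) <= 0)
        stop("cannot place interval of length ", w0, " inside the universe")
      j <- sample.int(nrow(all_segs), length(idx), replace = TRUE,
                      prob = slots / sum(slots))
      new_start[idx] <- as.integer(all_segs[j, "start"] +
                                     floor(stats::runif(length(idx)) *
                                             slots[j]))
      new_chrom[idx] <- seg_chrom[j]
    }
  }
  out <- GenomicRanges::GRanges(new_chrom,
                                IRanges::IRanges(start = new_start, width = w),
                                seqinfo = genome)
  out$rep <- rep_id
  out
}

#' Shuffle an interval set under the permutation null
#'
#' Re-places every interval uniformly at random among the feasible start
#' positions of the universe (whole chromosomes when no universe is set),
#' preserving the interval-length multiset and, with `by_chrom`, each
#' interval's chromosome. Shuffled intervals may overlap one another.
#'
#' Uses the current RNG stream; wrap in a seeded context for
#' reproducibility (enrichment functions do this via `cfg$seed`).
#'
#' @param gr A `GRanges` with a bound genome.
#' @param cfg A [shuffle_config()].
#' @return A `GRanges` of the same length.
#' @export
shuffle_intervals <- function(gr, cfg = shuffle_config()) {
  out <- shuffle_replicates(gr, cfg, 1L)
  out$rep <- NULL
  out
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up FDR control valid under arbitrary dependence; more conservative
#' than Benjamini-Hochberg by the harmonic factor `c(m) = sum(1/k)`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in the input order.
#' @export
by_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' Colocalization enrichment against shuffle nulls
#'
#' For each catalog, counts overlap events between the query and the
#' catalog, compares the observed count with its distribution over
#' `n_shuffles` shuffled replicates of the query (the same replicates are
#' reused across catalogs), and reports a z-score, a two-tailed p-value, a
#' Benjamini-Yekutieli q over all catalogs, and a log2 effect
#' `log2((n_obs + 1) / (mean_null + 1))`.
#'
#' The p-value is taken from a Student t distribution with
#' `n_shuffles - 1` degrees of freedom rather than the standard normal:
#' the null sd is itself estimated from the shuffles, and with the usual
#' small shuffle counts (the screen's default is 15) a normal tail is
#' anti-conservative, letting null catalogs reach small q-values by
#' chance. With many shuffles the two coincide.
#'
#' When the null sd is zero the p-value is 1 if the observed count equals
#' the null mean, and otherwise computed with an sd floor of 0.5 events.
#'
#' @param query `GRanges` of query peaks (non-empty).
#' @param catalogs Named list of `GRanges` catalogs.
#' @param min_frac Minimal overlap fraction passed to [overlap_events()].
#' @param cfg A [shuffle_config()] with `n_shuffles >= 2`.
#' @param mode Overlap-fraction mode, see [overlap_events()].
#' @return A `data.frame` with one row per catalog: `catalog`, `n_catalog`,
#'   `n_obs`, `mean_null`, `sd_null`, `z`, `p`, `q_by`, `log2_effect`.
#' @export
coloc_enrichment <- function(query, catalogs, min_frac = 0.1,
                             cfg = shuffle_config(), mode = "both") {
  if (length(query) == 0) stop("query interval set is empty")
  if (length(catalogs) == 0) stop("need at least one catalog")
  if (is.null(names(catalogs)) || any(!nzchar(names(catalogs))))
    stop("catalogs must be a named list")
  if (cfg$n_shuffles < 2) stop("n_shuffles must be >= 2 (null sd undefined)")
  shuffles <- with_seed(cfg$seed,
                        shuffle_replicates(query, cfg, cfg$n_shuffles))
  res <- lapply(names(catalogs), function(nm) {
    cat_gr <- catalogs[[nm]]
    n_obs <- overlap_events(query, cat_gr, min_frac, mode)$count
    null_counts <- replicate_overlap_counts(shuffles, cat_gr, min_frac, mode,
                                            cfg$n_shuffles, length(query))
    m <- mean(null_counts)
    s <- stats::sd(null_counts)
    df <- cfg$n_shuffles - 1
    if (s == 0) {
      if (n_obs == m) { z <- 0; p <- 1 } else {
        z <- (n_obs - m) / 0.5
        p <- 2 * stats::pt(-abs(z), df = df)
      }
    } else {
      z <- (n_obs - m) / s
      p <- 2 * stats::pt(-abs(z), df = df)
    }
    data.frame(catalog = nm, n_catalog = length(cat_gr), n_obs = n_obs,
               mean_null = m, sd_null = s, z = z, p = min(1, p),
               log2_effect = log2((n_obs + 1) / (m + 1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_by <- by_adjust(out$p)
  out[, c("catalog", "n_catalog", "n_obs", "mean_null", "sd_null",
          "z", "p", "q_by", "log2_effect")]
}

# Overlap-event counts of each shuffled replicate against one catalog,
# computed with a single findOverlaps call across all replicates.
replicate_overlap_counts <- function(shuffles, cat_gr, min_frac, mode,
                                     n_reps, n_query) {
  counts <- integer(n_reps)
  if (length(shuffles) == 0 || length(cat_gr) == 0) return(counts)
  hits <- GenomicRanges::findOverlaps(shuffles, cat_gr, ignore.strand = TRUE)
  if (length(hits) == 0) return(counts)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- pmin(GenomicRanges::end(shuffles)[q], GenomicRanges::end(cat_gr)[s]) -
    pmax(GenomicRanges::start(shuffles)[q], GenomicRanges::start(cat_gr)[s]) + 1
  ok <- switch(mode,
    both = ov >= min_frac * GenomicRanges::width(shuffles)[q] &
           ov >= min_frac * GenomicRanges::width(cat_gr)[s],
    query = ov >= min_frac * GenomicRanges::width(shuffles)[q],
    catalog = ov >= min_frac * GenomicRanges::width(cat_gr)[s])
  flagged <- unique(q[ok])  # flagged (replicate, interval) combinations
  if (length(flagged) == 0) return(counts)
  tab <- tabulate(shuffles$rep[flagged], nbins = n_reps)
  as.integer(tab)
}

#' Multi-scale colocalization enrichment
#'
#' Runs the enrichment screen at the three scales of the design:
#' \describe{
#'   \item{flank0}{query as-is, shuffled genome-wide;}
#'   \item{flank100kb}{query extended by 100-kb flanks, shuffled genome-wide;}
#'   \item{universe1Mb}{query as-is, shuffled within the merged 1-Mb
#'     neighborhood of the query peaks (the local background).}
#' }
#' A `selected` column applies the screen's filter: `q_by < 0.05` and
#' catalog size above `min_catalog` sites.
#'
#' @param query `GRanges` of query peaks.
#' @param catalogs Named list of `GRanges` catalogs.
#' @param min_frac Minimal overlap fraction (default 0.1).
#' @param cfg A [shuffle_config()]; its `universe` is ignored (each scale
#'   sets its own).
#' @param flank_bp Flank for the second scale (default 100 kb).
#' @param universe_bp Neighborhood radius for the local universe (default 1 Mb).
#' @param q_cutoff,min_catalog Selection filter (defaults 0.05 and 100).
#' @param mode Overlap-fraction mode (default `"catalog"`): at the flanked
#'   scale the query intervals are orders of magnitude longer than catalog
#'   sites, so requiring the fraction on the query would zero out that
#'   scale by construction; measuring it on the catalog site keeps the 10%
#'   rule meaningful at every scale.
#' @return A `data.frame` of [coloc_enrichment()] rows with `scale` and
#'   `selected` columns.
#' @export
multiscale_enrichment <- function(query, catalogs, min_frac = 0.1,
                                  cfg = shuffle_config(), flank_bp = 1e5,
                                  universe_bp = 1e6, q_cutoff = 0.05,
                                  min_catalog = 100, mode = "catalog") {
  cfg0 <- cfg; cfg0$universe <- NULL
  runs <- list(
    flank0 = coloc_enrichment(query, catalogs, min_frac, cfg0, mode = mode),
    flank100kb = coloc_enrichment(flank_intervals(query, flank_bp),
                                  catalogs, min_frac, cfg0, mode = mode))
  cfg_u <- cfg0
  cfg_u$universe <- merge_intervals(flank_intervals(query, universe_bp))
  runs$universe1Mb <- coloc_enrichment(query, catalogs, min_frac, cfg_u,
                                       mode = mode)
  out <- do.call(rbind, Map(function(tab, sc) {
    tab$scale <- sc
    tab
  }, runs, names(runs)))
  rownames(out) <- NULL
  out$selected <- out$q_by < q_cutoff & out$n_catalog > min_catalog
  out
}
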