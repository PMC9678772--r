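# Independent brute-force oracles, deliberately naive.

# base-wise union of BED intervals on one chromosome -> covered base set
oracle_covered_bases <- function(df, chrom_len) {
  v <- logical(chrom_len)
  for (i in seq_len(nrow(df))) v[(df$start[i] + 1):df$end[i]] <- TRUE
  v
}

# re-segment a coverage bit-vector into maximal runs (BED coords)
oracle_segments <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# merge with the >=1-shared-base rule by a sort-and-sweep independent of
# the package (strict start < current end)
oracle_merge <- function(df) {
  out <- NULL
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    cs <- d$start[1]; ce <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] < ce) ce <- max(ce, d$end[i])
      else { out <- rbind(out, data.frame(chrom = ch, start = cs, end = ce))
             cs <- d$start[i]; ce <- d$end[i] }
    }
    out <- rbind(out, data.frame(chrom = ch, start = cs, end = ce))
  }
  out
}

# nested-loop overlap events with the reciprocal-fraction rule
oracle_overlap_events <- function(q, s, min_frac,
                                  mode = c("both", "query", "catalog")) {
  mode <- match.arg(mode)
  flags <- logical(nrow(q))
  for (i in seq_len(nrow(q))) for (j in seq_len(nrow(s))) {
    if (q$chrom[i] != s$chrom[j]) next
    ov <- min(q$end[i], s$end[j]) - max(q$start[i], s$start[j])
    if (ov <= 0) next
    lq <- q$end[i] - q$start[i]; ls <- s$end[j] - s$start[j]
    hit <- switch(mode,
                  both = ov >= min_frac * lq && ov >= min_frac * ls,
                  query = ov >= min_frac * lq,
                  catalog = ov >= min_frac * ls)
    if (hit) { flags[i] <- TRUE; break }
  }
  list(count = sum(flags), flags = flags)
}

# exhaustive nearest distance (intervening bases) from peaks to points
oracle_nearest <- function(peaks, pts) {
  vapply(seq_len(nrow(peaks)), function(i) {
    same <- pts[pts$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(same) == 0) return(Inf)
    min(vapply(seq_len(nrow(same)), function(j)
      max(0, peaks$start[i] - same$start[j] - 1,
          same$start[j] - peaks$end[i]), 0))
  }, 0)
}

# two-sided Fisher p by full hypergeometric enumeration; tables with
# probability <= observed (up to the usual 1e-7 relative slack) are summed
oracle_fisher_two_sided <- function(n11, n12, n21, n22) {
  m <- n11 + n12; n <- n21 + n22; k <- n11 + n21
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  d_obs <- stats::dhyper(n11, m, n, k)
  sum(probs[probs <= d_obs * (1 + 1e-7)])
}

# Benjamini-Yekutieli by direct formula evaluation
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, ps * m * cm / seq_len(m))
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- q
  out
}

# continuity-corrected chi-square on a 2x2 table
oracle_chisq_yates <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  yates <- min(0.5, abs(tab[1, 1] - E[1, 1]))
  stat <- sum((abs(tab - E) - yates)^2 / E)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

oracle_canberra_pair <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) {
    den <- abs(x[i]) + abs(y[i])
    if (den > 0) s <- s + abs(x[i] - y[i]) / den
  }
  s
}

# per-window PWM log-odds score, one window at a time
oracle_window_score <- function(window, p) {
  freq <- sweep(p$counts + p$pseudocount, 2,
                colSums(p$counts + p$pseudocount), `/`)
  ch <- strsplit(window, "")[[1]]
  if (any(!ch %in% c("A", "C", "G", "T"))) return(NA_real_)
  sum(vapply(seq_along(ch), function(i)
    log2(freq[ch[i], i] / p$background[ch[i]]), 0))
}

oracle_scan <- function(seq, p, threshold_frac) {
  L <- ncol(p$counts)
  n <- nchar(seq)
  thr <- threshold_frac * pwm_max_score(p)
  hits <- NULL
  if (n >= L) for (pos in 0:(n - L)) {
    w <- substr(seq, pos + 1, pos + L)
    sf <- oracle_window_score(w, p)
    if (!is.na(sf) && sf >= thr)
      hits <- rbind(hits, data.frame(position = pos, strand = "+", score = sf))
    sr <- oracle_window_score(revcomp(w), p)
    if (!is.na(sr) && sr >= thr)
      hits <- rbind(hits, data.frame(position = pos, strand = "-", score = sr))
  }
  if (is.null(hits)) data.frame(position = integer(0), strand = character(0),
                                score = numeric(0)) else hits
}

# naive average-linkage agglomeration; returns merge heights and the
# sequence of merged label sets
oracle_average_linkage <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(rownames(d))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < bh - 1e-12) { bh <- h; best <- c(i, j) }
      }
    heights <- c(heights, bh)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges <- c(merges, list(merged))
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, merges = merges)
}

# dinucleotide count table of a sequence
dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  table(paste0(ch[-length(ch)], ch[-1]))
}
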