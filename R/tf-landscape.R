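#' Dual-background TF enrichment over two RE groups
#'
#' For every TF catalog, builds the 2x2 table of REs containing at least
#' one binding site in the peak-associated versus peak-free group, tests it
#' with a continuity-corrected chi-square, adjusts over TFs
#' (Benjamini-Hochberg by default), and reports per-megabase site densities
#' (sites overlapping group REs per Mb of merged group coverage) and their
#' ratio. Optionally adds a genome-background q-value by running the
#' shuffle-null colocalization screen on the peak-associated REs.
#'
#' @param catalogs Named list of `GRanges` TF catalogs.
#' @param split An `re_split` from [split_by_proximity()].
#' @param genome A `Seqinfo` genome.
#' @param fdr_method Multiplicity correction over TFs (default `"BH"`).
#' @param coloc_cfg Optional [shuffle_config()]; when given, a `q_genome`
#'   column from [coloc_enrichment()] of the with-peaks REs is appended.
#' @param min_frac Overlap fraction for the genome-background screen.
#' @return A `data.frame` with one row per TF: counts, totals, densities,
#'   `density_ratio`, `chi2_stat`, `p_chi2`, `q_fdr` (and `q_genome`).
#' @export
tf_dual_enrichment <- function(catalogs, split, genome, fdr_method = "BH",
                               coloc_cfg = NULL, min_frac = 0.1) {
  if (nrow(split$with_peaks) == 0 || nrow(split$without_peaks) == 0)
    stop("both RE groups must be non-empty")
  if (length(catalogs) == 0) stop("need at least one TF catalog")
  gw <- re_granges(split$with_peaks, genome)
  gwo <- re_granges(split$without_peaks, genome)
  cov_w <- coverage_bp(gw) / 1e6
  cov_wo <- coverage_bp(gwo) / 1e6
  if (cov_w == 0 || cov_wo == 0) stop("an RE group has zero coverage")
  nw <- length(gw); nwo <- length(gwo)
  rows <- lapply(names(catalogs), function(tf) {
    sites <- catalogs[[tf]]
    n_with <- sum(IRanges::overlapsAny(gw, sites, ignore.strand = TRUE))
    n_without <- sum(IRanges::overlapsAny(gwo, sites, ignore.strand = TRUE))
    tab <- matrix(c(n_with, nw - n_with, n_without, nwo - n_without), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      # degenerate margin (e.g. TF present in every RE of both groups):
      # no association is testable
      chi <- list(statistic = 0, p.value = 1)
    } else {
      chi <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    }
    d_w <- sum(IRanges::overlapsAny(sites, gw, ignore.strand = TRUE)) / cov_w
    d_wo <- sum(IRanges::overlapsAny(sites, gwo, ignore.strand = TRUE)) / cov_wo
    data.frame(tf = tf, n_with = n_with, n_with_total = nw,
               n_without = n_without, n_without_total = nwo,
               density_with = d_w, density_without = d_wo,
               density_ratio = if (d_wo == 0) {
                 if (d_w == 0) NA_real_ else Inf
               } else d_w / d_wo,
               chi2_stat = unname(chi$statistic), p_chi2 = chi$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_fdr <- stats::p.adjust(out$p_chi2, method = fdr_method)
  if (!is.null(coloc_cfg)) {
    gen <- coloc_enrichment(gw, catalogs, min_frac = min_frac, cfg = coloc_cfg)
    out$q_genome <- gen$q_by[match(out$tf, gen$catalog)]
  }
  out
}

#' Select TFs abundant in the peak-associated RE group
#'
#' Keeps TFs present in strictly more than `min_fraction_with` of the
#' peak-associated REs.
#'
#' @param results `data.frame` from [tf_dual_enrichment()].
#' @param min_fraction_with Abundance cutoff (default 0.75).
#' @return Character vector of TF labels.
#' @export
select_abundant_tfs <- function(results, min_fraction_with = 0.75) {
  if (nrow(results) == 0) stop("results table is empty")
  results$tf[results$n_with / results$n_with_total > min_fraction_with]
}

#' Build a binary RE x TF presence matrix
#'
#' Cell (r, t) is 1 when TF `t` has at least one site overlapping RE `r`.
#' Cells are `NA` (masked) when the TF catalog carries no data at all for
#' the RE's chromosome. Rows with no presence call are dropped; rows and
#' columns are ordered lexicographically.
#'
#' @param res RE table (`data.frame`).
#' @param catalogs Named list of `GRanges` TF catalogs.
#' @param tfs TF labels to include (must be catalog names).
#' @param genome A `Seqinfo` genome.
#' @return A numeric 0/1 matrix (possibly with `NA`s), dimnames set.
#' @export
build_presence_matrix <- function(res, catalogs, tfs, genome) {
  if (!all(tfs %in% names(catalogs)))
    stop("unknown TF: ", paste(setdiff(tfs, names(catalogs)), collapse = ", "))
  tfs <- sort(tfs)
  res <- res[order(res$re_id), , drop = FALSE]
  gr <- re_granges(res, genome)
  m <- matrix(0, nrow = nrow(res), ncol = length(tfs),
              dimnames = list(res$re_id, tfs))
  for (tf in tfs) {
    sites <- catalogs[[tf]]
    m[, tf] <- as.numeric(IRanges::overlapsAny(gr, sites, ignore.strand = TRUE))
    covered <- unique(as.character(GenomicRanges::seqnames(sites)))
    off <- !(res$chrom %in% covered)
    if (any(off)) m[off, tf] <- NA_real_
  }
  keep <- apply(m, 1, function(r) any(r == 1, na.rm = TRUE))
  m[keep, , drop = FALSE]
}

#' PCA with iterative SVD imputation
#'
#' Columns are mean-centered (means over observed cells); missing cells are
#' initialized at the column mean and refined by repeatedly reconstructing
#' the matrix at rank `n_components` from its SVD, until the largest
#' absolute change in an imputed cell drops below `tol` or `max_iter`
#' passes. On a complete matrix the loop is a no-op and the result equals
#' plain centered-SVD PCA. The sign of each component is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param m Numeric matrix, possibly with `NA` cells.
#' @param n_components Number of components (<= min(dim)).
#' @param tol,max_iter Convergence controls (defaults 1e-6 and 100).
#' @return A list with `scores` (n x k), `loadings` (p x k),
#'   `explained_variance` (length k, non-increasing), `imputed` (the
#'   completed centered matrix) and `iterations`.
#' @export
pca_svd_impute <- function(m, n_components, tol = 1e-6, max_iter = 100) {
  m <- as.matrix(m)
  if (n_components < 1 || n_components > min(dim(m)))
    stop("n_components must be in [1, min(dim(m))]")
  obs <- !is.na(m)
  if (any(colSums(obs) == 0)) stop("a column is entirely missing")
  mu <- colMeans(m, na.rm = TRUE)
  x <- sweep(m, 2, mu)
  x[!obs] <- 0  # column mean after centering
  iterations <- 0L
  if (any(!obs)) {
    for (it in seq_len(max_iter)) {
      iterations <- it
      sv <- svd(x, nu = n_components, nv = n_components)
      recon <- sv$u %*% (sv$d[seq_len(n_components)] * t(sv$v))
      delta <- max(abs(recon[!obs] - x[!obs]))
      x[!obs] <- recon[!obs]
      if (delta < tol) break
    }
  }
  sv <- svd(x)
  k <- seq_len(n_components)
  flip <- vapply(k, function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  loadings <- sweep(sv$v[, k, drop = FALSE], 2, flip, `*`)
  scores <- sweep(sv$u[, k, drop = FALSE] %*% diag(sv$d[k], nrow = length(k)),
                  2, flip, `*`)
  rownames(scores) <- rownames(m)
  rownames(loadings) <- colnames(m)
  colnames(scores) <- colnames(loadings) <- paste0("PC", k)
  list(scores = scores, loadings = loadings,
       explained_variance = sv$d[k]^2 / (nrow(m) - 1),
       imputed = x, iterations = iterations)
}

#' Canberra distance matrix
#'
#' `d(x, y) = sum_i |x_i - y_i| / (|x_i| + |y_i|)`, with 0/0 terms
#' contributing 0 (no rescaling of omitted terms). Emphasizes
#' presence/absence differences in sparse binary profiles.
#'
#' @param m Numeric matrix; distances are between rows.
#' @return A `dist` object.
#' @export
canberra_dist <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- abs(m[i, ] - m[j, ])
      den <- abs(m[i, ]) + abs(m[j, ])
      terms <- ifelse(den == 0, 0, num / den)
      d[i, j] <- d[j, i] <- sum(terms, na.rm = TRUE)
    }
  }
  stats::as.dist(structure(d, dimnames = list(rownames(m), rownames(m))))
}

#' Hierarchical clustering of a presence matrix
#'
#' Agglomerative clustering of rows or columns with Euclidean or Canberra
#' distance and average linkage. Ties are broken deterministically by the
#' (lexicographic) label order of the input matrix.
#'
#' @param m Numeric matrix.
#' @param axis `"rows"` or `"cols"`.
#' @param metric `"euclidean"` or `"canberra"`.
#' @param linkage Linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return A list with `order` (labels in dendrogram order), `merge`,
#'   `height` and the underlying `hclust` object.
#' @export
hcluster <- function(m, axis = c("rows", "cols"),
                     metric = c("euclidean", "canberra"),
                     linkage = "average") {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  x <- if (axis == "cols") t(as.matrix(m)) else as.matrix(m)
  if (nrow(x) < 2) stop("need at least 2 items on the chosen axis")
  d <- if (metric == "canberra") canberra_dist(x) else stats::dist(x)
  hc <- stats::hclust(d, method = linkage)
  list(order = rownames(x)[hc$order], merge = hc$merge,
       height = hc$height, hclust = hc)
}
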