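tf_fixture <- function(seed = 51) {
  g <- make_genome(c(chr1 = 2e6, chr2 = 2e6))
  set.seed(seed)
  mk_res <- function(n, prefix) {
    ch <- sample(c("chr1", "chr2"), n, TRUE)
    st <- sample.int(1.9e6, n)
    data.frame(re_id = sprintf("%s%03d", prefix, seq_len(n)), chrom = ch,
               start = st, end = st + 1500, gh_score = 1,
               stringsAsFactors = FALSE)
  }
  with_g <- mk_res(60, "W")
  without_g <- mk_res(80, "N")
  split <- structure(list(with_peaks = with_g, without_peaks = without_g,
                          max_dist = 1e4), class = "re_split")
  # TF "hot" planted preferentially inside with-group REs
  hot_idx <- sample(nrow(with_g), 50)
  hot_sites <- interval_set(with_g$chrom[hot_idx],
                            with_g$start[hot_idx] + 100,
                            with_g$start[hot_idx] + 300, g)
  cold <- rand_gr(80, g, max_len = 200)
  list(g = g, split = split,
       catalogs = list(hot = hot_sites, cold = cold))
}

test_that("chi-square with continuity correction matches the hand formula", {
  tab <- matrix(c(90, 27, 300, 552), nrow = 2, byrow = TRUE)
  got <- suppressWarnings(chisq.test(tab, correct = TRUE))
  orc <- oracle_chisq_yates(tab)
  expect_equal(unname(got$statistic), orc$stat, tolerance = 1e-10)
  expect_equal(got$p.value, orc$p, tolerance = 1e-10)
  set.seed(52)
  for (rep in 1:100) {
    tab <- matrix(rpois(4, sample(c(5, 20, 100), 1)) + 1, nrow = 2)
    got <- suppressWarnings(chisq.test(tab, correct = TRUE))
    orc <- oracle_chisq_yates(tab)
    expect_equal(unname(got$statistic), orc$stat, tolerance = 1e-10)
    expect_equal(got$p.value, orc$p, tolerance = 1e-10)
  }
})

test_that("dual-background enrichment flags the planted TF", {
  fx <- tf_fixture()
  res <- tf_dual_enrichment(fx$catalogs, fx$split, fx$g)
  hot <- res[res$tf == "hot", ]
  cold <- res[res$tf == "cold", ]
  expect_lt(hot$p_chi2, 0.01)
  expect_gt(hot$density_ratio, cold$density_ratio)
  expect_true(all(res$q_fdr >= res$p_chi2))
  # chi-square equals the formula oracle on the emitted counts
  tab <- matrix(c(hot$n_with, hot$n_with_total - hot$n_with,
                  hot$n_without, hot$n_without_total - hot$n_without), 2)
  expect_equal(hot$chi2_stat, oracle_chisq_yates(tab)$stat, tolerance = 1e-10)
  # density arithmetic: sites per Mb of merged group coverage
  gw <- chromcoloc:::re_granges(fx$split$with_peaks, fx$g)
  expect_equal(hot$density_with,
               sum(IRanges::overlapsAny(fx$catalogs$hot, gw)) /
                 (coverage_bp(gw) / 1e6))
  # TF present in every RE of both groups shows no association
  whole1 <- interval_set("chr1", 0, 2e6, fx$g)
  whole2 <- interval_set("chr2", 0, 2e6, fx$g)
  res_all <- tf_dual_enrichment(list(ubiq = c(whole1, whole2)), fx$split, fx$g)
  expect_equal(res_all$p_chi2, 1)
  # optional genome-background q column
  res_g <- tf_dual_enrichment(fx$catalogs, fx$split, fx$g,
                              coloc_cfg = shuffle_config(n_shuffles = 5,
                                                         seed = 2))
  expect_true("q_genome" %in% names(res_g))
  expect_lt(res_g$q_genome[res_g$tf == "hot"], 0.05)
})

test_that("abundance filter applies the strict >75% rule", {
  res <- data.frame(tf = c("a", "b", "c"),
                    n_with = c(88, 87, 117), n_with_total = 117)
  # 88/117 = 0.752 kept; 87/117 = 0.744 dropped
  expect_identical(select_abundant_tfs(res), c("a", "c"))
  set.seed(53)
  for (rep in 1:20) {
    res <- data.frame(tf = letters[1:10],
                      n_with = sample.int(100, 10), n_with_total = 100)
    cut <- runif(1, 0.2, 0.9)
    expect_identical(select_abundant_tfs(res, cut),
                     res$tf[res$n_with / 100 > cut])
  }
})

test_that("presence matrix matches a nested-loop oracle and drops empty rows", {
  fx <- tf_fixture(seed = 54)
  tfs <- names(fx$catalogs)
  pm <- build_presence_matrix(fx$split$with_peaks, fx$catalogs, tfs, fx$g)
  # oracle: per (RE, TF) any-overlap by nested loop
  res <- fx$split$with_peaks
  for (r in rownames(pm)) for (tf in colnames(pm)) {
    row <- res[res$re_id == r, ]
    s <- bed_df(fx$catalogs[[tf]])
    hit <- any(s$chrom == row$chrom & s$start < row$end & s$end > row$start)
    expect_equal(unname(pm[r, tf]), as.numeric(hit))
  }
  expect_true(all(rowSums(pm, na.rm = TRUE) > 0))
  expect_identical(rownames(pm), sort(rownames(pm)))
  expect_identical(colnames(pm), sort(tfs))
  # invariant to catalog ordering
  pm2 <- build_presence_matrix(fx$split$with_peaks, rev(fx$catalogs),
                               rev(tfs), fx$g)
  expect_identical(pm, pm2)
  # masked cells where a catalog has no data for a chromosome
  chr1_only <- fx$catalogs$hot[seqnames(fx$catalogs$hot) == "chr1"]
  pm3 <- build_presence_matrix(fx$split$with_peaks,
                               list(hot = chr1_only, cold = fx$catalogs$cold),
                               c("hot", "cold"), fx$g)
  chr2_res <- res$re_id[res$chrom == "chr2"]
  masked <- intersect(rownames(pm3), chr2_res)
  expect_true(all(is.na(pm3[masked, "hot"])))
})

test_that("PCA with SVD imputation recovers structure", {
  set.seed(55)
  # complete matrix: equals plain centered-SVD PCA
  m <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(paste0("r", 1:20),
                                                    paste0("c", 1:6)))
  pc <- pca_svd_impute(m, 3)
  pr <- prcomp(m, center = TRUE, scale. = FALSE)
  expect_equal(abs(pc$scores), abs(unname(pr$x[, 1:3])), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(pc$explained_variance, unname(pr$sdev[1:3]^2), tolerance = 1e-8)
  expect_equal(pc$iterations, 0L)
  # orthogonal scores, sign convention
  gram <- crossprod(pc$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  for (j in 1:3) {
    v <- pc$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  # full rank conserves total variance
  pc_full <- pca_svd_impute(m, 6)
  expect_equal(sum(pc_full$explained_variance), sum(apply(m, 2, var)),
               tolerance = 1e-8)
  expect_true(all(diff(pc_full$explained_variance) <= 1e-12))

  # rank-1 matrix with 10% masked cells: masked values recovered
  u <- rnorm(30); v <- rnorm(8)
  r1 <- u %*% t(v)
  dimnames(r1) <- list(paste0("r", 1:30), paste0("c", 1:8))
  mask <- matrix(runif(240) < 0.1, 30, 8)
  r1m <- r1; r1m[mask] <- NA
  pc1 <- pca_svd_impute(r1m, 1)
  centered_truth <- sweep(r1, 2, colMeans(r1))
  rmse <- sqrt(mean((pc1$imputed[mask] - centered_truth[mask])^2))
  expect_lt(rmse, 0.05)
  expect_error(pca_svd_impute(r1m, 99), "n_components")
})

test_that("Canberra distance and clustering match brute force", {
  expect_equal(oracle_canberra_pair(c(1, 0), c(0, 1)), 2)
  m <- rbind(x = c(1, 0), y = c(0, 1))
  expect_equal(as.matrix(canberra_dist(m))["x", "y"], 2)
  # 0/0 terms contribute 0 (no rescaling)
  m2 <- rbind(x = c(1, 0, 0), y = c(0, 1, 0))
  expect_equal(as.matrix(canberra_dist(m2))["x", "y"], 2)
  set.seed(56)
  m3 <- matrix(rbinom(10 * 6, 1, 0.4), 10, 6,
               dimnames = list(paste0("r", 1:10), NULL))
  cd <- as.matrix(canberra_dist(m3))
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(cd[i, j], oracle_canberra_pair(m3[i, ], m3[j, ]))

  # identical rows merge first at height 0
  m4 <- rbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(0, 0, 1), d = c(1, 0, 1))
  hc <- hcluster(m4, "rows", "euclidean")
  expect_equal(hc$height[1], 0)
  expect_setequal(rownames(m4)[-hc$merge[1, ]], c("a", "b"))

  # 12-point toy: merge tree equals the naive agglomerative oracle
  set.seed(57)
  m5 <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(letters[1:12], NULL))
  for (metric in c("euclidean", "canberra")) {
    hc <- hcluster(m5, "rows", metric)
    d <- if (metric == "canberra") canberra_dist(m5) else dist(m5)
    orc <- oracle_average_linkage(d)
    expect_equal(hc$height, orc$heights, tolerance = 1e-10)
    # cluster compositions agree at every merge
    labels <- rownames(m5)
    comp <- list()
    for (k in seq_len(nrow(hc$merge))) {
      members <- function(x) if (x < 0) labels[-x] else comp[[x]]
      comp[[k]] <- sort(c(members(hc$merge[k, 1]), members(hc$merge[k, 2])))
      expect_identical(comp[[k]], orc$merges[[k]])
    }
  }
  expect_error(hcluster(m5, "rows", "manhattan"))
  expect_error(hcluster(m5[1, , drop = FALSE], "rows"), "at least 2")
})
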