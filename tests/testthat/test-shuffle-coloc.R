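test_that("shuffling preserves lengths, chromosomes and the universe", {
  g <- toy_genome()
  set.seed(21)
  gr <- rand_gr(50, g, max_len = 150)
  cfg <- shuffle_config(n_shuffles = 5, by_chrom = TRUE)
  for (rep in 1:10) {
    sh <- shuffle_intervals(gr, cfg)
    expect_equal(sort(width(sh)), sort(width(gr)))
    expect_equal(table(as.character(seqnames(sh))),
                 table(as.character(seqnames(gr))))
  }
  # forced placement: interval as long as its chromosome
  g1 <- make_genome(c(c1 = 100))
  one <- interval_set("c1", 0, 100, g1)
  expect_identical(bed_df(shuffle_intervals(one, cfg)),
                   data.frame(chrom = "c1", start = 0L, end = 100L))
  # universe restriction is respected
  uni <- interval_set(c("chrA", "chrB"), c(1000, 2000), c(4000, 7000), g)
  cfg_u <- shuffle_config(universe = uni)
  for (rep in 1:10) {
    sh <- shuffle_intervals(gr, cfg_u)
    ov <- overlap_events(sh, uni, min_frac = 1, mode = "query")
    expect_equal(ov$count, length(sh))
  }
  # infeasible placement names the chromosome
  tiny <- interval_set("chrA", 0, 5000, g)
  cfg_bad <- shuffle_config(universe = interval_set("chrA", 0, 100, g))
  expect_error(shuffle_intervals(tiny, cfg_bad), "chrA")
})

test_that("shuffled start positions are uniform over feasible starts", {
  g <- make_genome(c(c1 = 1000))
  gr <- interval_set("c1", 0, 10, g)
  cfg <- shuffle_config()
  set.seed(22)
  # 10 000 independent replicates of the single 10-bp interval
  reps <- chromcoloc:::shuffle_replicates(gr, cfg, 10000L)
  starts <- start(reps) - 1L
  expect_length(starts, 10000)
  expect_gte(min(starts), 0)
  expect_lte(max(starts), 990)
  obs <- table(factor(starts %/% 100, levels = 0:9))
  p <- chisq.test(obs)$p.value
  expect_gt(p, 0.001)
  # single-call API draws from the same placement rule
  one <- shuffle_intervals(gr, cfg)
  expect_equal(width(one), 10)
})

test_that("Benjamini-Yekutieli adjustment matches the step-up formula", {
  expect_equal(by_adjust(0.05), 0.05)
  p <- c(0.01, 0.04, 0.03)
  expect_equal(by_adjust(p), oracle_by(p), tolerance = 1e-12)
  # hand evaluation with c(3) = 1 + 1/2 + 1/3
  expect_equal(by_adjust(p)[1], 0.01 * 3 * (1 + 1 / 2 + 1 / 3) / 1)
  set.seed(23)
  for (rep in 1:20) {
    p <- runif(sample(2:30, 1))
    q <- by_adjust(p)
    expect_equal(q, oracle_by(p), tolerance = 1e-12)
    expect_true(all(q >= p.adjust(p, "BH") - 1e-15))
    expect_true(all(q >= p & q <= 1))
  }
  expect_error(by_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("self-colocalization is detected on a sparse genome", {
  g <- make_genome(c(chrA = 1e6, chrB = 1e6))
  set.seed(24)
  q <- rand_gr(40, g, max_len = 200)
  res <- coloc_enrichment(q, list(self = q), cfg = shuffle_config(seed = 4))
  expect_equal(res$n_obs, 40)
  expect_lt(res$mean_null, 10)
  expect_gt(res$log2_effect, 0)
  expect_lt(res$p, 1e-6)
  expect_error(coloc_enrichment(GRanges(seqinfo = g), list(self = q)), "empty")
  expect_error(coloc_enrichment(q, list(self = q),
                                cfg = shuffle_config(n_shuffles = 1)),
               "n_shuffles")
})

test_that("the enrichment table is reproducible under a fixed seed", {
  g <- toy_genome()
  set.seed(25)
  q <- rand_gr(30, g, max_len = 100)
  cats <- list(a = rand_gr(40, g), b = rand_gr(40, g))
  cfg <- shuffle_config(seed = 77)
  r1 <- coloc_enrichment(q, cats, cfg = cfg)
  r2 <- coloc_enrichment(q, cats, cfg = cfg)
  expect_identical(r1, r2)
  # and the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(coloc_enrichment(q, cats, cfg = cfg))
  expect_identical(runif(1), before)
})

test_that("planted colocalization separates target from null catalog", {
  g <- make_genome(c(chr1 = 2e6, chr2 = 2e6))
  set.seed(28)
  catA <- rand_gr(150, g, max_len = 200)
  catB <- rand_gr(150, g, max_len = 200)
  # 60% of peaks placed within 500 bp of a catA site
  n <- 200
  near <- runif(n) < 0.6
  j <- sample.int(length(catA), n, replace = TRUE)
  ch <- ifelse(near, as.character(seqnames(catA))[j],
               sample(c("chr1", "chr2"), n, TRUE))
  st <- ifelse(near, pmax(0, start(catA)[j] - 1 + sample(-500:500, n, TRUE)),
               sample.int(2e6 - 200, n, TRUE))
  peaks <- interval_set(ch, st, st + 100, g)
  res <- coloc_enrichment(peaks, list(A = catA, B = catB), min_frac = 0,
                          cfg = shuffle_config(seed = 5))
  expect_lt(res$q_by[res$catalog == "A"], 0.05)
  expect_gt(res$q_by[res$catalog == "B"], 0.05)
  expect_gt(res$log2_effect[res$catalog == "A"],
            res$log2_effect[res$catalog == "B"])
})

test_that("increasing planted colocalization raises the effect size", {
  g <- make_genome(c(chr1 = 2e6))
  set.seed(27)
  cat1 <- rand_gr(100, g, max_len = 200)
  eff <- vapply(c(0.1, 0.5, 0.9), function(pr) {
    set.seed(round(1000 * pr))
    n <- 150
    near <- runif(n) < pr
    j <- sample.int(length(cat1), n, replace = TRUE)
    st <- ifelse(near, pmax(0, start(cat1)[j] - 1 + sample(-300:300, n, TRUE)),
                 sample.int(2e6 - 200, n, TRUE))
    peaks <- interval_set("chr1", st, st + 100, g)
    res <- coloc_enrichment(peaks, list(A = cat1),
                            min_frac = 0, cfg = shuffle_config(seed = 6))
    res$log2_effect
  }, 0)
  expect_true(all(diff(eff) >= 0))
})

test_that("a local universe raises the null mean for clustered catalogs", {
  # catalog sites cluster around the query; genome-wide shuffling lets the
  # query escape the cluster, a 100-kb local universe does not
  g <- make_genome(c(chr1 = 1e7))
  set.seed(28)
  centers <- sort(sample.int(9e6, 20) + 5e5)
  q <- interval_set("chr1", centers, centers + 500, g)
  near_sites <- unlist(lapply(centers, function(cc)
    cc + sample(-5e4:5e4, 10)))
  cat1 <- interval_set("chr1", near_sites, near_sites + 200, g)
  cfg_gw <- shuffle_config(n_shuffles = 10, seed = 9)
  cfg_loc <- shuffle_config(n_shuffles = 10, seed = 9,
                            universe = merge_intervals(flank_intervals(q, 1e5)))
  r_gw <- coloc_enrichment(q, list(A = cat1), min_frac = 0, cfg = cfg_gw)
  r_loc <- coloc_enrichment(q, list(A = cat1), min_frac = 0, cfg = cfg_loc)
  expect_gt(r_loc$mean_null, r_gw$mean_null)
})

test_that("multiscale run reports three scales and applies the filter", {
  g <- make_genome(c(chr1 = 2e6, chr2 = 2e6))
  set.seed(29)
  q <- rand_gr(60, g, max_len = 300)
  cats <- list(big = rand_gr(150, g, max_len = 200),
               small = rand_gr(50, g, max_len = 200),
               self = q)
  tab <- multiscale_enrichment(q, cats, cfg = shuffle_config(seed = 12))
  expect_setequal(unique(tab$scale), c("flank0", "flank100kb", "universe1Mb"))
  expect_equal(nrow(tab), 9)
  # small catalog (n = 50 <= 100) is never selected regardless of q
  expect_false(any(tab$selected[tab$catalog == "small"]))
  # self catalog exceeds 100? no (60) -> also excluded even though q ~ 0
  expect_false(any(tab$selected[tab$catalog == "self"]))
  expect_lt(min(tab$q_by[tab$catalog == "self" & tab$scale == "flank0"]), 0.05)
  # a big significant catalog would pass: emulate by relaxing the cutoff
  tab2 <- multiscale_enrichment(q, cats, cfg = shuffle_config(seed = 12),
                                min_catalog = 10)
  expect_true(any(tab2$selected[tab2$catalog == "self"]))
})
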