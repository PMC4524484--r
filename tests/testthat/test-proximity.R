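test_that("minimum distance follows the endpoint rule", {
  g <- make_genes(100, 200)
  expect_equal(min_site_distance(g, make_sites(150, 400))$distance_bp, 0L)
  expect_equal(min_site_distance(g, make_sites(300, 350))$distance_bp, 100L)
  expect_equal(min_site_distance(g, make_sites(c(10, 500), c(20, 600)))$distance_bp,
               80L)
  # adjacency is distance 1 under the endpoint rule, not 0
  expect_equal(min_site_distance(g, make_sites(201, 250))$distance_bp, 1L)
  expect_error(min_site_distance(g, make_sites(1, 10, chrom = "2L")),
               "no binding sites")
  expect_error(min_site_distance(g, make_sites(integer(), integer())), "empty")
})

test_that("minimum distance equals the brute-force four-endpoint oracle", {
  set.seed(13)
  gs <- sort(sample.int(5e6, 1000))
  genes <- make_genes(gs, gs + sample.int(3000, 1000, replace = TRUE))
  ss <- sort(sample.int(5e6, 1000))
  sites <- make_sites(ss, ss + sample.int(400, 1000, replace = TRUE))
  got <- min_site_distance(genes, sites)$distance_bp
  expect_equal(got, brute_min_distance(genes, sites))
})

test_that("HAS are the merged intersections of MLE and MSL-2 sites", {
  has <- colocalize_has(make_sites(100, 200), make_sites(150, 250))
  expect_equal(has$start, 150L)
  expect_equal(has$end, 200L)
  expect_equal(nrow(colocalize_has(make_sites(100, 200),
                                   make_sites(300, 400))), 0L)
  has2 <- colocalize_has(make_sites(100, 300),
                         make_sites(c(120, 200), c(140, 220)))
  expect_equal(has2$start, c(120L, 200L))
  expect_equal(has2$end, c(140L, 220L))
  expect_warning(out <- colocalize_has(make_sites(integer(), integer()),
                                       make_sites(1, 10)), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("distances to HAS are at least distances to the parent MLE set", {
  set.seed(17)
  ms <- sort(sample.int(1e6, 200)); mle <- make_sites(ms, ms + 300)
  m2 <- sort(sample.int(1e6, 200)); msl2 <- make_sites(m2, m2 + 300, component = "MSL2")
  has <- colocalize_has(mle, msl2)
  skip_if(nrow(has) == 0)
  gs <- sort(sample.int(1e6, 300))
  genes <- make_genes(gs, gs + 1000)
  d_mle <- min_site_distance(genes, mle)$distance_bp
  d_has <- min_site_distance(genes, has)$distance_bp
  expect_true(all(d_has >= d_mle))
})

test_that("Spearman rho handles monotone data, ties, and small n exactly", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)
  # tie-averaged ranks checked against the direct rank formula
  x <- c(1, 2, 3); y <- c(10, 10, 30)
  expect_equal(spearman_rho(x, y)$rho, cor(rank(x), rank(y)))
  # zero variance
  z <- spearman_rho(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(z$rho))
  expect_equal(z$p_value, 1)
  # exact permutation p at n = 5: monotone sequence has p = 2/5!
  ex <- spearman_rho(1:5, c(2, 4, 6, 8, 10))
  expect_equal(ex$p_value, 2 / factorial(5))
  # invariance under strictly monotone transforms
  set.seed(21)
  a <- rnorm(30); b <- rnorm(30)
  r0 <- spearman_rho(a, b)$rho
  expect_equal(spearman_rho(exp(a), b)$rho, r0)
  expect_equal(spearman_rho(a, b^3 + 5 * b)$rho, r0)
})

test_that("rank-sum test matches exact enumeration on small groups", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(5, 6, 7), c(5, 6, 7)), 1)
  # shift invariance
  p1 <- wilcoxon_rank_sum(c(1, 3, 9), c(2, 8, 20))
  p2 <- wilcoxon_rank_sum(c(1, 3, 9) + 100, c(2, 8, 20) + 100)
  expect_equal(p1, p2)
})

test_that("proximity summary joins calls to distances coherently", {
  set.seed(31)
  n <- 60
  gs <- sort(sample.int(2e5, n))
  genes <- make_genes(gs, gs + 500)
  sites <- make_sites(c(1000, 100000), c(1200, 100300))
  d <- min_site_distance(genes, sites)
  rec <- tibble::tibble(
    gene_id = genes$gene_id,
    log2_ratio = rnorm(n),
    call = sample(c("MBG", "UBG", "FBG"), n, replace = TRUE)
  )
  ps <- proximity_summary(rec, d)
  expect_equal(ps$n, n)
  expect_true(abs(ps$rho) <= 1)
  # medians agree with a direct group median
  expect_equal(ps$median_mbg,
               median(d$distance_bp[rec$call == "MBG"]))
  # sign consistency: direction of medians matches the rank-sum direction
  mbg <- d$distance_bp[rec$call == "MBG"]
  ubg <- d$distance_bp[rec$call == "UBG"]
  expect_equal(ps$wilcoxon_p_mbg_vs_ubg, wilcoxon_rank_sum(mbg, ubg))
})

test_that("magnitude-distance profile matches a groupby-median oracle", {
  set.seed(37)
  n <- 80
  rec <- tibble::tibble(
    gene_id = paste0("g", 1:n),
    log2_ratio = runif(n, 0.1, 4),
    call = "MBG"
  )
  d <- tibble::tibble(gene_id = rec$gene_id,
                      distance_bp = sample.int(5e4, n))
  prof <- magnitude_distance_profile(rec, d)
  expect_equal(nrow(prof), 4)
  expect_equal(sum(prof$n), n)
  bins <- magnitude_bin(rec$log2_ratio)
  for (b in levels(bins)) {
    want <- median(d$distance_bp[bins == b])
    got <- prof$median[prof$bin == b]
    if (sum(bins == b) == 0) expect_true(is.na(got)) else expect_equal(got, want)
  }
  # all MBG in one bin -> exactly one nonempty bin
  one <- magnitude_distance_profile(
    tibble::tibble(gene_id = "a", log2_ratio = 0.5, call = "MBG"),
    tibble::tibble(gene_id = "a", distance_bp = 100L))
  expect_equal(sum(one$n > 0), 1)
})
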