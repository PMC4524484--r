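test_that("the generator is fully deterministic under a seed", {
  s1 <- simulate_dataset(sim_config(seed = 5, n_genes = 300))
  s2 <- simulate_dataset(sim_config(seed = 5, n_genes = 300))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$atlas, s2$atlas)
  f1 <- tempfile(); f2 <- tempfile()
  write_genes_gff3(s1$genes, f1)
  write_genes_gff3(s2$genes, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the draw
  s3 <- simulate_dataset(sim_config(seed = 6, n_genes = 300))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("gene placement respects the X fraction and no-overlap rule", {
  g0 <- simulate_genome(sim_config(seed = 2, n_genes = 500, frac_x = 0))
  expect_equal(sum(g0$class == "X"), 0)
  g <- simulate_genome(sim_config(seed = 2, n_genes = 1000, frac_x = 0.16))
  expect_equal(sum(g$class == "X"), 160)
  # no overlap within a chromosome
  for (chr in unique(g$chrom)) {
    sub <- g[g$chrom == chr, ]
    sub <- sub[order(sub$start), ]
    expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
  }
  expect_error(simulate_genome(sim_config(seed = 2, n_genes = 5000,
                                          x_length_bp = 1e4,
                                          autosome_length_bp = 1e4)),
               "cannot fit")
})

test_that("site placement is sorted, disjoint, and scales with density", {
  cfg <- sim_config(seed = 3)
  sites <- simulate_sites(cfg)
  expect_equal(nrow(sites), cfg$n_sites)
  expect_true(all(diff(sites$start) > 0))
  expect_true(all(sites$start[-1] > sites$end[-nrow(sites)]))
  expect_equal(nrow(simulate_sites(sim_config(seed = 3, n_sites = 0))), 0)
  # doubling site density roughly halves the mean nearest distance
  genes <- simulate_genome(cfg)
  xg <- genes[genes$class == "X", ]
  d1 <- mean(min_site_distance(xg, simulate_sites(sim_config(seed = 3, n_sites = 30)))$distance_bp)
  d2 <- mean(min_site_distance(xg, simulate_sites(sim_config(seed = 3, n_sites = 60)))$distance_bp)
  expect_gt(d1 / d2, 1.4)
  expect_lt(d1 / d2, 2.8)
})

test_that("ground truth obeys the overcompensation model", {
  cfg <- sim_config(seed = 7, n_genes = 500)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  expect_true(all(tr$overcomp_multiplier[tr$class == "AUTOSOME"] == 1))
  on_x <- tr$class == "X"
  want <- 1 + cfg$overcomp_amplitude *
    exp(-tr$distance_bp[on_x] / cfg$overcomp_decay_bp)
  expect_equal(tr$overcomp_multiplier[on_x], want)
  # overcompensated male bias stays below 2-fold
  expect_true(all(tr$overcomp_multiplier <= 2))
})

test_that("a null configuration yields a calibrated false-positive rate", {
  cfg <- sim_config(seed = 11, overcomp_amplitude = 0,
                    frac_sex_regulated = 0, n_genes = 1500)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$true_log2fc == 0))
  de <- de_table_from_counts(sim$counts, sim$meta)
  rec <- classify_sex_bias(de, threshold_config("NOMINAL_P", 0.05))
  frac_called <- mean(rec$call %in% c("MBG", "FBG"))
  # nominal dialect: biased calls ~ alpha of expressed genes
  expect_gt(frac_called, 0.02)
  expect_lt(frac_called, 0.09)
  # FDR dialect: essentially no calls under the global null
  rec_fdr <- classify_sex_bias(de, threshold_config("FDR", 0.05))
  expect_lt(sum(rec_fdr$call %in% c("MBG", "FBG")), 5)
})

test_that("estimated fold changes recover the simulated truth", {
  cfg <- sim_config(seed = 13, overcomp_amplitude = 0,
                    frac_sex_regulated = 0.3, sexreg_frac_male = 0.5,
                    n_genes = 2000, n_reps_per_sex = 5)
  sim <- simulate_dataset(cfg)
  de <- de_table_from_counts(sim$counts, sim$meta)
  est <- log2_ratio(de$expr_male, de$expr_female, 1)
  fit <- lm(est ~ sim$truth$true_log2fc)
  slope <- unname(coef(fit)[2])
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("simulation bundles write to standard plain-text files", {
  sim <- simulate_dataset(sim_config(seed = 17, n_genes = 120))
  out <- tempfile()
  write_simulation(sim, out)
  expect_true(all(file.exists(file.path(out, c(
    "genes.gff3", "sites.bed", "counts.tsv", "meta.tsv", "atlas.tsv",
    "truth.tsv")))))
  # the GFF round-trips through the annotation reader
  back <- read_gene_models(file.path(out, "genes.gff3"))
  expect_equal(nrow(back), nrow(sim$genes))
  expect_equal(back[order(back$gene_id), ]$start,
               sim$genes[order(sim$genes$gene_id), ]$start)
  # the BED round-trips through the site reader
  sites <- read_sites_bed(file.path(out, "sites.bed"), "MLE")
  expect_equal(sites$start, sim$sites$start)
  expect_equal(sites$end, sim$sites$end)
})
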