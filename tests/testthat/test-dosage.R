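test_that("RPKM follows the unit construction and is linear", {
  expect_equal(rpkm(1000, 1000, 1e6), 1000)
  expect_equal(rpkm(0, 500, 1e7), 0)
  expect_equal(rpkm(250, 2000, 5e6), 25)
  # linear in reads, inverse in length and library size
  expect_equal(rpkm(500, 1000, 1e6), 2 * rpkm(250, 1000, 1e6))
  expect_equal(rpkm(250, 2000, 1e6), rpkm(250, 1000, 1e6) / 2)
  expect_equal(rpkm(250, 1000, 2e6), rpkm(250, 1000, 1e6) / 2)
  expect_error(rpkm(10, 100, 0), "positive")
  expect_error(rpkm(10, 0, 1e6), ">= 1")
})

test_that("X:A ratio recovers a simulated compensation deficit", {
  # identical distributions -> ratio ~ 1, p large
  set.seed(53)
  ids <- paste0("g", 1:400)
  classes <- tibble::tibble(gene_id = ids,
                            class = rep(c("AUTOSOME", "X"), each = 200))
  vals <- rlnorm(400, meanlog = 3, sdlog = 1)
  expr <- tibble::tibble(gene_id = ids, rpkm = vals)
  same <- xa_expression_ratio(expr, classes, min_rpkm = 0)
  expect_equal(same$ratio_a_over_x, 1, tolerance = 0.35)
  expect_gt(same$wilcoxon_p, 0.05)
  # halving male X expression -> ratio ~ 2 recovered
  halved <- expr
  halved$rpkm[classes$class == "X"] <- halved$rpkm[classes$class == "X"] / 2
  half <- xa_expression_ratio(halved, classes, min_rpkm = 0)
  expect_equal(half$ratio_a_over_x, 2, tolerance = 0.5)
  expect_lt(half$wilcoxon_p, 0.001)
  # medians agree with direct sort-and-pick
  expect_equal(half$median_autosome,
               median(halved$rpkm[classes$class == "AUTOSOME"]))
  # empty class after filtering errors informatively
  expect_error(xa_expression_ratio(expr, classes, min_rpkm = 1e9), "pass")
})

test_that("end-to-end dosage check on simulated uncompensated counts", {
  cfg <- sim_config(seed = 59, male_x_dosage = 0.5, overcomp_amplitude = 0,
                    n_genes = 800)
  sim <- simulate_dataset(cfg)
  lib <- colSums(sim$counts)
  male_cols <- sim$meta$sample[sim$meta$sex == "male"]
  reads <- rowMeans(sim$counts[, male_cols])
  expr <- tibble::tibble(
    gene_id = rownames(sim$counts),
    rpkm = rpkm(reads, sim$genes$exonic_length[match(rownames(sim$counts),
                                                     sim$genes$gene_id)],
                mean(lib[male_cols]))
  )
  res <- xa_expression_ratio(expr, sim$truth, min_rpkm = 0)
  expect_equal(res$ratio_a_over_x, 2, tolerance = 0.5)
})

test_that("component summaries report mean and SEM per replicate set", {
  tab <- tibble::tibble(
    gene_id = rep(c("mle", "msl2"), c(3, 1)),
    sample_id = c("s1", "s2", "s3", "s1"),
    rpkm = c(10, 12, 14, 7)
  )
  out <- component_expression_summary(tab, c(MLE = "mle", MSL2 = "msl2",
                                             MOF = "absent"))
  mle <- out[out$component == "MLE", ]
  expect_equal(mle$mean_rpkm, 12)
  expect_equal(mle$sem, sd(c(10, 12, 14)) / sqrt(3))
  single <- out[out$component == "MSL2", ]
  expect_equal(single$sem, 0)
  expect_false(single$sem_defined)
  expect_equal(out$n[out$component == "MOF"], 0)
  # constant replicates -> SEM 0
  cst <- component_expression_summary(
    tibble::tibble(gene_id = "x", sample_id = c("a", "b"), rpkm = c(5, 5)),
    c(X = "x"))
  expect_equal(cst$sem, 0)
})

test_that("mean age averages known genes only and reports coverage", {
  ages <- tibble::tibble(gene_id = c("a", "b", "c"), age_class = c(6, 6, 5))
  out <- mean_age(c("a", "b", "c", "d"), ages)
  expect_equal(out$mean_age, mean(c(6, 6, 5)))
  expect_equal(out$coverage, 0.75)
  expect_equal(mean_age(c("a", "b"), ages)$mean_age, 6)
  expect_error(mean_age("zz", ages), "known age")
  expect_error(mean_age("a", tibble::tibble(gene_id = "a", age_class = 9)),
               "0..6")
})

test_that("overlap test matches exact hypergeometric enumeration", {
  uni <- paste0("g", 1:20)
  a <- uni[1:5]; b <- uni[c(1, 2, 3, 10, 11)]
  out <- overlap_test(a, b, uni)
  expect_equal(out$n_overlap, 3)
  # exact sum over the upper tail
  want <- sum(dhyper(3:5, 5, 15, 5))
  expect_equal(out$p_value, want, tolerance = 1e-12)
  # disjoint and identical sets
  expect_equal(overlap_test(uni[1:4], uni[5:8], uni)$n_overlap, 0)
  expect_equal(overlap_test(uni[1:4], uni[5:8], uni)$p_value, 1,
               tolerance = 0.01)
  expect_equal(overlap_test(a, a, uni)$n_overlap, 5)
  expect_error(overlap_test(c(a, "zz"), b, uni), "universe")
})

test_that("overlap p agrees with Monte-Carlo resampling", {
  set.seed(61)
  uni <- paste0("g", 1:40)
  a <- uni[1:8]; b <- uni[c(1:4, 20:27)]
  out <- overlap_test(a, b, uni)
  draws <- replicate(1e4, length(intersect(sample(uni, 8), b)))
  mc <- mean(draws >= out$n_overlap)
  se <- sqrt(mc * (1 - mc) / 1e4)
  expect_lt(abs(out$p_value - mc), 3 * se + 1e-6)
})

test_that("remove-and-recompute drops genes from class and totals", {
  calls <- rep(c("MBG", "MBG", "UBG", "UBG"), c(10, 20, 100, 30))
  classes <- rep(c("X", "AUTOSOME", "AUTOSOME", "X"), c(10, 20, 100, 30))
  ids <- paste0("g", seq_along(calls))
  rec <- tibble::tibble(gene_id = ids, call = calls)
  cls <- tibble::tibble(gene_id = ids, class = classes)
  # empty removal set: identity
  same <- remove_and_recompute(rec, cls, character())
  expect_equal(same$counts, class_counts(rec, cls))
  # removing all X-linked MBG zeroes the percentage
  x_mbg <- ids[calls == "MBG" & classes == "X"]
  gone <- remove_and_recompute(rec, cls, x_mbg)
  expect_equal(gone$counts$pct_x[gone$counts$call == "MBG"], 0)
  # recomputation equals a from-scratch run on the reduced universe
  rm_set <- sample(ids, 30)
  a <- remove_and_recompute(rec, cls, rm_set)
  reduced <- rec[!rec$gene_id %in% rm_set, ]
  b <- class_counts(reduced, cls)
  expect_equal(a$counts, b)
  # a removal set disjoint from MBG never changes observed_x for MBG
  ubg_only <- ids[calls == "UBG" & classes == "AUTOSOME"][1:15]
  c_ <- remove_and_recompute(rec, cls, ubg_only)
  expect_equal(
    c_$counts$count_x[c_$counts$call == "MBG"],
    class_counts(rec, cls)$count_x[class_counts(rec, cls)$call == "MBG"]
  )
})
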