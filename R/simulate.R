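# Synthetic-data generator: a small genome (one X, one autosome), DCC
# binding sites on the X, negative-binomial replicate counts per sex with
# known sex effects and a distance-decaying overcompensation signal near
# sites, and a multi-tissue atlas with a tunable specificity spectrum.
# Ground truth is exposed so every pipeline stage can be checked against it.
#
# The count model, per gene g and sample s:
#   log2 mu_gs = baseline_g + [s male] * (true_log2fc_g + log2 m_g)
#   count_gs ~ NB(mean mu_gs * size_factor_s, dispersion phi)
# with variance mu + phi * mu^2. The overcompensation multiplier
# m_g = 1 + a * exp(-d_g / lambda) applies to X-linked genes only (m = 1 on
# autosomes), where d_g is the distance to the nearest DCC site: genes near
# sites have their male expression inflated beyond 2-fold compensation,
# producing weak male bias without any sex-specific regulation. Sex-regulated
# genes are a configurable minority; male-directed effects on the X are
# placed preferentially far from sites (see `sexreg_distance_bias`),
# encoding the idea that DCC binding interferes with further male-specific
# upregulation.

#' Simulation configuration
#'
#' All tunables of the synthetic generator, with defaults chosen to mimic a
#' somatic ("brain-like") bulk RNA-seq comparison: 16% of genes X-linked
#' (the genome-wide X fraction in *D. melanogaster*), moderate
#' overcompensation near DCC sites (`a = 0.35`, i.e. at most 1.35-fold
#' extra male expression, decaying with `lambda = 5` kb) and no
#' sex-regulated genes. See [gonad_like_config()] for the contrasting
#' regime with strong sex-specific regulation far from sites and no
#' overcompensation.
#'
#' @param seed Integer seed; the full output is a deterministic function of
#'   `(seed, config)`.
#' @param n_genes Total number of genes.
#' @param frac_x Fraction of genes on the X chromosome (default 0.16).
#' @param x_length_bp,autosome_length_bp Chromosome lengths.
#' @param n_sites Number of DCC binding sites on the X.
#' @param site_width_bp Width of each site.
#' @param n_reps_per_sex Replicate libraries per sex.
#' @param baseline_log2_mean,baseline_log2_sd Log2-scale distribution of
#'   baseline expression means.
#' @param nb_dispersion Negative-binomial dispersion `phi`
#'   (variance `mu + phi mu^2`); 0.05 is a typical bulk RNA-seq scale.
#' @param frac_sex_regulated Expected fraction of genes with a true sex
#'   effect.
#' @param sexreg_log2fc_mean,sexreg_log2fc_sd Magnitude distribution of
#'   true sex effects (log2 scale).
#' @param sexreg_frac_male Probability that a sex effect is male-directed
#'   (default 0.5; gonad-dominated samples show roughly a 65:35 split in
#'   favour of male-biased genes).
#' @param sexreg_distance_bias Propensity of male-directed effects on the X
#'   to lie far from DCC sites: a candidate X-linked male effect of
#'   magnitude `f` is accepted with weight `q^(bias * f / 2)` where `q` is
#'   the gene's distance quantile among X-linked genes. 0 disables the
#'   bias; larger values push strong male effects away from sites and, as a
#'   side effect, deplete male effects on the X relative to the autosomes
#'   (which carry no sites and are never penalised).
#' @param sexreg_female_near_bias Propensity of female-directed effects on
#'   the X to sit close to DCC sites (the mirror image of the male
#'   pattern). Unlike the male dial this does not change how many X genes
#'   carry female effects: the selected effects are re-hosted among
#'   unregulated X genes with weight `(1 - q)^(bias * f / 2)`, so X
#'   feminization is unaffected. 0 (default) leaves placement uniform.
#' @param overcomp_amplitude Overcompensation amplitude `a >= 0`.
#' @param overcomp_decay_bp Overcompensation decay length `lambda` in bp.
#' @param male_x_dosage Multiplier on male expression of every X-linked
#'   gene (default 1 = complete dosage compensation; 0.5 models a tissue
#'   with a single uncompensated male X, halving male X expression).
#' @param n_tissues Number of atlas tissues.
#' @param specificity_mix Fraction of genes in the tissue-specific atlas
#'   stratum (one dominant tissue) as opposed to the broad stratum.
#' @param size_factors Optional per-sample library-size multipliers
#'   (length `2 * n_reps_per_sex`); `NULL` means equal libraries.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       frac_x = 0.16,
                       x_length_bp = 2e6,
                       autosome_length_bp = 1e7,
                       n_sites = 60L,
                       site_width_bp = 200L,
                       n_reps_per_sex = 5L,
                       baseline_log2_mean = 7,
                       baseline_log2_sd = 2,
                       nb_dispersion = 0.05,
                       frac_sex_regulated = 0,
                       sexreg_log2fc_mean = 2,
                       sexreg_log2fc_sd = 1,
                       sexreg_frac_male = 0.5,
                       sexreg_distance_bias = 0,
                       sexreg_female_near_bias = 0,
                       overcomp_amplitude = 0.35,
                       overcomp_decay_bp = 5000,
                       male_x_dosage = 1,
                       n_tissues = 14L,
                       specificity_mix = 0.3,
                       size_factors = NULL) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              frac_x = frac_x, x_length_bp = x_length_bp,
              autosome_length_bp = autosome_length_bp,
              n_sites = as.integer(n_sites),
              site_width_bp = as.integer(site_width_bp),
              n_reps_per_sex = as.integer(n_reps_per_sex),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              nb_dispersion = nb_dispersion,
              frac_sex_regulated = frac_sex_regulated,
              sexreg_log2fc_mean = sexreg_log2fc_mean,
              sexreg_log2fc_sd = sexreg_log2fc_sd,
              sexreg_frac_male = sexreg_frac_male,
              sexreg_distance_bias = sexreg_distance_bias,
              sexreg_female_near_bias = sexreg_female_near_bias,
              overcomp_amplitude = overcomp_amplitude,
              overcomp_decay_bp = overcomp_decay_bp,
              male_x_dosage = male_x_dosage,
              n_tissues = as.integer(n_tissues),
              specificity_mix = specificity_mix,
              size_factors = size_factors)
  stopifnot(cfg$frac_x >= 0, cfg$frac_x <= 1,
            cfg$x_length_bp > 0, cfg$autosome_length_bp > 0,
            cfg$nb_dispersion > 0, cfg$overcomp_amplitude >= 0,
            cfg$overcomp_decay_bp > 0, cfg$n_reps_per_sex >= 2,
            cfg$specificity_mix >= 0, cfg$specificity_mix <= 1,
            cfg$sexreg_frac_male >= 0, cfg$sexreg_frac_male <= 1,
            cfg$male_x_dosage > 0)
  structure(cfg, class = "sim_config")
}

#' Brain-like simulation regime
#'
#' Overcompensation only: weak male bias arises purely from genes near DCC
#' sites having their male expression inflated beyond 2-fold. The pipeline
#' should recover MBG enriched on the X and a negative correlation between
#' the male/female ratio and site distance.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
brain_like_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, overcomp_amplitude = 0.35,
             overcomp_decay_bp = 5000, frac_sex_regulated = 0, ...)
}

#' Gonad-like simulation regime
#'
#' No overcompensation; 30% of genes carry strong sex-specific regulation
#' (|log2FC| ~ N(2, 1)), with male-directed effects on the X placed far
#' from DCC sites. The pipeline should recover a paucity of X-linked MBG
#' and a positive ratio-vs-distance correlation.
#'
#' @inheritParams brain_like_config
#' @return A `sim_config`.
#' @export
gonad_like_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, overcomp_amplitude = 0,
             frac_sex_regulated = 0.3, sexreg_log2fc_mean = 2,
             sexreg_log2fc_sd = 1, sexreg_frac_male = 0.65,
             sexreg_distance_bias = 2, sexreg_female_near_bias = 2, ...)
}

#' Simulate the gene annotation
#'
#' Places `round(n_genes * frac_x)` genes on the X and the rest on one
#' autosome (named `2L`), uniformly and without overlap. Gene lengths are
#' log-normal on the log2 scale (median ~1.4 kb); each gene is a single
#' transcript with a single exon, so `exonic_length` equals the span.
#'
#' @param cfg A [sim_config()].
#' @return A gene tibble in the format of [read_gene_models()].
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_x <- round(cfg$n_genes * cfg$frac_x)
  n_a <- cfg$n_genes - n_x
  place <- function(n, chrom_len, chrom, id_offset) {
    if (n == 0) {
      return(tibble(gene_id = character(), chrom = character(),
                    start = integer(), end = integer(),
                    strand = character(), exonic_length = integer()))
    }
    len <- pmax(200L, as.integer(round(2^rnorm(n, 10.5, 0.75))))
    free <- chrom_len - sum(len)
    if (free < n + 1) {
      abort("genes cannot fit without overlap; increase chromosome lengths")
    }
    gaps <- diff(c(0, sort(runif(n, 0, free))))
    starts <- as.integer(cumsum(gaps) + c(0, cumsum(len))[seq_len(n)] + 1)
    tibble(
      gene_id = sprintf("g%05d", id_offset + seq_len(n)),
      chrom = chrom,
      start = starts,
      end = starts + len - 1L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      exonic_length = len
    )
  }
  bind_rows(
    place(n_x, cfg$x_length_bp, "X", 0L),
    place(n_a, cfg$autosome_length_bp, "2L", n_x)
  ) |>
    mutate(class = classify_chromosome(.data$chrom)) |>
    select("gene_id", "chrom", "class", "start", "end", "strand",
           "exonic_length")
}

#' Simulate DCC binding sites on the X
#'
#' `n_sites` non-overlapping intervals of fixed width placed uniformly on
#' the X chromosome, sorted by position. `n_sites = 0` yields an empty set
#' (downstream distance operations then error cleanly).
#'
#' @param cfg A [sim_config()].
#' @return A site tibble (`component = "MLE"`, `chrom`, `start`, `end`).
#' @export
simulate_sites <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_sites
  if (n == 0) {
    return(tibble(component = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  w <- cfg$site_width_bp
  free <- cfg$x_length_bp - n * w
  if (free < n + 1) abort("sites cannot fit without overlap on the X")
  gaps <- diff(c(0, sort(runif(n, 0, free))))
  starts <- as.integer(cumsum(gaps) + c(0, cumsum(rep(w, n)))[seq_len(n)] + 1)
  tibble(component = "MLE", chrom = "X", start = starts,
         end = starts + w - 1L)
}

#' Simulate replicate count matrices with known ground truth
#'
#' Draws negative-binomial counts for `2 * n_reps_per_sex` samples under
#' the model described in [sim_config()], and returns the ground truth
#' (true sex effect, overcompensation multiplier, site distance, atlas
#' stratum placeholder) alongside.
#'
#' @param cfg A [sim_config()].
#' @param genome Gene tibble from [simulate_genome()].
#' @param sites Site tibble from [simulate_sites()].
#' @return A list: `counts` (integer matrix genes x samples), `meta`
#'   (tibble `sample`, `sex`), `truth` (tibble per gene).
#' @export
simulate_counts <- function(cfg, genome, sites) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n <- nrow(genome)
  on_x <- genome$class == "X"

  dist_bp <- rep(NA_real_, n)
  if (nrow(sites) > 0 && any(on_x)) {
    d <- min_site_distance(genome[on_x, ], sites)
    dist_bp[on_x] <- d$distance_bp[match(genome$gene_id[on_x], d$gene_id)]
  }

  mult <- rep(1, n)
  if (nrow(sites) > 0) {
    mult[on_x] <- 1 + cfg$overcomp_amplitude *
      exp(-dist_bp[on_x] / cfg$overcomp_decay_bp)
  }

  baseline <- rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)

  # candidate sex effects: magnitude ~ N(mean, sd) clamped at 0; sign
  # male-directed with probability sexreg_frac_male
  mag <- pmax(0, rnorm(n, cfg$sexreg_log2fc_mean, cfg$sexreg_log2fc_sd))
  sgn <- ifelse(runif(n) < cfg$sexreg_frac_male, 1, -1)
  fc_cand <- mag * sgn

  w <- rep(1, n)
  if (cfg$sexreg_distance_bias > 0 && nrow(sites) > 0) {
    male_x <- on_x & fc_cand > 0
    if (any(male_x)) {
      q <- rank(dist_bp[on_x]) / sum(on_x)
      names(q) <- genome$gene_id[on_x]
      qx <- q[genome$gene_id[male_x]]
      w[male_x] <- qx^(cfg$sexreg_distance_bias * fc_cand[male_x] / 2)
    }
  }
  p_sel <- if (cfg$frac_sex_regulated > 0) {
    pmin(1, cfg$frac_sex_regulated * w / mean(w))
  } else {
    rep(0, n)
  }
  selected <- runif(n) < p_sel
  true_fc <- ifelse(selected, fc_cand, 0)

  # re-host female-directed X effects near sites (placement only; the
  # number of regulated X genes is unchanged)
  if (cfg$sexreg_female_near_bias > 0 && nrow(sites) > 0 && any(on_x)) {
    q_all <- rep(NA_real_, n)
    q_all[on_x] <- rank(dist_bp[on_x]) / sum(on_x)
    movers <- which(on_x & selected & true_fc < 0)
    pool <- which(on_x & !selected)
    for (i in movers) {
      avail <- c(i, pool)
      wts <- (1 - q_all[avail] + 1e-9)^(cfg$sexreg_female_near_bias *
                                          abs(true_fc[i]) / 2)
      host <- avail[sample.int(length(avail), 1, prob = wts)]
      if (host != i) {
        true_fc[host] <- true_fc[i]
        selected[host] <- TRUE
        true_fc[i] <- 0
        selected[i] <- FALSE
        pool <- c(setdiff(pool, host), i)
      }
    }
  }

  reps <- cfg$n_reps_per_sex
  sex <- rep(c("male", "female"), each = reps)
  sample_ids <- paste0(sex, "_", rep(seq_len(reps), 2))
  sf <- cfg$size_factors %||% rep(1, 2 * reps)
  stopifnot(length(sf) == 2 * reps)

  dosage <- ifelse(on_x, log2(cfg$male_x_dosage), 0)
  log2_mu <- outer(baseline, rep(1, 2 * reps)) +
    outer(true_fc + log2(mult) + dosage, as.numeric(sex == "male"))
  mu <- sweep(2^log2_mu, 2, sf, `*`)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow = n, dimnames = list(genome$gene_id, sample_ids))

  list(
    counts = counts,
    meta = tibble(sample = sample_ids, sex = sex, strain = "sim"),
    truth = tibble(
      gene_id = genome$gene_id, chrom = genome$chrom, class = genome$class,
      baseline_log2 = baseline, sex_regulated = selected,
      true_log2fc = true_fc, distance_bp = dist_bp,
      overcomp_multiplier = mult
    )
  )
}

#' Simulate a multi-tissue expression atlas
#'
#' Each gene is assigned to the broad stratum (a flat Dirichlet profile
#' across tissues) or the specific stratum (all expression in one randomly
#' chosen tissue) with probability `specificity_mix`; the profile is scaled
#' by a log-normal overall level. The tau index should separate the two
#' strata cleanly.
#'
#' @param cfg A [sim_config()].
#' @param genome Gene tibble.
#' @return A list: `atlas` (genes x tissues matrix), `strata` (tibble
#'   `gene_id`, `stratum`).
#' @export
simulate_atlas <- function(cfg, genome) {
  stopifnot(inherits(cfg, "sim_config"), cfg$n_tissues >= 2)
  set.seed(cfg$seed + 3L)
  n <- nrow(genome)
  k <- cfg$n_tissues
  specific <- runif(n) < cfg$specificity_mix
  # near-uniform Dirichlet(50) profiles for the broad stratum, so broad
  # genes land in the housekeeping range (tau < 0.4)
  prof <- matrix(stats::rgamma(n * k, shape = 50), nrow = n)
  prof <- prof / rowSums(prof)
  hot <- sample.int(k, n, replace = TRUE)
  prof[specific, ] <- 0
  prof[cbind(which(specific), hot[specific])] <- 1
  level <- 2^rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  atlas <- prof * level * k
  rownames(atlas) <- genome$gene_id
  colnames(atlas) <- paste0("tissue_", seq_len(k))
  list(atlas = atlas,
       strata = tibble(gene_id = genome$gene_id,
                       stratum = ifelse(specific, "specific", "broad")))
}

#' Simulate a complete data set
#'
#' Runs [simulate_genome()], [simulate_sites()], [simulate_counts()] and
#' [simulate_atlas()] under one seed lineage and returns the bundle.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `xbias_simulation`: `config`, `genes`, `sites`,
#'   `counts`, `meta`, `truth`, `atlas`, `strata`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  genes <- simulate_genome(cfg)
  sites <- simulate_sites(cfg)
  cm <- simulate_counts(cfg, genes, sites)
  at <- simulate_atlas(cfg, genes)
  structure(
    list(config = cfg, genes = genes, sites = sites, counts = cm$counts,
         meta = cm$meta, truth = cm$truth, atlas = at$atlas,
         strata = at$strata),
    class = "xbias_simulation"
  )
}

#' Write simulated gene models as GFF3
#'
#' Emits one `gene`, one `mRNA` and one `exon` feature per gene with
#' ID/Parent links, so the file round-trips through [read_gene_models()].
#'
#' @param genes Gene tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  n <- nrow(genes)
  feat <- function(type, id, parent) {
    attrs <- if (is.null(parent)) {
      paste0("ID=", id)
    } else {
      paste0("ID=", id, ";Parent=", parent)
    }
    sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
            genes$chrom, type, genes$start, genes$end,
            ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
            attrs)
  }
  lines <- c("##gff-version 3",
             as.vector(rbind(
               feat("gene", genes$gene_id, NULL),
               feat("mRNA", paste0(genes$gene_id, ".t1"), genes$gene_id),
               feat("exon", paste0(genes$gene_id, ".e1"),
                    paste0(genes$gene_id, ".t1"))
             )))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulation bundle to disk
#'
#' Writes the standard files the analysis modules consume: `genes.gff3`,
#' `sites.bed`, `counts.tsv`, `meta.tsv`, `atlas.tsv`, `truth.tsv`.
#'
#' @param sim An `xbias_simulation` from [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "xbias_simulation"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_genes_gff3(sim$genes, file.path(outdir, "genes.gff3"))
  write_sites_bed(sim$sites, file.path(outdir, "sites.bed"))
  readr::write_tsv(as_tibble(sim$counts, rownames = "gene_id"),
                   file.path(outdir, "counts.tsv"))
  readr::write_tsv(sim$meta, file.path(outdir, "meta.tsv"))
  readr::write_tsv(as_tibble(sim$atlas, rownames = "gene_id"),
                   file.path(outdir, "atlas.tsv"))
  readr::write_tsv(sim$truth, file.path(outdir, "truth.tsv"))
  invisible(outdir)
}
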