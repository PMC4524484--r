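# Distance of X-linked genes to the nearest DCC binding site, HAS
# colocalization, and the correlation / rank-sum analyses relating the
# male/female expression ratio to site proximity.

#' Minimum distance from genes to the nearest binding site
#'
#' The distance between a gene and a site is the minimum, over the four
#' endpoint pairs, of the absolute difference between a site endpoint and a
#' gene endpoint of the transcriptional unit; when a site overlaps the unit
#' the distance is zero. For non-overlapping intervals this equals the
#' coordinate gap between the closest edges. Only genes on chromosomes that
#' carry sites are meaningful; a gene on a chromosome with no sites is an
#' error (sites exist only on the X, so restrict to X-linked genes first).
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @param sites Tibble with columns `chrom`, `start`, `end` (and optionally
#'   `component`, carried through).
#' @return A tibble `gene_id`, `component` (if present), `distance_bp`.
#' @export
min_site_distance <- function(genes, sites) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            all(c("chrom", "start", "end") %in% names(sites)))
  if (nrow(sites) == 0) abort("binding-site set is empty; distance undefined")
  missing_chr <- setdiff(unique(genes$chrom), unique(sites$chrom))
  if (length(missing_chr) > 0) {
    abort(paste0("no binding sites on chromosome(s): ",
                 paste(missing_chr, collapse = ", "),
                 "; distance undefined"))
  }
  g <- as_granges(genes)
  s <- as_granges(sites)
  hit <- GenomicRanges::distanceToNearest(g, s)
  if (length(hit) < nrow(genes)) abort("distance undefined for some genes")
  gap <- S4Vectors::mcols(hit)$distance
  overlaps <- GenomicRanges::countOverlaps(g, s) > 0
  # endpoint rule: overlap -> 0; otherwise |endpoint difference| = gap + 1
  d <- ifelse(overlaps, 0L, gap + 1L)
  out <- tibble(gene_id = genes$gene_id, distance_bp = as.integer(d))
  if ("component" %in% names(sites) && length(unique(sites$component)) == 1) {
    out <- tibble(gene_id = out$gene_id,
                  component = sites$component[1],
                  distance_bp = out$distance_bp)
  }
  out
}

#' Derive high-affinity sites (HAS) by MLE / MSL-2 colocalization
#'
#' A HAS is the intersection of an MLE interval and an MSL-2 interval that
#' share at least `min_overlap` bp; overlapping intersections are merged.
#'
#' @param mle,msl2 Site tibbles (`chrom`, `start`, `end`).
#' @param min_overlap Minimum shared length in bp (default 1).
#' @return A site tibble with `component = "HAS"`.
#' @export
colocalize_has <- function(mle, msl2, min_overlap = 1) {
  if (nrow(mle) == 0 || nrow(msl2) == 0) {
    warn("empty input site set; no HAS derived")
    return(tibble(component = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  a <- as_granges(mle)
  b <- as_granges(msl2)
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = min_overlap)
  if (length(hits) == 0) {
    return(tibble(component = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  inter <- GenomicRanges::pintersect(a[S4Vectors::queryHits(hits)],
                                     b[S4Vectors::subjectHits(hits)])
  merged <- GenomicRanges::reduce(inter)
  tibble(
    component = "HAS",
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged)
  ) |>
    arrange(.data$chrom, .data$start)
}

#' Spearman rank correlation with small-sample exact permutation p
#'
#' Rho uses average ranks for ties. The two-sided p-value comes from the
#' t-distribution approximation, except for very small samples (n <= 8)
#' where the full permutation distribution is enumerated exactly. Zero
#' variance in either variable yields `rho = NA`, `p = 1`.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A list with `rho` and `p_value`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) abort("at least 3 pairs are required")
  if (sd(x) == 0 || sd(y) == 0) return(list(rho = NA_real_, p_value = 1))
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 8) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(t_stat), n - 2)
    p <- min(p, 1)
  }
  list(rho = rho, p_value = p)
}

# All permutations of 1..n as a matrix (n! rows); internal, n <= 8.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1), n, after = pos - 1),
                           drop = FALSE]
    out[row:(row + nrow(sub) - 1), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration for small samples (total n <= 12, no ties), otherwise
#' the tie-corrected normal approximation with continuity correction.
#'
#' @param group_a,group_b Numeric vectors, both nonempty.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  n <- length(group_a) + length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  suppressWarnings(
    wilcox.test(group_a, group_b, exact = (n <= 12 && !ties),
                correct = TRUE)$p.value
  )
}

#' Proximity summary for one data set and one site component
#'
#' Joins sex-bias calls to site distances for X-linked genes and computes
#' the Spearman correlation between the log2 male/female ratio and the
#' distance to the nearest site (over all expressed X-linked genes), the
#' median distance per bias class, and a Wilcoxon rank-sum comparison of
#' MBG vs UBG distances.
#'
#' @param records Classified table from [classify_sex_bias()] (columns
#'   `gene_id`, `log2_ratio`, `call`).
#' @param distances Tibble from [min_site_distance()] restricted to
#'   X-linked genes.
#' @return A one-row tibble: `component`, `n`, `rho`, `rho_p`,
#'   `median_mbg`, `median_fbg`, `median_ubg`, `wilcoxon_p_mbg_vs_ubg`.
#' @export
proximity_summary <- function(records, distances) {
  comp <- if ("component" %in% names(distances) && nrow(distances) > 0) {
    distances$component[1]
  } else {
    NA_character_
  }
  df <- as_tibble(records) |>
    filter(.data$call != "NOT_EXPRESSED") |>
    inner_join(as_tibble(distances)[, c("gene_id", "distance_bp")],
               by = "gene_id")
  sp <- spearman_rho(df$log2_ratio, df$distance_bp)
  med <- function(cls) {
    v <- df$distance_bp[df$call == cls]
    if (length(v) == 0) NA_real_ else median(v)
  }
  mbg <- df$distance_bp[df$call == "MBG"]
  ubg <- df$distance_bp[df$call == "UBG"]
  wp <- if (length(mbg) > 0 && length(ubg) > 0) {
    wilcoxon_rank_sum(mbg, ubg)
  } else {
    NA_real_
  }
  tibble(component = comp, n = nrow(df), rho = sp$rho, rho_p = sp$p_value,
         median_mbg = med("MBG"), median_fbg = med("FBG"),
         median_ubg = med("UBG"), wilcoxon_p_mbg_vs_ubg = wp)
}

#' Distance profile across male-bias magnitude bins
#'
#' For the male-biased genes only, bins the log2 ratio with
#' [magnitude_bin()] and reports per-bin count, median and quartiles of the
#' distance to the nearest site. Empty bins are reported with `n = 0`.
#'
#' @param records Classified table (columns `gene_id`, `log2_ratio`,
#'   `call`).
#' @param distances Tibble from [min_site_distance()].
#' @return A tibble with one row per magnitude bin: `bin`, `n`, `q1`,
#'   `median`, `q3`.
#' @export
magnitude_distance_profile <- function(records, distances) {
  df <- as_tibble(records) |>
    filter(.data$call == "MBG") |>
    inner_join(as_tibble(distances)[, c("gene_id", "distance_bp")],
               by = "gene_id") |>
    mutate(bin = magnitude_bin(.data$log2_ratio))
  levels_ <- levels(magnitude_bin(0))
  df |>
    group_by(.data$bin) |>
    summarise(n = dplyr::n(),
              q1 = quantile(.data$distance_bp, 0.25),
              median = median(.data$distance_bp),
              q3 = quantile(.data$distance_bp, 0.75)) |>
    tidyr::complete(bin = factor(levels_, levels = levels_, ordered = TRUE),
                    fill = list(n = 0L, q1 = NA_real_, median = NA_real_,
                                q3 = NA_real_)) |>
    arrange(.data$bin)
}
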