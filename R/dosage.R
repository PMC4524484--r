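# RPKM normalisation, X:autosome male expression ratios under expression
# and housekeeping filters, DCC-component expression summaries, gene-age
# means, and cross-data-set overlap / remove-and-recompute analyses.

#' Reads per kilobase of exonic model per million mapped reads
#'
#' `rpkm = 1e9 * reads / (exonic_length * total_mapped)`. Vectorised over
#' `read_count` and `exonic_length`.
#'
#' @param read_count Nonnegative read counts.
#' @param exonic_length Exonic gene-model length in bp (>= 1).
#' @param total_mapped Total mapped reads in the library (> 0).
#' @return Numeric RPKM values.
#' @export
#' @examples
#' rpkm(1000, 1000, 1e6)  # 1000
rpkm <- function(read_count, exonic_length, total_mapped) {
  if (any(total_mapped <= 0)) abort("total_mapped must be positive")
  if (any(exonic_length < 1)) abort("exonic_length must be >= 1")
  1e9 * read_count / (exonic_length * total_mapped)
}

#' X:autosome male expression ratio
#'
#' Compares the male expression distribution of autosomal and X-linked
#' genes, optionally restricted to expressed genes (`min_rpkm`) and to
#' broadly expressed "housekeeping" genes (`max_tau`). Under complete
#' dosage compensation the ratio of median autosomal to median X-linked
#' male expression is ~1; without germline compensation the X (present in
#' one copy in males) is expected to fall behind.
#'
#' @param expr Data frame with columns `gene_id` and `rpkm` (male
#'   expression).
#' @param classes Data frame with `gene_id`, `class`.
#' @param tau Optional data frame with `gene_id`, `tau`; required when
#'   `max_tau` is finite.
#' @param min_rpkm Expression filter (default 1, i.e. RPKM > 1).
#' @param max_tau Housekeeping filter (default `Inf`, i.e. off); the
#'   published housekeeping convention is `tau < 0.4`.
#' @return A one-row tibble: `n_autosome`, `n_x`, `median_autosome`,
#'   `median_x`, `ratio_a_over_x`, `wilcoxon_p`.
#' @export
xa_expression_ratio <- function(expr, classes, tau = NULL, min_rpkm = 1,
                                max_tau = Inf) {
  df <- as_tibble(expr) |>
    inner_join(as_tibble(classes)[, c("gene_id", "class")], by = "gene_id") |>
    filter(.data$class %in% c("X", "AUTOSOME"), .data$rpkm > min_rpkm)
  if (is.finite(max_tau)) {
    if (is.null(tau)) abort("a tau table is required when max_tau is finite")
    df <- df |>
      inner_join(as_tibble(tau)[, c("gene_id", "tau")], by = "gene_id") |>
      filter(.data$tau < max_tau)
  }
  a <- df$rpkm[df$class == "AUTOSOME"]
  x <- df$rpkm[df$class == "X"]
  if (length(a) == 0 || length(x) == 0) {
    abort(paste0("no ", if (length(a) == 0) "autosomal" else "X-linked",
                 " genes pass the filters (min_rpkm = ", min_rpkm,
                 ", max_tau = ", max_tau, ")"))
  }
  tibble(
    n_autosome = length(a), n_x = length(x),
    median_autosome = median(a), median_x = median(x),
    ratio_a_over_x = median(a) / median(x),
    wilcoxon_p = wilcoxon_rank_sum(a, x)
  )
}

#' Per-component expression summary (mean and SEM over replicates)
#'
#' Mean RPKM and standard error of the mean (`sd/sqrt(n)`) per gene over
#' replicate samples, intended for the DCC components MLE, MSL-1, MSL-2,
#' MSL-3 and MOF. Components missing from the table are reported with
#' `n = 0`; a single replicate has no defined SEM and reports 0 with
#' `sem_defined = FALSE`.
#'
#' @param rpkm_by_sample Data frame with columns `gene_id`, `sample_id`,
#'   `rpkm`.
#' @param components Named character vector mapping component labels to
#'   gene ids, e.g. `c(MLE = "FBgn0005617", ...)`.
#' @return A tibble: `component`, `gene_id`, `n`, `mean_rpkm`, `sem`,
#'   `sem_defined`.
#' @export
component_expression_summary <- function(rpkm_by_sample, components) {
  stopifnot(all(c("gene_id", "sample_id", "rpkm") %in% names(rpkm_by_sample)),
            !is.null(names(components)))
  purrr::imap(components, function(gid, comp) {
    v <- rpkm_by_sample$rpkm[rpkm_by_sample$gene_id == gid]
    n <- length(v)
    tibble(
      component = comp, gene_id = gid, n = n,
      mean_rpkm = if (n > 0) mean(v) else NA_real_,
      sem = if (n > 1) sd(v) / sqrt(n) else 0,
      sem_defined = n > 1
    )
  }) |>
    list_rbind()
}

#' Mean gene age of a gene set
#'
#' Arithmetic mean of the age class (0 = species-specific .. 6 = present in
#' the whole genus) over the genes present in the age table; genes absent
#' from the table are excluded from numerator and denominator, and the
#' coverage fraction is reported so that low-coverage means are visible.
#'
#' @param gene_set Character vector of gene ids.
#' @param ages Data frame with columns `gene_id`, `age_class` (integers
#'   0..6).
#' @return A one-row tibble: `n_set`, `n_with_age`, `coverage`, `mean_age`.
#' @export
mean_age <- function(gene_set, ages) {
  stopifnot(all(c("gene_id", "age_class") %in% names(ages)))
  if (any(!ages$age_class %in% 0:6)) abort("age_class values must be in 0..6")
  matched <- ages$age_class[ages$gene_id %in% gene_set]
  if (length(matched) == 0) abort("no genes of the set have a known age")
  tibble(
    n_set = length(gene_set),
    n_with_age = length(matched),
    coverage = length(matched) / length(gene_set),
    mean_age = mean(matched)
  )
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail test of the overlap between two gene sets drawn from a common
#' universe: `p = P(X >= n_overlap)` for
#' `X ~ Hypergeometric(|universe|, |a|, |b|)`. The universe should be the
#' genes expressed in both data sets being compared.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe Character vector containing both sets.
#' @param set_a_name,set_b_name Labels for the output row.
#' @return A one-row tibble: `set_a_name`, `set_b_name`, `n_a`, `n_b`,
#'   `n_overlap`, `universe_size`, `p_value`.
#' @export
overlap_test <- function(set_a, set_b, universe,
                         set_a_name = "a", set_b_name = "b") {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("both sets must be contained in the universe")
  }
  k <- length(intersect(set_a, set_b))
  p <- phyper(k - 1, length(set_a), length(universe) - length(set_a),
              length(set_b), lower.tail = FALSE)
  tibble(set_a_name = set_a_name, set_b_name = set_b_name,
         n_a = length(set_a), n_b = length(set_b), n_overlap = k,
         universe_size = length(universe), p_value = p)
}

#' Remove a gene set and recompute X-linkage enrichment
#'
#' Drops the removal set from the classified records entirely (from the
#' focal class and from the totals, so the X-linked baseline shifts) and
#' recomputes [class_counts()] and [x_enrichment()]. Used to ask whether an
#' enrichment in a composite sample survives removal of the genes driving
#' it in a component tissue.
#'
#' @param records Classified table from [classify_sex_bias()].
#' @param classes Gene chromosome classes.
#' @param removal_set Character vector of gene ids to drop.
#' @param versus Passed to [x_enrichment()].
#' @return A list with `counts` (from [class_counts()]) and `enrichment`
#'   (from [x_enrichment()]).
#' @export
remove_and_recompute <- function(records, classes, removal_set,
                                 versus = "rest") {
  kept <- as_tibble(records) |> filter(!.data$gene_id %in% removal_set)
  counts <- class_counts(kept, classes)
  list(counts = counts, enrichment = x_enrichment(counts, versus = versus))
}
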