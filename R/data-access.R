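# Packaged reference data.

#' Published per-tissue sex-biased gene counts for D. melanogaster
#'
#' A compendium of per-data-set counts of male-biased (MBG), female-biased
#' (FBG) and unbiased (UBG) genes on the autosomes and the X chromosome
#' across 14 published male/female expression comparisons (brain, head,
#' Malpighian tubule, whole fly, gonadectomized carcass and gonads),
#' together with the X-linked percentage of each class as reported
#' (`pct_*_x` columns). These counts serve as reference inputs for the
#' enrichment bookkeeping: feeding the A/X counts through [class_counts()]
#' arithmetic reproduces the reported percentages, and the 2x2 Fisher
#' constructions reproduce the reported enrichment directions (e.g. strong
#' X enrichment of brain MBG, X paucity of gonad MBG).
#'
#' Note: three of the 42 reported percentages (data set 5 FBG, data set 9
#' UBG, data set 12 FBG) are off by one point from the value their own
#' counts imply under any integer rounding; the table transmits the
#' reported values verbatim.
#'
#' @return A tibble with columns `dataset`, `source`, and per class
#'   (`mbg`, `fbg`, `ubg`) the `_a`, `_x` counts and reported `pct_*_x`.
#' @export
dmel_sexbias_counts <- function() {
  path <- system.file("extdata", "dmel_sexbias_class_counts.tsv",
                      package = "xbias", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Reference counts as a per-data-set list of class-count tables
#'
#' Reshapes [dmel_sexbias_counts()] into the [class_counts()] output format
#' (one tibble per data set with `call`, `count_autosome`, `count_x`,
#' `pct_x` recomputed by the package's own rounding), ready for
#' [x_enrichment()].
#'
#' @return A named list of tibbles, one per data set.
#' @export
dmel_class_counts <- function() {
  tab <- dmel_sexbias_counts()
  out <- purrr::pmap(tab, function(dataset, source, mbg_a, mbg_x, fbg_a,
                                   fbg_x, ubg_a, ubg_x, ...) {
    tibble(
      call = factor(c("MBG", "FBG", "UBG"), levels = c("MBG", "FBG", "UBG")),
      count_autosome = c(mbg_a, fbg_a, ubg_a),
      count_x = c(mbg_x, fbg_x, ubg_x)
    ) |>
      mutate(pct_x = pct_round(.data$count_x,
                               .data$count_autosome + .data$count_x))
  })
  names(out) <- paste0(tab$dataset, "_", gsub(" ", "_", tolower(tab$source)))
  out
}
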