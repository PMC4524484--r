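# Observed/expected X-linkage of sex-biased gene classes and Fisher exact
# tests, mirroring the per-data-set tabulation (counts with the X-linked
# percentage in parentheses) and the observed/expected ratio panels.

#' Tabulate bias classes by chromosome class
#'
#' Counts MBG/FBG/UBG on the autosomes and the X chromosome and reports the
#' X-linked percentage of each class, rounded half-up to an integer (the
#' convention that reproduces published tabulations of this kind).
#' `NOT_EXPRESSED` genes and genes on `EXCLUDED` chromosomes are dropped;
#' genes missing a chromosome class are dropped with a message.
#'
#' @param records Data frame with columns `gene_id` and `call`
#'   (from [classify_sex_bias()]).
#' @param classes Data frame with columns `gene_id` and `class`
#'   (`"X"`/`"AUTOSOME"`/`"EXCLUDED"`), e.g. from [read_gene_models()].
#' @return A tibble with one row per bias class: `call`, `count_autosome`,
#'   `count_x`, `pct_x`.
#' @export
class_counts <- function(records, classes) {
  stopifnot(all(c("gene_id", "call") %in% names(records)),
            all(c("gene_id", "class") %in% names(classes)))
  joined <- as_tibble(records) |>
    inner_join(as_tibble(classes)[, c("gene_id", "class")], by = "gene_id")
  n_missing <- nrow(records) - nrow(joined)
  if (n_missing > 0) {
    inform(paste0(n_missing, " gene(s) missing from the annotation dropped"))
  }
  joined |>
    filter(.data$call %in% c("MBG", "FBG", "UBG"),
           .data$class %in% c("X", "AUTOSOME")) |>
    count(.data$call, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      if (!"AUTOSOME" %in% names(d)) d$AUTOSOME <- 0L
      if (!"X" %in% names(d)) d$X <- 0L
      d
    })() |>
    transmute(
      call = factor(.data$call, levels = c("MBG", "FBG", "UBG")),
      count_autosome = .data$AUTOSOME,
      count_x = .data$X,
      pct_x = pct_round(.data$X, .data$AUTOSOME + .data$X)
    ) |>
    arrange(.data$call)
}

# Integer percentage with half-up rounding (round() would round half to even).
pct_round <- function(x, total) {
  ifelse(total > 0, floor(100 * x / total + 0.5), NA_real_)
}

#' Expected number of X-linked genes in a bias class
#'
#' The expectation under random placement: the proportion of all genes in
#' the data set that are X-linked, multiplied by the size of the class.
#'
#' @param n_class Number of genes in the bias class.
#' @param n_x_total Number of X-linked genes in the data set.
#' @param n_total Total number of (expressed) genes in the data set.
#' @return The expected count (real-valued).
#' @export
#' @examples
#' expected_x(128, 1833, 11053)
expected_x <- function(n_class, n_x_total, n_total) {
  if (any(n_total == 0)) abort("n_total must be positive")
  stopifnot(n_x_total <= n_total, all(n_class <= n_total))
  n_class * n_x_total / n_total
}

#' Fisher exact test on a 2x2 contingency table
#'
#' Conditional (hypergeometric) odds ratio and two-sided p-value, the
#' two-sided p being the total probability of tables at most as probable as
#' the observed one. If a row or column margin is zero the test is
#' degenerate: p = 1 and the odds ratio is `NaN`.
#'
#' @param a,b,c,d Cell counts, laid out as `[a, b; c, d]` (for X-linkage
#'   enrichment: `a` = class on X, `b` = class on autosomes, `c` = other
#'   genes on X, `d` = other genes on autosomes).
#' @return A list with `odds_ratio` and `p_value`.
#' @export
fisher_exact <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    return(list(odds_ratio = NaN, p_value = 1))
  }
  ft <- fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Observed/expected X-linkage enrichment per bias class
#'
#' For each bias class, the observed X-linked count, the expected count
#' under random placement, their ratio, and a Fisher exact test of the
#' 2x2 table contrasting the focal class with the rest of the expressed
#' genes in the data set (or with the unbiased genes only, as a sensitivity
#' variant).
#'
#' @param counts A tibble from [class_counts()] (or with the same columns).
#' @param versus `"rest"` (default) contrasts each class against all other
#'   expressed genes; `"ubg"` contrasts against unbiased genes only.
#' @return A tibble with one row per bias class: `call`, `observed_x`,
#'   `expected_x`, `oe_ratio`, `odds_ratio`, `p_value`, `stars`.
#' @export
x_enrichment <- function(counts, versus = c("rest", "ubg")) {
  versus <- match.arg(versus)
  stopifnot(all(c("call", "count_autosome", "count_x") %in% names(counts)))
  n_x_total <- sum(counts$count_x)
  n_total <- sum(counts$count_x) + sum(counts$count_autosome)
  ubg <- counts[counts$call == "UBG", ]
  purrr::pmap(counts, function(call, count_autosome, count_x, ...) {
    n_class <- count_autosome + count_x
    exp_x <- expected_x(n_class, n_x_total, n_total)
    if (versus == "rest" || call == "UBG") {
      other_x <- n_x_total - count_x
      other_a <- (n_total - n_x_total) - count_autosome
    } else {
      other_x <- sum(ubg$count_x)
      other_a <- sum(ubg$count_autosome)
    }
    ft <- fisher_exact(count_x, count_autosome, other_x, other_a)
    tibble(call = call, observed_x = count_x, expected_x = exp_x,
           oe_ratio = ifelse(exp_x > 0, count_x / exp_x, NA_real_),
           odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  }) |>
    list_rbind() |>
    mutate(stars = significance_stars(.data$p_value))
}

#' Significance stars at the 0.05 / 0.01 / 0.001 levels
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `"***"` for p < 0.001, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, `""` otherwise.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}
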