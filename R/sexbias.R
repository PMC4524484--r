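# Sex-bias classification: MBG / FBG / UBG calls from per-gene expression
# summaries and p-values, under the two threshold dialects used for RNA-seq
# (BH/FDR at 5%) and microarray (nominal p) data sets.

#' Threshold configuration for sex-bias classification
#'
#' @param mode `"FDR"` (significance judged on BH-adjusted p-values, the
#'   RNA-seq dialect) or `"NOMINAL_P"` (raw p-values, the microarray
#'   dialect).
#' @param alpha Significance cutoff, default 0.05. Some microarray data sets
#'   need a laxer cutoff (e.g. 0.10) to yield usable numbers of genes.
#' @param pseudocount Added to both sexes before the log2 ratio. Use 1 for
#'   count-scale input, 0 for pre-normalised expression.
#' @param min_expression Genes with both sexes below this level are flagged
#'   `NOT_EXPRESSED` and excluded from all downstream totals. `0` (default)
#'   disables the filter; `RPKM > 1` style robustness checks set it to 1.
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(mode = c("FDR", "NOMINAL_P"), alpha = 0.05,
                             pseudocount = 1, min_expression = 0) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, pseudocount >= 0)
  structure(list(mode = mode, alpha = alpha, pseudocount = pseudocount,
                 min_expression = min_expression),
            class = "threshold_config")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1, returned in the input
#' order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; no missing values.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.04))  # 0.02, 0.04
bh_adjust <- function(p) {
  if (anyNA(p)) abort("missing p-values; filter them before adjustment")
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Log2 male/female expression ratio
#'
#' `log2((male + pseudocount) / (female + pseudocount))`. When both values
#' and the pseudocount are zero the ratio is undefined and `NaN` is
#' returned; such genes are flagged `NOT_EXPRESSED` by [classify_sex_bias()].
#'
#' @param expr_male,expr_female Nonnegative expression values (vectorised).
#' @param pseudocount Nonnegative offset.
#' @return Numeric vector of log2 ratios.
#' @export
log2_ratio <- function(expr_male, expr_female, pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  if (any(expr_male < 0, na.rm = TRUE) || any(expr_female < 0, na.rm = TRUE)) {
    abort("expression values must be nonnegative")
  }
  num <- expr_male + pseudocount
  den <- expr_female + pseudocount
  out <- log2(num / den)
  out[num == 0 & den == 0] <- NaN
  out
}

#' Classify genes as male-biased, female-biased or unbiased
#'
#' Takes a per-gene differential-expression table (as produced by any
#' upstream DE tool, or by [standin_de_test()] on simulated counts) and
#' assigns each gene one of `MBG`, `FBG`, `UBG` or `NOT_EXPRESSED`:
#' a gene is biased when it is significant under the configured dialect
#' (`p_adj < alpha` in FDR mode, `p_raw < alpha` in nominal mode) and its
#' log2 male/female ratio is nonzero; the sign of the ratio sets the
#' direction. A significant gene with a ratio of exactly zero has no
#' direction and is called `UBG`, with a warning. Genes with both sexes
#' below `min_expression` are `NOT_EXPRESSED` and must be excluded from all
#' downstream totals.
#'
#' @param de Data frame with columns `gene_id`, `expr_male`, `expr_female`
#'   and `p_raw` (and/or `p_adj`). If FDR mode is requested and `p_adj` is
#'   absent it is computed with [bh_adjust()] over the non-missing `p_raw`.
#' @param cfg A [threshold_config()].
#' @return A tibble with the input columns plus `p_adj`, `log2_ratio` and
#'   `call`.
#' @export
classify_sex_bias <- function(de, cfg = threshold_config()) {
  stopifnot(is.data.frame(de),
            all(c("gene_id", "expr_male", "expr_female") %in% names(de)))
  de <- as_tibble(de)
  if (!"p_raw" %in% names(de)) de$p_raw <- NA_real_
  if (!"p_adj" %in% names(de)) {
    de$p_adj <- NA_real_
    if (cfg$mode == "FDR") {
      ok <- !is.na(de$p_raw)
      de$p_adj[ok] <- bh_adjust(de$p_raw[ok])
    }
  }

  de$log2_ratio <- log2_ratio(de$expr_male, de$expr_female, cfg$pseudocount)

  p_used <- if (cfg$mode == "FDR") de$p_adj else de$p_raw
  significant <- !is.na(p_used) & p_used < cfg$alpha

  not_expressed <- (de$expr_male < cfg$min_expression &
                      de$expr_female < cfg$min_expression) |
    is.nan(de$log2_ratio)

  call <- rep("UBG", nrow(de))
  call[significant & !is.nan(de$log2_ratio) & de$log2_ratio > 0] <- "MBG"
  call[significant & !is.nan(de$log2_ratio) & de$log2_ratio < 0] <- "FBG"
  zero_sig <- significant & !is.nan(de$log2_ratio) & de$log2_ratio == 0
  if (any(zero_sig)) {
    warn(paste0(sum(zero_sig),
                " significant gene(s) with log2 ratio exactly 0 called UBG"))
  }
  call[not_expressed] <- "NOT_EXPRESSED"
  de$call <- call
  de
}

#' Bin the magnitude of sex-biased expression
#'
#' Fold change is `2^|log2_ratio|`; bins are `<=2-fold`, `2-4-fold`,
#' `4-6-fold` and `>6-fold`, with boundary values assigned to the lower bin.
#'
#' @param log2_ratio Numeric vector of log2 male/female ratios (the absolute
#'   value is binned, so FBG can be passed directly).
#' @return A factor with the four ordered bin labels.
#' @export
magnitude_bin <- function(log2_ratio) {
  fold <- 2^abs(log2_ratio)
  labels <- c("<=2-fold", "2-4-fold", "4-6-fold", ">6-fold")
  idx <- findInterval(fold, c(2, 4, 6), left.open = TRUE) + 1L
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' Stand-in differential-expression test for simulated counts
#'
#' A two-sided Welch t-test on `log2(count + 1)`. This is a deliberately
#' simple surrogate used to exercise the pipeline end-to-end on simulated
#' counts; it is not a reimplementation of a negative-binomial DE tool, and
#' real data should be classified from the output table of such a tool.
#' Genes with zero variance in both groups and equal means return p = 1 by
#' convention.
#'
#' @param counts_male,counts_female Nonnegative integer vectors, at least 2
#'   replicates each.
#' @return A single raw p-value.
#' @export
standin_de_test <- function(counts_male, counts_female) {
  if (length(counts_male) < 2 || length(counts_female) < 2) {
    abort("at least 2 replicates per sex are required")
  }
  m <- log2(counts_male + 1)
  f <- log2(counts_female + 1)
  if (sd(m) == 0 && sd(f) == 0) {
    return(if (mean(m) == mean(f)) 1 else 0)
  }
  t.test(m, f)$p.value
}

# Vectorised Welch t-test over the rows of two matrices (genes x replicates).
# Same convention as standin_de_test; used by the simulator-scale pipeline.
welch_t_rows <- function(mat_male, mat_female) {
  lm_ <- log2(mat_male + 1)
  lf_ <- log2(mat_female + 1)
  nm <- ncol(lm_); nf <- ncol(lf_)
  mm <- rowMeans(lm_); mf <- rowMeans(lf_)
  vm <- rowSums((lm_ - mm)^2) / (nm - 1)
  vf <- rowSums((lf_ - mf)^2) / (nf - 1)
  se2 <- vm / nm + vf / nf
  t_stat <- (mm - mf) / sqrt(se2)
  df <- se2^2 / ((vm / nm)^2 / (nm - 1) + (vf / nf)^2 / (nf - 1))
  p <- 2 * pt(-abs(t_stat), df)
  p[se2 == 0] <- ifelse(mm[se2 == 0] == mf[se2 == 0], 1, 0)
  p
}

#' Differential-expression table from a simulated count matrix
#'
#' Applies the stand-in Welch test ([standin_de_test()]) to every gene of a
#' count matrix and returns the per-gene table consumed by
#' [classify_sex_bias()]. Expression summaries are mean counts per sex.
#'
#' @param counts Numeric matrix, genes x samples, with rownames.
#' @param meta Data frame with columns `sample` (matching `colnames(counts)`)
#'   and `sex` (`"male"`/`"female"`).
#' @return A tibble with `gene_id`, `expr_male`, `expr_female`, `p_raw`.
#' @export
de_table_from_counts <- function(counts, meta) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            all(c("sample", "sex") %in% names(meta)),
            all(colnames(counts) %in% meta$sample))
  sex <- meta$sex[match(colnames(counts), meta$sample)]
  males <- counts[, sex == "male", drop = FALSE]
  females <- counts[, sex == "female", drop = FALSE]
  if (ncol(males) < 2 || ncol(females) < 2) {
    abort("at least 2 replicates per sex are required")
  }
  tibble(
    gene_id = rownames(counts),
    expr_male = rowMeans(males),
    expr_female = rowMeans(females),
    p_raw = welch_t_rows(males, females)
  )
}
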