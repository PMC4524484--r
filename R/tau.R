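# Tissue-specificity index tau from a multi-tissue expression atlas, with
# the preprocessing used for microarray atlases: probe collapsing,
# composite-tissue exclusion, and condition averaging.

#' Collapse probe-level atlas rows to gene level
#'
#' When several array probes map to the same gene, only the probe with the
#' highest hybridization intensity is kept. "Highest" defaults to the
#' highest mean intensity across tissues; `rule = "max"` instead keeps the
#' probe with the highest single-tissue value. Probes absent from the map
#' are dropped, with a message.
#'
#' @param atlas Numeric matrix (probes x tissues) with probe rownames, or a
#'   data frame whose first column is the probe id.
#' @param probe_map Data frame with columns `probe` and `gene_id`.
#' @param rule `"mean"` (default) or `"max"`.
#' @return A numeric matrix, genes x tissues, with gene rownames.
#' @export
collapse_probes <- function(atlas, probe_map, rule = c("mean", "max")) {
  rule <- match.arg(rule)
  atlas <- as_atlas_matrix(atlas)
  stopifnot(all(c("probe", "gene_id") %in% names(probe_map)))
  idx <- match(rownames(atlas), probe_map$probe)
  unmapped <- is.na(idx)
  if (any(unmapped)) {
    inform(paste0(sum(unmapped), " unmapped probe(s) dropped"))
  }
  atlas <- atlas[!unmapped, , drop = FALSE]
  genes <- probe_map$gene_id[idx[!unmapped]]
  score <- if (rule == "mean") rowMeans(atlas) else apply(atlas, 1, max)
  ord <- order(genes, -score)
  keep <- ord[!duplicated(genes[ord])]
  out <- atlas[keep, , drop = FALSE]
  rownames(out) <- genes[keep]
  out[order(rownames(out)), , drop = FALSE]
}

#' Exclude and average atlas tissue columns
#'
#' Removes composite-structure columns (e.g. whole "head" and "carcass",
#' which duplicate their component tissues) and replaces each group of
#' condition columns (e.g. mated and virgin spermatheca) by the arithmetic
#' mean column named after the group.
#'
#' @param atlas Genes x tissues matrix (see [collapse_probes()]).
#' @param exclude Character vector of column names to drop.
#' @param average_groups Named list of character vectors; each element is
#'   replaced by one column of means carrying the element's name.
#' @return The transformed matrix.
#' @export
prepare_tissues <- function(atlas, exclude = character(),
                            average_groups = list()) {
  atlas <- as_atlas_matrix(atlas)
  wanted <- c(exclude, unlist(average_groups))
  missing <- setdiff(wanted, colnames(atlas))
  if (length(missing) > 0) {
    abort(paste0("tissue column(s) not found: ",
                 paste(missing, collapse = ", ")))
  }
  atlas <- atlas[, !colnames(atlas) %in% exclude, drop = FALSE]
  for (nm in names(average_groups)) {
    grp <- average_groups[[nm]]
    avg <- rowMeans(atlas[, grp, drop = FALSE])
    atlas <- atlas[, !colnames(atlas) %in% grp, drop = FALSE]
    atlas <- cbind(atlas, avg)
    colnames(atlas)[ncol(atlas)] <- nm
  }
  atlas
}

#' Tissue-specificity index tau
#'
#' For an expression profile `x` over `N >= 2` tissues,
#' `tau = sum_i (1 - x_i / max(x)) / (N - 1)`; 0 for a uniformly (broadly)
#' expressed gene, 1 for expression confined to a single tissue. Negative
#' values (possible after microarray background correction) are clamped to
#' zero; an all-zero profile has no defined tau and returns `NA`.
#'
#' @param x Numeric vector of expression values over tissues.
#' @return tau in `[0, 1]`, or `NA` for an all-zero profile.
#' @export
#' @examples
#' compute_tau(c(8, 2, 2, 2))  # 0.75
compute_tau <- function(x) {
  if (length(x) < 2) abort("tau requires at least 2 tissues")
  x <- pmax(x, 0)
  m <- max(x)
  if (m == 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1)
}

#' Per-gene tau table from a prepared atlas
#'
#' Applies [compute_tau()] to every row and flags housekeeping-like
#' (`tau < 0.4`) and highly tissue-specific (`tau > 0.7`) genes; records the
#' tissue of maximal expression. Genes with all-zero profiles are skipped
#' with a warning. Negative values are clamped to zero first (with a
#' message when any occur). An optional log2 pre-transform
#' (`log2(x + 1)`) is available since published variants of the index
#' differ on this; the default uses raw intensities.
#'
#' @param atlas Genes x tissues matrix.
#' @param log_transform Apply `log2(x + 1)` before computing tau.
#' @param housekeeping_max,specific_min Flag thresholds (defaults 0.4, 0.7).
#' @return A tibble: `gene_id`, `tau`, `n_tissues_used`, `is_housekeeping`,
#'   `is_specific`, `max_tissue`.
#' @export
tau_table <- function(atlas, log_transform = FALSE,
                      housekeeping_max = 0.4, specific_min = 0.7) {
  atlas <- as_atlas_matrix(atlas)
  if (any(atlas < 0)) {
    inform(paste0(sum(atlas < 0), " negative value(s) clamped to 0"))
    atlas[atlas < 0] <- 0
  }
  if (log_transform) atlas <- log2(atlas + 1)
  tau <- apply(atlas, 1, compute_tau)
  if (anyNA(tau)) {
    warn(paste0(sum(is.na(tau)), " all-zero profile(s) skipped (tau undefined)"))
  }
  out <- tibble(
    gene_id = rownames(atlas),
    tau = tau,
    n_tissues_used = ncol(atlas),
    is_housekeeping = !is.na(tau) & tau < housekeeping_max,
    is_specific = !is.na(tau) & tau > specific_min,
    max_tissue = colnames(atlas)[apply(atlas, 1, which.max)]
  )
  out[!is.na(out$tau), ]
}

# Coerce atlas input (matrix, or data frame with an id first column) to a
# numeric matrix with rownames.
as_atlas_matrix <- function(atlas) {
  if (is.matrix(atlas)) {
    storage.mode(atlas) <- "double"
    return(atlas)
  }
  stopifnot(is.data.frame(atlas))
  ids <- as.character(atlas[[1]])
  m <- as.matrix(atlas[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}
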