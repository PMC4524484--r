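# End-to-end orchestration of one data set: classification, X-linkage
# enrichment, site proximity per DCC component, magnitude bins, tau and age
# joins; plus cross-data-set comparison tables.

#' Data-set configuration for a pipeline run
#'
#' @param name Data-set label.
#' @param de Differential-expression table (tibble with `gene_id`,
#'   `expr_male`, `expr_female`, `p_raw`[, `p_adj`]) or a path to a TSV
#'   with those columns.
#' @param genes Gene table (from [read_gene_models()] or
#'   [simulate_genome()]) or a path to a GFF3 file.
#' @param sites Named list of site tibbles (one per DCC component), a
#'   single site tibble, or a named character vector of BED paths.
#' @param threshold A [threshold_config()]; use the FDR dialect for
#'   RNA-seq-style tables and the nominal-p dialect for microarray-style
#'   tables.
#' @param atlas Optional prepared atlas matrix for the tau analysis.
#' @param ages Optional age table (`gene_id`, `age_class`).
#' @param analyses Which optional stages to run.
#' @return A list of class `dataset_config`.
#' @export
dataset_config <- function(name, de, genes, sites = list(),
                           threshold = threshold_config(),
                           atlas = NULL, ages = NULL,
                           analyses = c("enrichment", "proximity",
                                        "magnitude", "tau", "age")) {
  if (is.character(de)) de <- readr::read_tsv(de, show_col_types = FALSE)
  if (is.character(genes)) genes <- read_gene_models(genes)
  if (is.character(sites)) {
    sites <- purrr::imap(as.list(sites), \(p, comp) read_sites_bed(p, comp))
  }
  if (is.data.frame(sites)) {
    comp <- if ("component" %in% names(sites) && nrow(sites) > 0) {
      sites$component[1]
    } else {
      "MLE"
    }
    sites <- setNames(list(sites), comp)
  }
  structure(list(name = name, de = as_tibble(de), genes = as_tibble(genes),
                 sites = sites, threshold = threshold, atlas = atlas,
                 ages = ages, analyses = analyses),
            class = "dataset_config")
}

#' Run the full analysis for one data set
#'
#' Stage order: sex-bias classification; class counts and X-linkage
#' enrichment; site proximity per component (X-linked genes only);
#' male-bias magnitude bins and their distance profile; tau summary of the
#' X-linked MBG; mean gene age per class. Stages toggled off in
#' `cfg$analyses` are skipped and recorded as such in the manifest. Any
#' stage failure aborts with an error naming the stage.
#'
#' @param cfg A [dataset_config()].
#' @param outdir Optional directory; when given, one TSV per analysis and a
#'   JSON manifest are written there.
#' @return A list of class `xbias_report`.
#' @export
run_dataset <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "dataset_config"))
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", label, "' failed: ", conditionMessage(e)))
    })
  }
  stages <- character()
  skipped <- character()

  records <- stage("classify", classify_sex_bias(cfg$de, cfg$threshold))
  stages <- c(stages, "classify")
  classes <- cfg$genes[, c("gene_id", "class")]

  counts <- NULL; enrichment <- NULL
  if ("enrichment" %in% cfg$analyses) {
    counts <- stage("class_counts", class_counts(records, classes))
    enrichment <- stage("enrichment", x_enrichment(counts))
    stages <- c(stages, "class_counts", "enrichment")
  } else {
    skipped <- c(skipped, "enrichment")
  }

  proximity <- NULL; distances <- NULL
  if ("proximity" %in% cfg$analyses && length(cfg$sites) > 0) {
    proximity <- stage("proximity", {
      x_genes <- cfg$genes |> filter(.data$class == "X")
      expressed <- records$gene_id[records$call != "NOT_EXPRESSED"]
      x_genes <- x_genes |> filter(.data$gene_id %in% expressed)
      purrr::imap(cfg$sites, function(s, comp) {
        d <- min_site_distance(x_genes, s)
        if (!"component" %in% names(d)) d$component <- comp
        summ <- proximity_summary(records, d)
        summ$component <- comp
        list(distances = d, summary = summ)
      })
    })
    distances <- purrr::map(proximity, "distances")
    proximity <- purrr::map(proximity, "summary") |> list_rbind()
    stages <- c(stages, "proximity")
  } else if ("proximity" %in% cfg$analyses) {
    skipped <- c(skipped, "proximity")
  } else {
    skipped <- c(skipped, "proximity")
  }

  magnitude <- NULL
  if ("magnitude" %in% cfg$analyses) {
    magnitude <- stage("magnitude", {
      mbg <- records |> filter(.data$call == "MBG")
      bins <- mbg |>
        mutate(bin = magnitude_bin(.data$log2_ratio)) |>
        count(.data$bin, .drop = FALSE)
      profile <- if (!is.null(distances) && length(distances) > 0) {
        magnitude_distance_profile(records, distances[[1]])
      } else {
        NULL
      }
      list(bins = bins, profile = profile)
    })
    stages <- c(stages, "magnitude")
  } else {
    skipped <- c(skipped, "magnitude")
  }

  tau_summary <- NULL
  if ("tau" %in% cfg$analyses && !is.null(cfg$atlas)) {
    tau_summary <- stage("tau", {
      tt <- tau_table(cfg$atlas)
      x_mbg <- records |>
        inner_join(classes, by = "gene_id") |>
        filter(.data$call == "MBG", .data$class == "X") |>
        inner_join(tt, by = "gene_id")
      tibble(
        n_x_mbg_with_tau = nrow(x_mbg),
        mean_tau = if (nrow(x_mbg) > 0) mean(x_mbg$tau) else NA_real_,
        n_specific = sum(x_mbg$is_specific),
        pct_specific = if (nrow(x_mbg) > 0) {
          pct_round(sum(x_mbg$is_specific), nrow(x_mbg))
        } else {
          NA_real_
        }
      )
    })
    stages <- c(stages, "tau")
  } else {
    skipped <- c(skipped, "tau")
  }

  age_summary <- NULL
  if ("age" %in% cfg$analyses && !is.null(cfg$ages)) {
    age_summary <- stage("age", {
      x_mbg <- records |>
        inner_join(classes, by = "gene_id") |>
        filter(.data$call == "MBG", .data$class == "X")
      if (nrow(x_mbg) > 0 &&
          any(x_mbg$gene_id %in% cfg$ages$gene_id)) {
        mean_age(x_mbg$gene_id, cfg$ages)
      } else {
        tibble(n_set = nrow(x_mbg), n_with_age = 0L, coverage = 0,
               mean_age = NA_real_)
      }
    })
    stages <- c(stages, "age")
  } else {
    skipped <- c(skipped, "age")
  }

  manifest <- list(
    name = cfg$name,
    package_version = as.character(utils::packageVersion("xbias")),
    config_hash = rlang::hash(cfg),
    threshold = unclass(cfg$threshold),
    n_input = nrow(cfg$de),
    n_expressed = sum(records$call != "NOT_EXPRESSED"),
    n_dropped_not_expressed = sum(records$call == "NOT_EXPRESSED"),
    n_dropped_unannotated = sum(!records$gene_id %in% classes$gene_id),
    stages_completed = stages,
    stages_skipped = skipped
  )

  report <- structure(
    list(name = cfg$name, records = records, counts = counts,
         enrichment = enrichment, proximity = proximity,
         distances = distances, magnitude = magnitude,
         tau_summary = tau_summary, age_summary = age_summary,
         manifest = manifest),
    class = "xbias_report"
  )
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

# Write one TSV per analysis plus a JSON manifest.
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) {
    if (!is.null(x)) readr::write_tsv(x, file.path(outdir, f))
  }
  wr(report$records, "records.tsv")
  wr(report$counts, "class_counts.tsv")
  wr(report$enrichment, "enrichment.tsv")
  wr(report$proximity, "proximity.tsv")
  if (!is.null(report$magnitude)) {
    wr(report$magnitude$bins, "magnitude_bins.tsv")
    wr(report$magnitude$profile, "magnitude_distance.tsv")
  }
  wr(report$tau_summary, "tau_summary.tsv")
  wr(report$age_summary, "age_summary.tsv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(outdir)
}

#' @export
print.xbias_report <- function(x, ...) {
  cat("<xbias_report> data set:", x$name, "\n")
  cat("  expressed genes:", x$manifest$n_expressed, "\n")
  if (!is.null(x$counts)) {
    cat("  class counts:\n")
    print(as.data.frame(x$counts), row.names = FALSE)
  }
  if (!is.null(x$proximity)) {
    cat("  proximity (per component):\n")
    print(as.data.frame(x$proximity), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy a pipeline report into a long statistic table
#'
#' @param x An `xbias_report`.
#' @param ... Unused.
#' @return A tibble `dataset`, `analysis`, `term`, `statistic`, `value`.
#' @export
tidy.xbias_report <- function(x, ...) {
  rows <- list()
  if (!is.null(x$enrichment)) {
    rows$enrichment <- x$enrichment |>
      tidyr::pivot_longer(c("observed_x", "expected_x", "oe_ratio",
                            "odds_ratio", "p_value"),
                          names_to = "statistic", values_to = "value") |>
      transmute(analysis = "enrichment", term = as.character(.data$call),
                statistic = .data$statistic, value = .data$value)
  }
  if (!is.null(x$proximity)) {
    rows$proximity <- x$proximity |>
      tidyr::pivot_longer(c("rho", "rho_p", "median_mbg", "median_fbg",
                            "median_ubg", "wilcoxon_p_mbg_vs_ubg"),
                          names_to = "statistic", values_to = "value") |>
      transmute(analysis = "proximity", term = .data$component,
                statistic = .data$statistic, value = .data$value)
  }
  bind_rows(rows) |> mutate(dataset = x$name, .before = 1)
}

#' One-row summary of a pipeline report
#'
#' @param x An `xbias_report`.
#' @param ... Unused.
#' @return A one-row tibble with headline statistics.
#' @export
glance.xbias_report <- function(x, ...) {
  cc <- x$counts
  g <- function(cls, col) {
    if (is.null(cc)) return(NA_real_)
    v <- cc[[col]][cc$call == cls]
    if (length(v) == 0) NA_real_ else v
  }
  mbg_row <- if (!is.null(x$enrichment)) {
    x$enrichment[x$enrichment$call == "MBG", ]
  } else {
    NULL
  }
  tibble(
    dataset = x$name,
    n_expressed = x$manifest$n_expressed,
    n_mbg = g("MBG", "count_autosome") + g("MBG", "count_x"),
    n_fbg = g("FBG", "count_autosome") + g("FBG", "count_x"),
    pct_x_mbg = g("MBG", "pct_x"),
    oe_mbg = if (!is.null(mbg_row) && nrow(mbg_row)) mbg_row$oe_ratio else NA_real_,
    p_mbg = if (!is.null(mbg_row) && nrow(mbg_row)) mbg_row$p_value else NA_real_,
    rho = if (!is.null(x$proximity)) x$proximity$rho[1] else NA_real_,
    rho_p = if (!is.null(x$proximity)) x$proximity$rho_p[1] else NA_real_
  )
}

#' Combine several reports into a cross-data-set table
#'
#' Long-format table (data set x analysis x statistic) with significance
#' stars, suitable for multi-panel comparison plots.
#'
#' @param reports A list of `xbias_report` objects.
#' @return A tibble.
#' @export
compare_datasets <- function(reports) {
  stopifnot(length(reports) >= 2)
  tab <- purrr::map(reports, tidy) |> list_rbind()
  p_rows <- tab$statistic %in% c("p_value", "rho_p", "wilcoxon_p_mbg_vs_ubg")
  tab$stars <- ""
  tab$stars[p_rows] <- significance_stars(tab$value[p_rows])
  tab
}
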