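# Annotation and binding-site I/O.
#
# Internal coordinates are 1-based and inclusive at both ends (the GFF
# convention). BED input (0-based, half-open) is converted on read, so a BED
# line "X 0 100" becomes the internal interval (X, 1, 100).

#' Chromosome classification configuration
#'
#' Maps chromosome (arm) names onto the three classes used throughout the
#' package: `X`, `AUTOSOME` and `EXCLUDED`. The defaults reflect the
#' euchromatic *D. melanogaster* karyotype: `X` is the X chromosome;
#' `2L`, `2R`, `3L`, `3R` and `4` are autosomes; heterochromatic arms
#' (`XHet`, `2LHet`, ...), the mitochondrial genome and unplaced scaffolds
#' are excluded. Unknown names classify as `EXCLUDED` with a warning.
#'
#' @param x_chroms Character vector of names counted as X-linked.
#' @param autosomes Character vector of names counted as autosomal.
#' @param excluded Character vector of names silently excluded (anything not
#'   listed in any of the three vectors is also excluded, with a warning).
#' @return A named list of class `chrom_config`.
#' @export
#' @examples
#' cfg <- chrom_config()
#' classify_chromosome(c("X", "2L", "mitochondrion_genome"), cfg)
chrom_config <- function(x_chroms = "X",
                         autosomes = c("2L", "2R", "3L", "3R", "4"),
                         excluded = c("XHet", "2LHet", "2RHet", "3LHet",
                                      "3RHet", "YHet", "Y", "U", "Uextra",
                                      "mitochondrion_genome", "dmel_mitochondrion_genome")) {
  overlap <- intersect(x_chroms, autosomes)
  if (length(overlap) > 0) {
    abort(paste0("chromosome(s) listed as both X and autosome: ",
                 paste(overlap, collapse = ", ")))
  }
  structure(list(x_chroms = x_chroms, autosomes = autosomes,
                 excluded = excluded),
            class = "chrom_config")
}

#' Classify chromosome names as X, autosome or excluded
#'
#' @param chrom Character vector of chromosome names.
#' @param config A [chrom_config()].
#' @return A character vector over `{"X", "AUTOSOME", "EXCLUDED"}`, same
#'   length as `chrom`.
#' @export
classify_chromosome <- function(chrom, config = chrom_config()) {
  stopifnot(inherits(config, "chrom_config"))
  out <- rep("EXCLUDED", length(chrom))
  out[chrom %in% config$x_chroms] <- "X"
  out[chrom %in% config$autosomes] <- "AUTOSOME"
  known <- c(config$x_chroms, config$autosomes, config$excluded)
  unknown <- setdiff(unique(chrom), known)
  if (length(unknown) > 0) {
    warn(paste0("unknown chromosome name(s) classified as EXCLUDED: ",
                paste(head(unknown, 10), collapse = ", ")))
  }
  out
}

#' Read gene models from a GFF3 annotation
#'
#' Parses `gene`, transcript (`mRNA` and other children of genes) and `exon`
#' features and collapses them to one record per gene. The genomic span is
#' the transcriptional unit: the minimum start to the maximum end over all
#' transcripts of the gene (falling back to the gene feature itself when no
#' transcripts are annotated). `exonic_length` is the length of the union of
#' all exon intervals across transcripts; genes without annotated exons fall
#' back to the span length, with a warning.
#'
#' @param path Path to a GFF3 file.
#' @param config A [chrom_config()] used to add a chromosome `class` column.
#' @return A tibble with columns `gene_id`, `chrom`, `class`, `start`,
#'   `end`, `strand`, `exonic_length` (all coordinates 1-based inclusive).
#' @export
read_gene_models <- function(path, config = chrom_config()) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID)
  parents <- meta$Parent  # CharacterList
  parent1 <- vapply(as.list(parents), function(p) {
    if (length(p) == 0) NA_character_ else p[[1]]
  }, character(1))

  is_gene <- type == "gene"
  if (!any(is_gene)) abort("no 'gene' features found in GFF3 file")
  gene_ids <- ids[is_gene]
  if (anyNA(gene_ids)) abort("gene feature without an ID attribute")

  genes <- tibble(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene]
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "unknown"

  # transcript -> gene map: any feature whose Parent is a gene
  is_tx <- !is_gene & !is.na(parent1) & parent1 %in% gene_ids & type != "exon"
  tx_gene <- setNames(parent1[is_tx], ids[is_tx])

  if (any(is_tx)) {
    tx_spans <- tibble(
      gene_id = unname(tx_gene[ids[is_tx]]),
      start = GenomicRanges::start(gr)[is_tx],
      end = GenomicRanges::end(gr)[is_tx]
    ) |>
      group_by(.data$gene_id) |>
      summarise(tx_start = min(.data$start), tx_end = max(.data$end))
    genes <- genes |>
      left_join(tx_spans, by = "gene_id") |>
      mutate(start = ifelse(is.na(.data$tx_start), .data$start, .data$tx_start),
             end = ifelse(is.na(.data$tx_end), .data$end, .data$tx_end)) |>
      select(-"tx_start", -"tx_end")
  }

  # exon union per gene (exons are children of transcripts; tolerate exons
  # attached directly to genes)
  is_exon <- type == "exon" & !is.na(parent1)
  exon_gene <- ifelse(parent1[is_exon] %in% gene_ids,
                      parent1[is_exon],
                      unname(tx_gene[parent1[is_exon]]))
  keep <- !is.na(exon_gene)
  exonic <- tibble(gene_id = character(), exonic_length = integer())
  if (any(keep)) {
    exon_gr <- GenomicRanges::GRanges(
      seqnames = exon_gene[keep],  # group by gene, not chromosome
      ranges = IRanges::IRanges(GenomicRanges::start(gr)[is_exon][keep],
                                GenomicRanges::end(gr)[is_exon][keep])
    )
    red <- GenomicRanges::reduce(exon_gr)
    exonic <- tibble(
      gene_id = as.character(GenomicRanges::seqnames(red)),
      w = GenomicRanges::width(red)
    ) |>
      group_by(.data$gene_id) |>
      summarise(exonic_length = as.integer(sum(.data$w)))
  }

  genes <- genes |> left_join(exonic, by = "gene_id")
  no_exons <- is.na(genes$exonic_length)
  if (any(no_exons)) {
    warn(paste0(sum(no_exons),
                " gene(s) without annotated exons; exonic_length set to span length"))
    genes$exonic_length[no_exons] <-
      as.integer(genes$end[no_exons] - genes$start[no_exons] + 1L)
  }

  genes |>
    mutate(class = classify_chromosome(.data$chrom, config)) |>
    select("gene_id", "chrom", "class", "start", "end", "strand",
           "exonic_length") |>
    arrange(.data$chrom, .data$start)
}

#' Read binding-site intervals from a BED file
#'
#' Reads a BED3+ file (0-based, half-open) and converts to the package's
#' 1-based inclusive coordinates. An empty file yields an empty tibble.
#'
#' @param path Path to a BED file.
#' @param component Label attached to the intervals, one of
#'   `"MLE"`, `"MSL1"`, `"MSL2"`, `"MSL3"`, `"MOF"`, `"HAS"` (free-form
#'   labels are allowed for non-DCC uses).
#' @return A tibble with columns `component`, `chrom`, `start`, `end`,
#'   sorted by `(chrom, start)`.
#' @export
read_sites_bed <- function(path, component = "MLE") {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0) {
    return(tibble(component = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("malformed BED line (fewer than 3 fields) at line ",
                 which(nf < 3)[1]))
  }
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start0) || anyNA(end0)) {
    abort(paste0("non-numeric BED coordinate at line ",
                 which(is.na(start0) | is.na(end0))[1]))
  }
  bad <- start0 >= end0
  if (any(bad)) {
    abort(paste0("BED interval with start >= end at line ", which(bad)[1]))
  }
  tibble(
    component = component,
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(start0 + 1),
    end = as.integer(end0)
  ) |>
    arrange(.data$chrom, .data$start)
}

#' Write binding-site intervals to a BED file
#'
#' Inverse of [read_sites_bed()]: internal 1-based inclusive intervals are
#' written as 0-based half-open BED3.
#'
#' @param sites Tibble with columns `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  lines <- sprintf("%s\t%d\t%d", sites$chrom, sites$start - 1L, sites$end)
  writeLines(lines, path)
  invisible(path)
}

#' Write a parsed gene table to TSV
#'
#' @param genes Tibble from [read_gene_models()] (or [simulate_genome()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  readr::write_tsv(genes, path)
  invisible(path)
}

# Convert a gene/site tibble to GRanges (internal).
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end)
  )
}
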