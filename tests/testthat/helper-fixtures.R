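# Shared fixture builders. Everything is generated in code; no binary data.

# Minimal GFF3 with two genes:
#  - gA: two transcripts spanning [100,200] and [150,300] (span 100..300),
#        exons [100,119],[180,200] and [150,300] -> union 20+151 = 171
#  - gB: single transcript, single exon [10,19] on 2L
write_fixture_gff <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    "X\ttest\tgene\t100\t300\t.\t+\t.\tID=gA",
    "X\ttest\tmRNA\t100\t200\t.\t+\t.\tID=gA.t1;Parent=gA",
    "X\ttest\texon\t100\t119\t.\t+\t.\tID=gA.t1.e1;Parent=gA.t1",
    "X\ttest\texon\t180\t200\t.\t+\t.\tID=gA.t1.e2;Parent=gA.t1",
    "X\ttest\tmRNA\t150\t300\t.\t+\t.\tID=gA.t2;Parent=gA",
    "X\ttest\texon\t150\t300\t.\t+\t.\tID=gA.t2.e1;Parent=gA.t2",
    "2L\ttest\tgene\t10\t19\t.\t-\t.\tID=gB",
    "2L\ttest\tmRNA\t10\t19\t.\t-\t.\tID=gB.t1;Parent=gB",
    "2L\ttest\texon\t10\t19\t.\t-\t.\tID=gB.t1.e1;Parent=gB.t1"
  ), path)
  path
}

# Site tibble from a compact matrix-like spec.
make_sites <- function(starts, ends, chrom = "X", component = "MLE") {
  tibble::tibble(component = component, chrom = chrom,
                 start = as.integer(starts), end = as.integer(ends))
}

make_genes <- function(starts, ends, chrom = "X",
                       ids = sprintf("g%03d", seq_along(starts))) {
  tibble::tibble(gene_id = ids, chrom = chrom,
                 class = ifelse(chrom == "X", "X", "AUTOSOME"),
                 start = as.integer(starts), end = as.integer(ends),
                 strand = "+",
                 exonic_length = as.integer(ends) - as.integer(starts) + 1L)
}

# Brute-force four-endpoint minimum distance (the literal rule), used as
# the oracle for min_site_distance.
brute_min_distance <- function(genes, sites) {
  vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    s <- sites[sites$chrom == g$chrom, ]
    d <- vapply(seq_len(nrow(s)), function(j) {
      if (s$start[j] <= g$end && s$end[j] >= g$start) return(0L)
      min(abs(c(s$start[j] - g$start, s$start[j] - g$end,
                s$end[j] - g$start, s$end[j] - g$end)))
    }, integer(1))
    as.integer(min(d))
  }, integer(1))
}

# Step-up BH oracle written independently of p.adjust.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Exact two-sided Fisher p by enumeration over all tables with the
# observed margins (probability-mass rule).
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
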