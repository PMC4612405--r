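#' RPM-normalized transmission rate from raw window counts
#'
#' Core estimator algebra, exposed for direct use: counts are normalized to
#' reads per million (RPM) with each library's own mapped-read total, and the
#' rate is the receptor share of the total donor-attributable signal,
#' `RPM_receptor / (RPM_receptor + RPM_donor)`.  The rate is invariant under
#' scaling both library totals by one factor, lies in `[0, 1]`, and is `NA`
#' when both counts are zero (undefined, not silently 0).
#'
#' @param count_receptor,count_donor Raw donor-origin read counts in the
#'   receptor and donor libraries.
#' @param total_receptor,total_donor Mapped-read totals of the two libraries.
#' @return Numeric vector of rates in `[0, 1]` (or `NA` where undefined).
#' @export
transmission_rate <- function(count_receptor, total_receptor, count_donor,
                              total_donor) {
  if (any(c(total_receptor, total_donor) <= 0))
    stop("library totals must be positive")
  rpm_r <- count_receptor / total_receptor * 1e6
  rpm_d <- count_donor / total_donor * 1e6
  ifelse(rpm_r + rpm_d == 0, NA_real_, rpm_r / (rpm_r + rpm_d))
}

#' Per-SNP transmission rates in windows around diagnostic loci
#'
#' For each diagnostic locus a transmission window is built, centered at the
#' locus and extended left and right by one read length (clipped at contig
#' bounds and flagged when clipped).  Donor-origin reads whose alignments lie
#' entirely within the window are counted separately in the receptor and
#' donor tissue libraries, converted to RPM with each library's mapped total,
#' and combined into a per-locus rate.
#'
#' Two window-membership rules are available.  The default, `"informative"`,
#' additionally requires the read to cover the locus with the donor allele —
#' reads not covering the SNP match both haplotypes and cannot be attributed
#' to the donor (such reads are automatically contained in the window).
#' `"contained"` counts every read that perfectly matches the donor consensus
#' and is contained in the window, whether or not it covers the locus.
#'
#' Loci where both libraries count zero are dropped with a message (the rate
#' is undefined there; this cannot occur for a transmitting gene's loci).
#'
#' @param classified_receptor,classified_donor [classify_reads()] results for
#'   the receptor-tissue and donor-tissue libraries, classified against the
#'   same donor.
#' @param snps [diagnostic_snps()] output (gene-annotated).
#' @param read_length Window extension in bases (the read length).
#' @param genes Optional character vector restricting estimation to these
#'   genes' loci (typically the transmitting genes).
#' @param rule Window-membership rule, `"informative"` (default) or
#'   `"contained"`.
#' @param total_receptor,total_donor Mapped-read totals; default to each
#'   library's alignment count.
#' @param contig_lengths Optional named integer vector for window clipping at
#'   contig ends.
#' @return Data frame with one row per (locus, gene): `gene_id`, `contig`,
#'   `pos`, `window_start`, `window_end`, `clipped`, `count_receptor`,
#'   `count_donor`, `rpm_receptor`, `rpm_donor`, `rate`.
#' @export
snp_transmission_rates <- function(classified_receptor, classified_donor,
                                   snps, read_length, genes = NULL,
                                   rule = c("informative", "contained"),
                                   total_receptor = NULL, total_donor = NULL,
                                   contig_lengths = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(classified_receptor, "classified_reads"),
            inherits(classified_donor, "classified_reads"))
  if (is.null(total_receptor)) total_receptor <- classified_receptor$library_total
  if (is.null(total_donor)) total_donor <- classified_donor$library_total
  if (total_receptor <= 0 || total_donor <= 0)
    stop("library totals must be positive")

  loci <- snps[!is.na(snps$gene_id), , drop = FALSE]
  if (!is.null(genes)) loci <- loci[loci$gene_id %in% genes, , drop = FALSE]
  empty <- data.frame(gene_id = character(0), contig = character(0),
                      pos = integer(0), window_start = integer(0),
                      window_end = integer(0), clipped = logical(0),
                      count_receptor = integer(0), count_donor = integer(0),
                      rpm_receptor = numeric(0), rpm_donor = numeric(0),
                      rate = numeric(0), stringsAsFactors = FALSE)
  if (nrow(loci) == 0L) return(empty)

  ws <- loci$pos - read_length
  we <- loci$pos + read_length
  clipped <- ws < 1L
  ws <- pmax(ws, 1L)
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[loci$contig]
    clipped <- clipped | we > lim
    we <- pmin(we, lim)
  }

  count_in_windows <- function(classified) {
    out <- integer(nrow(loci))
    if (rule == "informative") {
      lp <- classified$loci
      donor_rows <- which(classified$reads$label == "donor")
      lp <- lp[lp$row %in% donor_rows & lp$allele_class == "donor", ,
               drop = FALSE]
      if (nrow(lp) == 0L) return(out)
      # a read covering its locus is always contained in that locus' window
      cnt <- as.data.table(lp)[, .N, by = .(contig, pos)]
      m <- cnt[data.table(contig = loci$contig, pos = loci$pos),
               on = c("contig", "pos")]
      out <- fifelse(is.na(m$N), 0L, m$N)
    } else {
      rd <- classified$reads
      keep <- which(rd$nm_donor == 0L)
      if (length(keep) == 0L) return(out)
      for (ct in unique(loci$contig)) {
        li <- which(loci$contig == ct)
        ri <- keep[rd$contig[keep] == ct]
        if (length(ri) == 0L) next
        ov <- IRanges::findOverlaps(
          IRanges::IRanges(rd$start[ri], width = nchar(rd$seq[ri])),
          IRanges::IRanges(ws[li], we[li]), type = "within")
        tab <- tabulate(S4Vectors::subjectHits(ov), nbins = length(li))
        out[li] <- tab
      }
    }
    out
  }

  cr <- count_in_windows(classified_receptor)
  cd <- count_in_windows(classified_donor)
  out <- data.frame(gene_id = loci$gene_id, contig = loci$contig,
                    pos = loci$pos, window_start = ws, window_end = we,
                    clipped = clipped, count_receptor = cr, count_donor = cd,
                    rpm_receptor = cr / total_receptor * 1e6,
                    rpm_donor = cd / total_donor * 1e6,
                    rate = transmission_rate(cr, total_receptor, cd,
                                             total_donor),
                    stringsAsFactors = FALSE)
  undef <- is.na(out$rate)
  if (any(undef)) {
    message(sum(undef), " locus/loci with zero donor-attributable signal ",
            "skipped (rate undefined)")
    out <- out[!undef, , drop = FALSE]
  }
  out <- out[order(out$gene_id, out$contig, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Per-gene transmission rates
#'
#' The gene rate is the arithmetic (unweighted) mean of the per-SNP rates
#' across the gene's diagnostic loci.  The donor read total — raw
#' donor-origin reads summed over the gene's windows in the donor library —
#' gates the `reportable` flag: rates from genes with fewer than
#' `min_donor_reads` donor reads are kept but flagged not reportable, to
#' reduce small-sample bias in reported distributions.
#'
#' @param snp_rates [snp_transmission_rates()] output.
#' @param direction Direction label carried into the output.
#' @param min_donor_reads Reporting floor on the donor read total (default
#'   50).
#' @return Data frame with `gene_id`, `direction`, `rate`, `n_snps`,
#'   `donor_reads`, `receptor_reads`, `reportable`.
#' @export
gene_transmission_rates <- function(snp_rates,
                                    direction = "donor_to_receptor",
                                    min_donor_reads = 50L) {
  if (nrow(snp_rates) == 0L) stop("no per-SNP rate records")
  dt <- as.data.table(snp_rates)
  res <- dt[, .(rate = mean(rate), n_snps = .N,
                donor_reads = sum(count_donor),
                receptor_reads = sum(count_receptor)), by = gene_id]
  res[, `:=`(direction = direction,
             reportable = donor_reads >= min_donor_reads)]
  out <- as.data.frame(res[, .(gene_id, direction, rate, n_snps, donor_reads,
                               receptor_reads, reportable)])
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' RPKM gene expression
#'
#' Raw counts are reads overlapping a gene's exons (after alignment filters),
#' normalized to reads per kilobase of exon model per million mapped reads:
#' `RPKM = count * 1e9 / (exon_length * library_total)`.  An optional
#' read-exclusion hook stands in for an upstream rRNA filter.
#'
#' @param aln Alignment table (may contain several libraries).
#' @param gene_models Gene-model table (`gene_id`, `contig`, `start`, `end`);
#'   multiple rows per gene are summed as exons.
#' @param library_totals Optional named vector of mapped-read totals per
#'   library; defaults to each library's (post-exclusion) alignment count.
#' @param exclude_read_ids Optional read ids to drop before counting (e.g.
#'   rRNA-matching reads).
#' @return Data frame with `gene_id`, `library`, `count`, `exon_length`,
#'   `rpkm` for every gene × library combination.
#' @export
rpkm <- function(aln, gene_models, library_totals = NULL,
                 exclude_read_ids = NULL) {
  if (!is.null(exclude_read_ids))
    aln <- aln[!aln$read_id %in% exclude_read_ids, , drop = FALSE]
  libs <- sort(unique(aln$library))
  if (length(libs) == 0L) stop("no alignments")
  if (is.null(library_totals))
    library_totals <- vapply(libs, function(l) sum(aln$library == l), 1L)
  if (any(library_totals <= 0)) stop("zero library total")
  exon_len <- tapply(gene_models$end - gene_models$start + 1L,
                     gene_models$gene_id, sum)
  genes <- sort(unique(gene_models$gene_id))

  counts <- matrix(0L, nrow = length(genes), ncol = length(libs),
                   dimnames = list(genes, libs))
  for (ct in unique(gene_models$contig)) {
    gi <- which(gene_models$contig == ct)
    ai <- which(aln$contig == ct)
    if (length(ai) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(aln$start[ai], width = nchar(aln$seq[ai])),
      IRanges::IRanges(gene_models$start[gi], gene_models$end[gi]))
    if (length(ov) == 0L) next
    hits <- unique(data.frame(
      read = ai[S4Vectors::queryHits(ov)],
      gene = gene_models$gene_id[gi][S4Vectors::subjectHits(ov)]))
    tab <- table(hits$gene, aln$library[hits$read])
    counts[rownames(tab), colnames(tab)] <-
      counts[rownames(tab), colnames(tab), drop = FALSE] + as.matrix(tab)
  }
  out <- data.frame(
    gene_id = rep(genes, times = length(libs)),
    library = rep(libs, each = length(genes)),
    count = as.vector(counts),
    exon_length = rep(as.integer(exon_len[genes]), times = length(libs)),
    stringsAsFactors = FALSE)
  out$rpkm <- out$count * 1e9 /
    (out$exon_length * as.numeric(library_totals[out$library]))
  out <- out[order(out$library, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Distribution summary of gene transmission rates
#'
#' Reports, over reportable genes only, the fractions of genes with rates
#' below 0.01, below 0.001 and above 0.5, a histogram at configurable bin
#' edges, and (rate, log10 donor reads) scatter pairs.
#'
#' @param gene_rates [gene_transmission_rates()] output.
#' @param edges Histogram bin edges over `[0, 1]`; bins are left-closed,
#'   the last bin closed on both sides.
#' @return List with `n`, `frac_below_0.01`, `frac_below_0.001`,
#'   `frac_above_0.5` (all `NA` when no reportable genes), `histogram`
#'   (`bin_start`, `bin_end`, `count`), `scatter` (`gene_id`, `rate`,
#'   `log10_donor_reads`).
#' @export
rate_distribution <- function(gene_rates,
                              edges = c(0, 0.001, 0.01, 0.05, 0.1, 0.5, 1)) {
  g <- gene_rates[gene_rates$reportable, , drop = FALSE]
  n <- nrow(g)
  hist_df <- data.frame(bin_start = edges[-length(edges)],
                        bin_end = edges[-1L], count = 0L)
  scatter <- data.frame(gene_id = character(0), rate = numeric(0),
                        log10_donor_reads = numeric(0),
                        stringsAsFactors = FALSE)
  if (n == 0L)
    return(list(n = 0L, frac_below_0.01 = NA_real_,
                frac_below_0.001 = NA_real_, frac_above_0.5 = NA_real_,
                histogram = hist_df, scatter = scatter))
  bin <- findInterval(g$rate, edges, rightmost.closed = TRUE)
  tab <- tabulate(bin, nbins = nrow(hist_df))
  hist_df$count <- tab
  list(n = n,
       frac_below_0.01 = mean(g$rate < 0.01),
       frac_below_0.001 = mean(g$rate < 0.001),
       frac_above_0.5 = mean(g$rate > 0.5),
       histogram = hist_df,
       scatter = data.frame(gene_id = g$gene_id, rate = g$rate,
                            log10_donor_reads = log10(g$donor_reads),
                            stringsAsFactors = FALSE))
}

#' Correlation of transmission rates between two estimate sets
#'
#' Pearson correlation over genes reportable in both sets, with the list of
#' genes whose rates differ five-fold or more.  A constant set makes the
#' correlation undefined; it is flagged, not silently zero.
#'
#' @param est_1,est_2 [gene_transmission_rates()] outputs.
#' @param fold Fold-difference threshold for the large-difference list
#'   (default 5).
#' @return List with `r`, `n_shared`, `degenerate`, `n_large_diff`, and
#'   `genes` (`gene_id`, `rate_1`, `rate_2`, `fold`, `large_diff`; `fold` is
#'   `Inf` when exactly one rate is zero).
#' @export
rate_correlation <- function(est_1, est_2, fold = 5) {
  a <- est_1[est_1$reportable, c("gene_id", "rate")]
  b <- est_2[est_2$reportable, c("gene_id", "rate")]
  m <- merge(a, b, by = "gene_id", suffixes = c("_1", "_2"))
  if (nrow(m) < 3L)
    stop("insufficient overlap: ", nrow(m), " shared reportable gene(s)")
  degenerate <- stats::sd(m$rate_1) == 0 || stats::sd(m$rate_2) == 0
  r <- if (degenerate) NA_real_ else stats::cor(m$rate_1, m$rate_2)
  hi <- pmax(m$rate_1, m$rate_2)
  lo <- pmin(m$rate_1, m$rate_2)
  m$fold <- ifelse(hi == 0, 1, ifelse(lo == 0, Inf, hi / lo))
  m$large_diff <- m$fold >= fold
  m <- m[order(m$gene_id), ]
  rownames(m) <- NULL
  list(r = r, n_shared = nrow(m), degenerate = degenerate,
       n_large_diff = sum(m$large_diff), genes = m)
}
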