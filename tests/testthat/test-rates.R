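test_that("transmission-rate algebra behaves as specified", {
  # symmetric counts and library sizes -> 0.5
  expect_equal(transmission_rate(100L, 1e6, 100L, 1e6), 0.5)
  # direct arithmetic on the formula
  expect_equal(transmission_rate(10L, 1e6, 990L, 1e6), 0.01)
  # zero receptor signal -> 0; zero signal everywhere -> undefined
  expect_equal(transmission_rate(0L, 1e6, 50L, 1e6), 0)
  expect_true(is.na(transmission_rate(0L, 1e6, 0L, 1e6)))
  # invariance under joint scaling of both library totals
  expect_equal(transmission_rate(7L, 2e6, 31L, 4e6),
               transmission_rate(7L, 2e7, 31L, 4e7))
  # doubling only the receptor total strictly decreases the rate
  expect_lt(transmission_rate(10L, 2e6, 990L, 1e6),
            transmission_rate(10L, 1e6, 990L, 1e6))
  expect_error(transmission_rate(1L, 0, 1L, 1e6), "positive")
})

test_that("gene rates are unweighted means of per-SNP rates", {
  snp_rates <- data.frame(
    gene_id = c("g1", "g2", "g2"), contig = "chr1",
    pos = c(10L, 50L, 70L), window_start = 1L, window_end = 200L,
    clipped = FALSE, count_receptor = c(5L, 2L, 4L),
    count_donor = c(45L, 38L, 16L), rpm_receptor = 1, rpm_donor = 1,
    rate = c(0.5, 0.2, 0.4), stringsAsFactors = FALSE)
  out <- gene_transmission_rates(snp_rates, min_donor_reads = 50L)
  expect_equal(out$rate[out$gene_id == "g1"], 0.5)
  expect_equal(out$rate[out$gene_id == "g2"], 0.3)
  expect_equal(out$donor_reads[out$gene_id == "g2"], 54L)
  expect_identical(out$reportable, c(FALSE, TRUE))
  expect_error(gene_transmission_rates(snp_rates[0, ]), "no per-SNP")
})

test_that("window counts respect the membership rule and the window bounds", {
  fx_ref <- c(chr1 = random_dna(600L))
  don <- strsplit(fx_ref[[1]], "")[[1]]
  don[300L] <- chartr("ACGT", "GTAC", don[300L])
  donor_hap <- c(chr1 = paste(don, collapse = ""))
  snps <- make_snps(pos = 300L, allele_1 = substring(fx_ref[[1]], 300L, 300L),
                    allele_2 = don[300L], ref = substring(fx_ref[[1]], 300L, 300L),
                    gene_id = "g1")
  consensi <- list(A = fx_ref, B = donor_hap)
  R <- 40L
  don_sub <- function(s) substring(donor_hap[[1]], s, s + R - 1L)
  # receptor library: one read covering the SNP, one perfect-donor read in
  # the window but not covering the SNP, one outside the window
  # window is [260, 340]; the "nocov" read (301..340) sits inside it without
  # covering the SNP at 300, the "out" read lies outside entirely
  rec_aln <- make_aln(c(don_sub(280L), don_sub(301L), don_sub(500L)),
                      c(280L, 301L, 500L), read_id = c("cov", "nocov", "out"))
  don_aln <- make_aln(don_sub(290L), 290L, read_id = "d1")
  cls_r <- classify_reads(rec_aln, snps, consensi, donor = "B")
  cls_d <- classify_reads(don_aln, snps, consensi, donor = "B")
  informative <- snp_transmission_rates(cls_r, cls_d, snps, read_length = R,
                                        contig_lengths = nchar(fx_ref))
  expect_equal(informative$count_receptor, 1L)  # only the SNP-covering read
  expect_equal(informative$count_donor, 1L)
  contained <- snp_transmission_rates(cls_r, cls_d, snps, read_length = R,
                                      rule = "contained",
                                      contig_lengths = nchar(fx_ref))
  # the non-covering perfect-donor read inside [260, 340] now counts
  expect_equal(contained$count_receptor, 2L)
  expect_false(informative$clipped)
  # windows at the contig edge are clipped and flagged
  snps_edge <- make_snps(pos = 20L, allele_1 = "A", allele_2 = "C",
                         ref = "A", gene_id = "g1")
  suppressMessages(
    edge <- snp_transmission_rates(cls_r, cls_d, snps_edge, read_length = R,
                                   contig_lengths = nchar(fx_ref)))
  # no donor signal at that locus -> record skipped entirely
  expect_equal(nrow(edge), 0L)
})

test_that("rpkm matches hand-computed unit cases", {
  genes <- data.frame(gene_id = "g1", contig = "chr1", start = 1001L,
                      end = 2000L, strand = "+", stringsAsFactors = FALSE)
  aln <- make_aln(rep(strrep("A", 50L), 3L), c(1001L, 1500L, 1951L),
                  read_id = c("r1", "r2", "r3"))
  out <- rpkm(aln, genes, library_totals = c(lib = 1e6))
  expect_equal(out$count, 3L)
  expect_equal(out$rpkm, 3 * 1e9 / (1000 * 1e6))
  # 1000 reads, 1 kb exon, 1 M mapped -> RPKM 1000 (scaled by count)
  expect_equal(1000 * 1e9 / (1000 * 1e6), 1000)
  # zero-count genes appear with RPKM 0
  genes2 <- rbind(genes, data.frame(gene_id = "g2", contig = "chr1",
                                    start = 5000L, end = 5999L, strand = "+"))
  out2 <- rpkm(aln, genes2, library_totals = c(lib = 1e6))
  expect_equal(out2$rpkm[out2$gene_id == "g2"], 0)
  expect_error(rpkm(aln, genes, library_totals = c(lib = 0)), "zero library")
})

test_that("rpkm agrees with a brute-force recount on random instances", {
  set.seed(23)
  for (i in 1:10) {
    n_genes <- sample(2:4, 1L)
    genes <- data.frame(
      gene_id = sprintf("g%d", seq_len(n_genes)), contig = "chr1",
      start = cumsum(sample(100:200, n_genes)),
      strand = "+", stringsAsFactors = FALSE)
    genes$end <- genes$start + sample(50:150, n_genes)
    n <- sample(10:40, 1L)
    aln <- make_aln(vapply(seq_len(n), function(i) random_dna(20L), ""),
                    sample.int(800L, n, replace = TRUE),
                    library = sample(c("l1", "l2"), n, replace = TRUE),
                    read_id = sprintf("r%03d", seq_len(n)))
    totals <- c(l1 = 1000, l2 = 2000)
    got <- rpkm(aln, genes, library_totals = totals)
    want <- oracle_rpkm(aln, genes, totals)
    expect_equal(got[, c("gene_id", "library", "count", "rpkm")], want,
                 ignore_attr = TRUE)
  }
})

test_that("rate distributions summarize reportable genes only", {
  gr <- data.frame(gene_id = sprintf("g%d", 1:4), direction = "d",
                   rate = c(0.005, 0.005, 0.6, 0.0005),
                   n_snps = 1L, donor_reads = c(100L, 100L, 100L, 10L),
                   receptor_reads = 1L,
                   reportable = c(TRUE, TRUE, TRUE, FALSE),
                   stringsAsFactors = FALSE)
  d <- rate_distribution(gr)
  expect_equal(d$n, 3L)
  expect_equal(d$frac_below_0.01, 2 / 3)
  expect_equal(d$frac_above_0.5, 1 / 3)
  expect_equal(sum(d$histogram$count), 3L)
  # all rates below 0.01
  d1 <- rate_distribution(gr[gr$rate < 0.01 & gr$reportable, ])
  expect_equal(d1$frac_below_0.01, 1)
  # empty input: no division by zero, NA fractions
  d0 <- rate_distribution(gr[0, ])
  expect_equal(d0$n, 0L)
  expect_true(is.na(d0$frac_below_0.01))
})

test_that("rate correlations flag degeneracy and insufficient overlap", {
  gr <- function(rates, genes = sprintf("g%d", seq_along(rates))) data.frame(
    gene_id = genes, direction = "d", rate = rates, n_snps = 1L,
    donor_reads = 100L, receptor_reads = 1L, reportable = TRUE,
    stringsAsFactors = FALSE)
  a <- gr(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(rate_correlation(a, a)$r, 1)
  const <- gr(rep(0.2, 4L))
  out <- rate_correlation(a, const)
  expect_true(out$degenerate)
  expect_true(is.na(out$r))
  expect_error(rate_correlation(a[1:2, ], a[1:2, ]), "insufficient overlap")
  # five-fold differences are listed, zeros flagged as infinite fold
  b <- gr(c(0.5, 0.2, 0.3, 0))
  fc <- rate_correlation(a, b)
  expect_equal(fc$n_large_diff, 2L)
  expect_true(is.infinite(fc$genes$fold[fc$genes$gene_id == "g4"]))
})
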