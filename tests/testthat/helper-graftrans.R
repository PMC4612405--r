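# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (loops, exhaustive enumeration) and share no
# code with the implementation paths they check.

tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(genome_length = 30000L, n_genes = 8L, exon_length = 900L,
                   snp_density = 3, diagnostic_fraction = 0.6,
                   read_length = 101L, genomic_depth = 20,
                   rnaseq_reads_per_library = 12000L, error_rate = 0,
                   duplication_rate = 0, seed = 101L)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# brute-force per-position base tally
oracle_pileup <- function(aln) {
  acc <- list()
  for (i in seq_len(nrow(aln))) {
    bases <- strsplit(aln$seq[i], "")[[1]]
    for (j in seq_along(bases)) {
      if (!bases[j] %in% c("A", "C", "G", "T")) next
      key <- paste(aln$library[i], aln$contig[i], aln$start[i] + j - 1L)
      if (is.null(acc[[key]]))
        acc[[key]] <- c(A = 0L, C = 0L, G = 0L, T = 0L)
      acc[[key]][bases[j]] <- acc[[key]][bases[j]] + 1L
    }
  }
  if (length(acc) == 0L)
    return(data.frame(library = character(0), contig = character(0),
                      pos = integer(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0)))
  parts <- strsplit(names(acc), " ")
  out <- data.frame(
    library = vapply(parts, `[`, "", 1L),
    contig = vapply(parts, `[`, "", 2L),
    pos = as.integer(vapply(parts, `[`, "", 3L)),
    A = vapply(acc, `[[`, 0L, "A"), C = vapply(acc, `[[`, 0L, "C"),
    G = vapply(acc, `[[`, 0L, "G"), T = vapply(acc, `[[`, 0L, "T"),
    stringsAsFactors = FALSE)
  out <- out[order(out$library, out$contig, out$pos, method = "radix"), ]
  rownames(out) <- NULL
  out
}

# exhaustive evaluation of the three transmitting-gene rules over evidence
# pairs (read_key, gene_id, pos): enumerates reads and read pairs directly
oracle_criteria <- function(pairs) {
  out <- list()
  for (g in sort(unique(pairs$gene_id))) {
    p <- unique(pairs[pairs$gene_id == g, c("read_key", "pos")])
    reads <- unique(p$read_key)
    cov <- lapply(reads, function(r) unique(p$pos[p$read_key == r]))
    names(cov) <- reads
    a <- FALSE; b <- FALSE; c <- FALSE
    for (r in reads) if (length(cov[[r]]) >= 2L) a <- TRUE
    for (l in unique(p$pos))
      if (sum(vapply(cov, function(x) l %in% x, TRUE)) >= 2L) b <- TRUE
    if (length(reads) >= 2L)
      for (r1 in reads) for (r2 in reads)
        if (r1 != r2)
          for (l1 in cov[[r1]]) for (l2 in cov[[r2]])
            if (l1 != l2) c <- TRUE
    out[[g]] <- list(a = a, b = b, c = c, transmitting = a || b || c)
  }
  out
}

# brute-force RPKM recount
oracle_rpkm <- function(aln, gene_models, library_totals) {
  res <- list()
  for (lib in sort(unique(aln$library))) {
    for (g in sort(unique(gene_models$gene_id))) {
      ex <- gene_models[gene_models$gene_id == g, , drop = FALSE]
      len <- sum(ex$end - ex$start + 1L)
      cnt <- 0L
      for (i in which(aln$library == lib)) {
        e <- aln$start[i] + nchar(aln$seq[i]) - 1L
        hit <- FALSE
        for (k in seq_len(nrow(ex)))
          if (aln$contig[i] == ex$contig[k] && aln$start[i] <= ex$end[k] &&
              e >= ex$start[k]) hit <- TRUE
        if (hit) cnt <- cnt + 1L
      }
      res[[paste(lib, g)]] <- data.frame(
        gene_id = g, library = lib, count = cnt,
        rpkm = cnt * 1e9 / (len * library_totals[[lib]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

# random micro-instance of evidence pairs for rule testing
random_evidence_instance <- function(n_genes = 2L, max_reads = 50L,
                                     max_loci = 10L) {
  n_loci <- sample.int(max_loci, 1L)
  loci <- sort(sample.int(5000L, n_loci))
  gene_of_locus <- sample(sprintf("g%02d", seq_len(n_genes)), n_loci,
                          replace = TRUE)
  n_reads <- sample.int(max_reads, 1L)
  rows <- list()
  for (r in seq_len(n_reads)) {
    k <- sample.int(min(3L, n_loci), 1L)
    cov <- sample.int(n_loci, k)
    rows[[r]] <- data.frame(read_key = sprintf("r%03d", r),
                            gene_id = gene_of_locus[cov], pos = loci[cov],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# alignment-table constructor for hand-built scenarios
make_aln <- function(seqs, starts, contig = "chr1", strand = "+",
                     library = "lib", read_id = NULL, nm = 0L) {
  n <- length(seqs)
  data.frame(
    read_id = if (is.null(read_id)) sprintf("r%03d", seq_len(n)) else read_id,
    library = rep_len(library, n), contig = rep_len(contig, n),
    start = as.integer(starts), strand = rep_len(strand, n), seq = seqs,
    nm = rep_len(as.integer(nm), n), stringsAsFactors = FALSE)
}

# hand-built diagnostic-SNP table
make_snps <- function(pos, allele_1, allele_2, ref = NA_character_,
                      gene_id = NA_character_, contig = "chr1",
                      genotype_1 = "A", genotype_2 = "B") {
  n <- length(pos)
  data.frame(contig = rep_len(contig, n), pos = as.integer(pos),
             ref = rep_len(ref, n),
             genotype_1 = rep_len(genotype_1, n), allele_1 = allele_1,
             depth_1 = rep_len(10L, n), genotype_2 = rep_len(genotype_2, n),
             allele_2 = allele_2, depth_2 = rep_len(10L, n),
             gene_id = rep_len(gene_id, n), stringsAsFactors = FALSE)
}

# run the standard two-direction analysis on a simulated experiment using
# module functions (alignment -> calls -> snps -> classify/detect/rates)
analyze_sim <- function(sim, cfg, min_donor_reads = 50L) {
  ref <- sim$pair$reference
  aln_g <- lapply(c(A = "A", B = "B"), function(g)
    remove_duplicates(test_align(sim$genomic[[g]], ref,
                                 library_id = paste0("gdna_", g))))
  calls <- lapply(c(A = "A", B = "B"), function(g)
    call_homozygous(pileup(aln_g[[g]]), genotype = g))
  snps <- diagnostic_snps(calls$A, calls$B, reference = ref,
                          gene_models = sim$pair$genes)
  consensi <- lapply(calls, function(cl) consensus_haplotype(ref, cl))
  rna <- lapply(c(scion = "scion", rootstock = "rootstock"), function(tt)
    test_align(sim$rna[[tt]], ref, library_id = paste0("rna_", tt)))
  out <- list(snps = snps, calls = calls, consensi = consensi, rna = rna)
  for (receptor in c("scion", "rootstock")) {
    donor_tissue <- setdiff(c("scion", "rootstock"), receptor)
    donor_g <- if (donor_tissue == "scion") "A" else "B"
    lab <- paste0(donor_tissue, "_to_", receptor)
    cls_r <- classify_reads(rna[[receptor]], snps, consensi, donor = donor_g)
    cls_d <- classify_reads(rna[[donor_tissue]], snps, consensi,
                            donor = donor_g)
    ev <- detect_transmitting_genes(cls_r, snps, direction = lab)
    sr <- snp_transmission_rates(cls_r, cls_d, snps,
                                 read_length = cfg$read_length,
                                 genes = ev$gene_id[ev$transmitting],
                                 contig_lengths = nchar(ref))
    out$evidence[[lab]] <- ev
    out$gene_rates[[lab]] <- if (nrow(sr) > 0L)
      gene_transmission_rates(sr, direction = lab,
                              min_donor_reads = min_donor_reads)
    else NULL
  }
  out
}
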