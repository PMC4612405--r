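test_that("test_align recovers error-free reads at their true coordinates", {
  cfg <- tiny_cfg(genome_length = 15000L, n_genes = 2L, genomic_depth = 10)
  pair <- make_genotype_pair(cfg)
  reads <- simulate_genomic_reads(pair$reference, cfg)
  aln <- test_align(reads, pair$reference, library_id = "t")
  # only reads whose sequence occurs once in the genome can be placed
  m <- merge(reads, aln, by = "read_id")
  expect_gte(nrow(m) / nrow(reads), 0.999)
  expect_identical(m$start, m$true_start)
  expect_identical(m$strand, m$true_strand)
  expect_true(all(m$nm == 0L))
})

test_that("reads matching two genome positions equally are dropped", {
  block <- random_dna(101L)
  ref <- c(chr1 = paste0(random_dna(200L), block, random_dna(300L), block,
                         random_dna(200L)))
  hit <- test_align(data.frame(read_id = "amb", seq = block), ref)
  expect_equal(nrow(hit), 0L)
  # the same read against a single-copy genome aligns fine
  ref1 <- c(chr1 = paste0(random_dna(200L), block, random_dna(300L)))
  hit1 <- test_align(data.frame(read_id = "uni", seq = block), ref1)
  expect_equal(hit1$start, 201L)
})

test_that("reads beyond the edit threshold stay unaligned", {
  ref <- c(chr1 = random_dna(2000L))
  read <- substring(ref[[1]], 301L, 401L)
  # plant max_edit + 1 = 5 mismatches
  s <- strsplit(read, "")[[1]]
  at <- c(5L, 25L, 45L, 65L, 85L)
  s[at] <- chartr("ACGT", "GTAC", s[at])
  mutated <- paste(s, collapse = "")
  expect_equal(nrow(test_align(data.frame(read_id = "x", seq = mutated), ref,
                               max_edit = 4L)), 0L)
  # at the threshold itself the read aligns
  s4 <- strsplit(read, "")[[1]]
  s4[at[1:4]] <- chartr("ACGT", "GTAC", s4[at[1:4]])
  aln <- test_align(data.frame(read_id = "y", seq = paste(s4, collapse = "")),
                    ref, max_edit = 4L)
  expect_equal(aln$start, 301L)
  expect_equal(aln$nm, 4L)
})

test_that("SAM round trip preserves alignments, tags and filters", {
  cfg <- tiny_cfg(genome_length = 8000L, n_genes = 2L, exon_length = 400L,
                  genomic_depth = 4, error_rate = 0.005)
  pair <- make_genotype_pair(cfg)
  reads <- simulate_genomic_reads(pair$hap_B, cfg)
  aln <- test_align(reads, pair$reference, library_id = "lib")
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, pair$reference, sam)
  back <- read_sam(sam, library_id = "lib", reference = pair$reference)
  key <- function(df) df[order(df$read_id), c("read_id", "contig", "start",
                                              "strand", "seq", "nm")]
  expect_equal(key(back), key(aln), ignore_attr = TRUE)
  # NM recomputed from the reference equals the stored tag
  back_tag <- read_sam(sam, library_id = "lib")
  expect_identical(key(back_tag)$nm, key(aln)$nm)
})

test_that("unmapped and NM-less records are handled as specified", {
  ref <- c(chr1 = random_dna(500L))
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:500",
    paste0("mapped\t0\tchr1\t11\t60\t20M\t*\t0\t0\t",
           substring(ref[[1]], 11L, 30L), "\t", strrep("I", 20L), "\tNM:i:0"),
    paste0("unmapped\t4\t*\t0\t0\t*\t*\t0\t0\t", random_dna(20L), "\t",
           strrep("I", 20L))), sam)
  aln <- read_sam(sam, reference = ref)
  expect_identical(aln$read_id, "mapped")
  expect_identical(aln$nm, 0L)
  # no NM tag and no reference is an error, with reference it recomputes
  sam2 <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:500",
    paste0("r1\t0\tchr1\t11\t60\t20M\t*\t0\t0\t",
           substring(ref[[1]], 11L, 30L), "\t", strrep("I", 20L))), sam2)
  expect_error(read_sam(sam2), "cannot derive mismatches")
  expect_identical(read_sam(sam2, reference = ref)$nm, 0L)
})

test_that("one planted mismatch is recovered at its reference position", {
  ref <- c(chr1 = random_dna(300L))
  seq <- substring(ref[[1]], 101L, 140L)
  s <- strsplit(seq, "")[[1]]
  s[17L] <- chartr("ACGT", "GTAC", s[17L])
  aln <- make_aln(paste(s, collapse = ""), 101L, nm = 1L)
  mism <- alignment_mismatches(aln, ref)
  expect_equal(nrow(mism), 1L)
  expect_equal(mism$pos, 117L)
  expect_identical(mism$ref_base, substring(ref[[1]], 117L, 117L))
})

test_that("duplicate removal keys on (library, contig, start, strand)", {
  a <- make_aln(c("ACGT", "ACGT", "ACGT"), c(10L, 10L, 10L),
                strand = c("+", "+", "-"),
                read_id = c("b", "a", "c"))
  out <- remove_duplicates(a)
  expect_equal(nrow(out), 2L)
  # representative is the lexicographically smallest read id
  expect_identical(out$read_id[out$strand == "+"], "a")
  expect_identical(out$read_id[out$strand == "-"], "c")
  # idempotent
  expect_identical(remove_duplicates(out), out)
  # different libraries are kept apart
  b <- make_aln(c("ACGT", "ACGT"), c(10L, 10L), library = c("l1", "l2"))
  expect_equal(nrow(remove_duplicates(b)), 2L)
})

test_that("pileup counts match hand-checked columns", {
  a1 <- make_aln("ACGT", 1L)
  p1 <- pileup(a1)
  expect_equal(nrow(p1), 4L)
  expect_identical(p1$pos, 1:4)
  expect_identical(as.integer(diag(as.matrix(p1[, c("A", "C", "G", "T")]))),
                   rep(1L, 4L))
  a7 <- make_aln(rep("AA", 7L), rep(5L, 7L),
                 read_id = sprintf("r%d", 1:7))
  p7 <- pileup(a7)
  expect_identical(p7$A, c(7L, 7L))
  expect_identical(p7$C + p7$G + p7$T, c(0L, 0L))
})

test_that("pileup agrees with a brute-force tally on random instances", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(3:25, 1L)
    aln <- make_aln(
      vapply(seq_len(n), function(i) random_dna(sample(4:12, 1L)), ""),
      sample.int(40L, n, replace = TRUE),
      library = sample(c("x", "y"), n, replace = TRUE),
      read_id = sprintf("r%03d", seq_len(n)))
    expect_equal(pileup(aln), oracle_pileup(aln), ignore_attr = TRUE)
  }
})

test_that("pileup column sums equal the number of covering reads", {
  cfg <- tiny_cfg(genome_length = 5000L, n_genes = 1L, exon_length = 300L,
                  genomic_depth = 8)
  pair <- make_genotype_pair(cfg)
  aln <- test_align(simulate_genomic_reads(pair$hap_A, cfg), pair$reference)
  p <- pileup(aln)
  tot <- rowSums(p[, c("A", "C", "G", "T")])
  covering <- vapply(seq_len(nrow(p)), function(i)
    sum(aln$start <= p$pos[i] & aln$start + nchar(aln$seq) - 1L >= p$pos[i]),
    1L)
  expect_identical(as.integer(tot), covering)
})
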