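# A hand-built two-locus scenario: the receptor genotype equals the
# reference; the donor differs at diagnostic loci 150 and 170.
mobility_fixture <- function() {
  set.seed(5)
  ref <- c(chr1 = random_dna(400L))
  don <- strsplit(ref[[1]], "")[[1]]
  don[150L] <- chartr("ACGT", "GTAC", don[150L])
  don[170L] <- chartr("ACGT", "GTAC", don[170L])
  donor_hap <- c(chr1 = paste(don, collapse = ""))
  snps <- make_snps(pos = c(150L, 170L),
                    allele_1 = substring(ref[[1]], c(150L, 170L),
                                         c(150L, 170L)),
                    allele_2 = c(don[150L], don[170L]),
                    ref = substring(ref[[1]], c(150L, 170L), c(150L, 170L)),
                    gene_id = "g1", genotype_1 = "A", genotype_2 = "B")
  list(ref = ref, donor_hap = donor_hap, snps = snps,
       consensi = list(A = ref, B = donor_hap))
}

test_that("read classification follows the perfect-match and allele rules", {
  fx <- mobility_fixture()
  don_sub <- function(s, e) substring(fx$donor_hap[[1]], s, e)
  ref_sub <- function(s, e) substring(fx$ref[[1]], s, e)
  # donor alleles at both loci, perfect donor match -> donor-origin
  r_don <- don_sub(140L, 179L)
  # no diagnostic locus covered -> uninformative
  r_unif <- don_sub(200L, 239L)
  # donor allele at locus 150 but an extra mismatch elsewhere -> rejected
  s <- strsplit(don_sub(140L, 179L), "")[[1]]
  s[5L] <- chartr("ACGT", "GTAC", s[5L])
  r_imperfect <- paste(s, collapse = "")
  # donor allele at 150, receptor allele at 170 -> conflicted
  r_chim <- paste0(don_sub(140L, 159L), ref_sub(160L, 179L))
  # receptor alleles throughout, matches receptor -> receptor-origin
  r_rec <- ref_sub(140L, 179L)
  aln <- make_aln(c(r_don, r_unif, r_imperfect, r_chim, r_rec),
                  c(140L, 200L, 140L, 140L, 140L),
                  read_id = c("don", "unif", "imp", "chim", "rec"))
  cls <- classify_reads(aln, fx$snps, fx$consensi, donor = "B")
  lab <- setNames(cls$reads$label, cls$reads$read_id)
  expect_identical(lab[["don"]], "donor")
  expect_identical(lab[["unif"]], "uninformative")
  expect_identical(lab[["imp"]], "uninformative")
  expect_identical(lab[["chim"]], "conflicted")
  expect_identical(lab[["rec"]], "receptor")
  expect_equal(cls$reads$nm_donor[cls$reads$read_id == "don"], 0L)
})

test_that("the three transmitting-gene rules fire on their defining patterns", {
  fx <- mobility_fixture()
  don_sub <- function(s, e) substring(fx$donor_hap[[1]], s, e)
  classify <- function(aln) classify_reads(aln, fx$snps, fx$consensi,
                                           donor = "B")
  # (a) one read carrying both loci
  ev_a <- detect_transmitting_genes(
    classify(make_aln(don_sub(140L, 179L), 140L)), fx$snps)
  expect_true(ev_a$transmitting)
  expect_identical(ev_a$criteria, "a")
  # a single read over a single locus is not enough
  ev_0 <- detect_transmitting_genes(
    classify(make_aln(don_sub(120L, 159L), 120L)), fx$snps)
  expect_false(ev_0$transmitting)
  expect_identical(ev_0$criteria, "")
  # (b) two unique reads over the same locus
  ev_b <- detect_transmitting_genes(
    classify(make_aln(c(don_sub(120L, 159L), don_sub(130L, 169L)),
                      c(120L, 130L), read_id = c("r1", "r2"))), fx$snps)
  expect_true(ev_b$transmitting)
  expect_true(grepl("b", ev_b$criteria))
  # (c) two unique reads carrying different loci
  ev_c <- detect_transmitting_genes(
    classify(make_aln(c(don_sub(120L, 159L), don_sub(161L, 200L)),
                      c(120L, 161L), read_id = c("r1", "r2"))), fx$snps)
  expect_true(ev_c$transmitting)
  expect_identical(ev_c$criteria, "c")
  # duplicated coordinates do not create "unique" reads
  ev_dupkey <- detect_transmitting_genes(
    classify(make_aln(c(don_sub(120L, 159L), don_sub(120L, 159L)),
                      c(120L, 120L), read_id = c("r1", "r2"))), fx$snps)
  expect_false(ev_dupkey$transmitting)
})

test_that("rule evaluation matches the exhaustive oracle on random instances", {
  set.seed(42)
  for (i in 1:50) {
    inst <- random_evidence_instance()
    got <- detect_transmitting_genes(inst)
    want <- oracle_criteria(inst)
    expect_identical(got$gene_id, names(want))
    for (j in seq_len(nrow(got))) {
      w <- want[[got$gene_id[j]]]
      expect_identical(got$transmitting[j], w$transmitting)
      expect_identical(
        got$criteria[j],
        paste0(c(if (w$a) "a", if (w$b) "b", if (w$c) "c"), collapse = ""))
    }
  }
})

test_that("adding donor-origin reads never revokes a transmitting call", {
  set.seed(99)
  for (i in 1:25) {
    inst <- random_evidence_instance(max_reads = 20L)
    base <- detect_transmitting_genes(inst)
    extra <- random_evidence_instance(max_reads = 5L)
    extra$read_key <- paste0("x", extra$read_key)
    both <- detect_transmitting_genes(rbind(inst, extra))
    for (g in base$gene_id[base$transmitting])
      expect_true(both$transmitting[both$gene_id == g])
    # removing reads never adds a call
    for (g in setdiff(both$gene_id[both$transmitting], base$gene_id[base$transmitting]))
      expect_true(g %in% extra$gene_id || !g %in% base$gene_id ||
                    !base$transmitting[base$gene_id == g])
  }
})

test_that("relabeling donor and receptor swaps direction without changing counts", {
  cfg <- tiny_cfg(transmission_fractions = 0.3, seed = 17L)
  sim <- simulate_graft_experiment(cfg)
  res <- analyze_sim(sim, cfg)
  # genes sourced in A move scion->rootstock, genes sourced in B the reverse;
  # swapping the donor/receptor labels swaps which evidence table holds them
  src <- setNames(sim$pair$genes$source_genotype, sim$pair$genes$gene_id)
  ev_s2r <- res$evidence$scion_to_rootstock
  ev_r2s <- res$evidence$rootstock_to_scion
  expect_true(all(src[ev_s2r$gene_id[ev_s2r$transmitting]] == "A"))
  expect_true(all(src[ev_r2s$gene_id[ev_r2s$transmitting]] == "B"))
})

test_that("direction summaries tally sets and overlaps", {
  ev <- function(genes, dir) data.frame(
    gene_id = genes, direction = rep_len(dir, length(genes)),
    n_reads = rep_len(2L, length(genes)), n_loci = rep_len(1L, length(genes)),
    criteria = rep_len("b", length(genes)),
    transmitting = rep_len(TRUE, length(genes)),
    read_ids = rep_len("r", length(genes)), stringsAsFactors = FALSE)
  empty <- ev(character(0), character(0))
  s0 <- direction_summary(list(g1 = list(up = empty, down = empty)))
  expect_true(all(s0$per_graft$n_genes == 0L))
  s <- direction_summary(list(
    g1 = list(up = ev(c("a", "b", "c"), "up"), down = ev(c("b", "d"), "down")),
    g2 = list(up = ev(c("c", "d"), "up"), down = ev("e", "down"))))
  pg <- s$per_graft
  expect_equal(pg$n_genes[pg$graft == "g1" & pg$direction == "up"], 3L)
  expect_equal(pg$n_genes[pg$graft == "g1" & pg$direction == "both"], 1L)
  expect_equal(s$cross_graft$n_shared, 2L)  # c and d shared between grafts
})
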