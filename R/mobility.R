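#' Consensus haplotype of a genotype
#'
#' The reference sequence with the genotype's homozygous calls substituted.
#' Classification of a read's genotype of origin tests perfect alignment
#' against this consensus, so shared (non-diagnostic) substitutions that both
#' partners carry relative to the reference do not disqualify a read.
#' Positions without a homozygous call stay at the reference base.
#'
#' @param reference Named character vector of contig sequences.
#' @param calls [call_homozygous()] output for one genotype.
#' @return Named character vector of consensus contig sequences.
#' @export
consensus_haplotype <- function(reference, calls) {
  out <- reference
  for (ct in unique(calls$contig)) {
    if (!ct %in% names(out)) next
    s <- strsplit(out[[ct]], "", fixed = TRUE)[[1L]]
    sel <- calls$contig == ct
    s[calls$pos[sel]] <- calls$allele[sel]
    out[[ct]] <- paste(s, collapse = "")
  }
  out
}

#' Classify RNA-Seq reads by genotype of origin
#'
#' Each alignment is labeled:
#' \describe{
#'   \item{`uninformative`}{covers no diagnostic locus, or fails the
#'     perfect-match requirement for either assignment without showing mixed
#'     alleles (e.g. a sequencing-error base at or outside the loci).}
#'   \item{`donor`}{every covered diagnostic locus shows the donor allele
#'     *and* the read aligns with zero mismatches to the donor consensus
#'     haplotype — the perfect-match rule.}
#'   \item{`receptor`}{symmetric to `donor`.}
#'   \item{`conflicted`}{the covered loci show a mix of donor and receptor
#'     alleles (a chimera or error); discarded from evidence on both sides.}
#' }
#'
#' @param aln Alignment table (one RNA library, post alignment filters).
#' @param snps [diagnostic_snps()] output; `genotype_1`/`genotype_2` must
#'   contain `donor`.
#' @param consensi Named list of consensus haplotypes by genotype id (from
#'   [consensus_haplotype()]).
#' @param donor Genotype id of the donor partner; the other genotype in
#'   `snps` is the receptor.
#' @return List of class `classified_reads`: `reads` (the alignment table
#'   plus `nm_donor`, `nm_receptor`, `n_loci`, `label`), `loci` (one row per
#'   read × covered locus: `row`, `read_id`, `library`, `contig`, `start`,
#'   `strand`, `pos`, `base`, `allele_class`), `donor`, `receptor`,
#'   `library_total` (mapped reads in the library).
#' @export
classify_reads <- function(aln, snps, consensi, donor) {
  gts <- unique(c(snps$genotype_1, snps$genotype_2))
  gts <- gts[!is.na(gts)]
  if (!donor %in% gts && nrow(snps) > 0L)
    stop("donor genotype '", donor, "' not present in snps")
  receptor <- setdiff(gts, donor)
  if (length(receptor) == 0L) receptor <- NA_character_
  if (!all(c(donor, receptor) %in% names(consensi), na.rm = TRUE))
    stop("consensi must be named by genotype id")

  loci <- unique(snps[, c("contig", "pos", "genotype_1", "allele_1",
                          "allele_2")])
  loci$donor_allele <- ifelse(loci$genotype_1 == donor, loci$allele_1,
                              loci$allele_2)
  loci$receptor_allele <- ifelse(loci$genotype_1 == donor, loci$allele_2,
                                 loci$allele_1)

  n <- nrow(aln)
  nm_d <- integer(n); nm_r <- integer(n)
  for (ct in unique(aln$contig)) {
    sel <- which(aln$contig == ct)
    nm_d[sel] <- hamming_to_subject(aln$seq[sel], aln$start[sel],
                                    consensi[[donor]][[ct]])
    nm_r[sel] <- if (is.na(receptor)) NA_integer_ else
      hamming_to_subject(aln$seq[sel], aln$start[sel],
                         consensi[[receptor]][[ct]])
  }

  pairs <- list()
  for (ct in unique(aln$contig)) {
    ai <- which(aln$contig == ct)
    li <- which(loci$contig == ct)
    if (length(li) == 0L || length(ai) == 0L) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(aln$start[ai], width = nchar(aln$seq[ai])),
      IRanges::IRanges(loci$pos[li], width = 1L))
    if (length(ov) == 0L) next
    q <- ai[S4Vectors::queryHits(ov)]
    s <- li[S4Vectors::subjectHits(ov)]
    base <- substr(aln$seq[q], loci$pos[s] - aln$start[q] + 1L,
                   loci$pos[s] - aln$start[q] + 1L)
    pairs[[length(pairs) + 1L]] <- data.frame(
      row = q, read_id = aln$read_id[q], library = aln$library[q],
      contig = ct, start = aln$start[q], strand = aln$strand[q],
      pos = loci$pos[s], base = base,
      allele_class = ifelse(base == loci$donor_allele[s], "donor",
                            ifelse(base == loci$receptor_allele[s],
                                   "receptor", "other")),
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs) > 0L) do.call(rbind, pairs) else
    data.frame(row = integer(0), read_id = character(0),
               library = character(0), contig = character(0),
               start = integer(0), strand = character(0), pos = integer(0),
               base = character(0), allele_class = character(0),
               stringsAsFactors = FALSE)

  n_loci <- tabulate(pairs$row, nbins = n)
  n_don <- tabulate(pairs$row[pairs$allele_class == "donor"], nbins = n)
  n_rec <- tabulate(pairs$row[pairs$allele_class == "receptor"], nbins = n)

  label <- rep("uninformative", n)
  label[n_don > 0L & n_rec > 0L] <- "conflicted"
  label[n_loci > 0L & n_don == n_loci & nm_d == 0L] <- "donor"
  if (!is.na(receptor))
    label[n_loci > 0L & n_rec == n_loci & nm_r == 0L] <- "receptor"

  reads <- aln
  reads$nm_donor <- nm_d
  reads$nm_receptor <- nm_r
  reads$n_loci <- n_loci
  reads$label <- label
  structure(list(reads = reads, loci = pairs, donor = donor,
                 receptor = receptor, library_total = n),
            class = "classified_reads")
}

#' @export
print.classified_reads <- function(x, ...) {
  cat("classified_reads: ", nrow(x$reads), " alignments (donor=", x$donor,
      ", receptor=", x$receptor, "); labels: ", sep = "")
  print(table(x$reads$label))
  invisible(x)
}

# donor-origin read x diagnostic-locus evidence pairs with gene annotation
.donor_evidence_pairs <- function(classified, snps) {
  lp <- classified$loci
  donor_rows <- which(classified$reads$label == "donor")
  lp <- lp[lp$row %in% donor_rows & lp$allele_class == "donor", , drop = FALSE]
  gmap <- unique(snps[!is.na(snps$gene_id),
                      c("contig", "pos", "gene_id"), drop = FALSE])
  if (nrow(lp) == 0L || nrow(gmap) == 0L)
    return(data.frame(read_key = character(0), read_id = character(0),
                      gene_id = character(0), contig = character(0),
                      pos = integer(0), stringsAsFactors = FALSE))
  m <- merge(lp, gmap, by = c("contig", "pos"))
  data.frame(read_key = paste(m$contig, m$start, m$strand, sep = ":"),
             read_id = m$read_id, gene_id = m$gene_id, contig = m$contig,
             pos = m$pos, stringsAsFactors = FALSE)
}

#' Call graft-transmitting genes from classified reads
#'
#' Per gene and direction, three evidence rules are evaluated over
#' donor-origin reads and the gene's diagnostic loci:
#' \describe{
#'   \item{a}{at least one read carries two or more diagnostic SNP loci;}
#'   \item{b}{at least two unique reads cover one (the same) diagnostic SNP
#'     locus;}
#'   \item{c}{at least two unique reads carry different diagnostic SNP loci.}
#' }
#' A gene is called transmitting when any rule holds.  "Unique reads" are
#' distinct alignment coordinate keys (`contig:start:strand`), the
#' post-deduplication notion of distinct molecules.
#'
#' Since every evidence read covers at least one locus, rule (c) is
#' equivalent to (≥2 distinct read keys AND ≥2 distinct loci): pick two
#' distinct loci; if one read carries both, any second read carries a locus
#' differing from at least one of them.
#'
#' @param x A `classified_reads` object, or a pre-built evidence pair table
#'   with columns `read_key`, `gene_id`, `pos` (useful for testing the rules
#'   in isolation).
#' @param snps [diagnostic_snps()] output (ignored when `x` is already a
#'   pair table).
#' @param direction Direction label recorded in the output, e.g.
#'   `"rootstock_to_scion"`.
#' @return Data frame with one row per gene with any donor-origin evidence:
#'   `gene_id`, `direction`, `n_reads` (distinct keys), `n_loci` (distinct
#'   loci), `criteria` (subset of `"abc"`), `transmitting`, `read_ids`
#'   (collapsed).  Genes whose evidence satisfies no rule appear with
#'   `transmitting = FALSE`.
#' @export
detect_transmitting_genes <- function(x, snps = NULL,
                                      direction = "donor_to_receptor") {
  if (inherits(x, "classified_reads")) {
    stopifnot(!is.null(snps))
    ev <- .donor_evidence_pairs(x, snps)
  } else {
    ev <- as.data.frame(x)
    if (!"read_id" %in% names(ev)) ev$read_id <- ev$read_key
  }
  if (nrow(ev) == 0L)
    return(data.frame(gene_id = character(0), direction = character(0),
                      n_reads = integer(0), n_loci = integer(0),
                      criteria = character(0), transmitting = logical(0),
                      read_ids = character(0), stringsAsFactors = FALSE))
  dt <- unique(as.data.table(ev)[, .(gene_id, read_key, pos, read_id)])
  res <- dt[, {
    u <- unique(.SD[, .(read_key, pos)])
    crit_a <- any(u[, .N, by = read_key]$N >= 2L)
    crit_b <- any(u[, .N, by = pos]$N >= 2L)
    crit_c <- uniqueN(u$read_key) >= 2L && uniqueN(u$pos) >= 2L
    .(n_reads = uniqueN(u$read_key), n_loci = uniqueN(u$pos),
      criteria = paste0(c(if (crit_a) "a", if (crit_b) "b",
                          if (crit_c) "c"), collapse = ""),
      transmitting = crit_a || crit_b || crit_c,
      read_ids = paste(sort(unique(read_id)), collapse = ";"))
  }, by = gene_id]
  res[, direction := direction]
  out <- as.data.frame(res[, .(gene_id, direction, n_reads, n_loci, criteria,
                               transmitting, read_ids)])
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Summarize movement directions within and across grafts
#'
#' Mirrors the usual graft-experiment summary: per graft, the number of genes
#' whose mRNAs moved in each direction and in both directions; across grafts,
#' pairwise overlaps of transmitting-gene sets.
#'
#' @param grafts Named list of grafts; each graft is a named list of
#'   [detect_transmitting_genes()] tables (one per direction).
#' @return List with `per_graft` (columns `graft`, `direction`, `n_genes`
#'   plus one `both` row per graft with the intersection across that graft's
#'   directions) and `cross_graft` (pairwise `graft_1`, `graft_2`,
#'   `n_shared`).
#' @export
direction_summary <- function(grafts) {
  stopifnot(is.list(grafts), length(grafts) > 0L)
  per <- list()
  sets <- list()
  for (g in names(grafts)) {
    dirs <- grafts[[g]]
    gene_sets <- lapply(dirs, function(ev) {
      unique(ev$gene_id[ev$transmitting])
    })
    for (d in names(dirs))
      per[[length(per) + 1L]] <- data.frame(
        graft = g, direction = d, n_genes = length(gene_sets[[d]]),
        stringsAsFactors = FALSE)
    per[[length(per) + 1L]] <- data.frame(
      graft = g, direction = "both",
      n_genes = length(Reduce(intersect, gene_sets)),
      stringsAsFactors = FALSE)
    sets[[g]] <- unique(unlist(gene_sets))
  }
  cross <- data.frame(graft_1 = character(0), graft_2 = character(0),
                      n_shared = integer(0), stringsAsFactors = FALSE)
  gn <- names(sets)
  if (length(gn) > 1L) {
    cb <- utils::combn(gn, 2L)
    cross <- data.frame(
      graft_1 = cb[1L, ], graft_2 = cb[2L, ],
      n_shared = vapply(seq_len(ncol(cb)), function(i)
        length(intersect(sets[[cb[1L, i]]], sets[[cb[2L, i]]])), 1L),
      stringsAsFactors = FALSE)
  }
  list(per_graft = do.call(rbind, per), cross_graft = cross)
}
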