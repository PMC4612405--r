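#' Call homozygous genotypes from a genomic pileup
#'
#' A position is called homozygous for its dominant base when at least
#' `min_depth` reads support the dominant base (non-strict) and the dominant
#' base's frequency among all covering reads is strictly greater than
#' `min_fraction`.  A tie for the dominant base yields no call — a tied base
#' cannot be "the dominant allele".  No-calls are silently omitted; they are
#' values, not errors.
#'
#' The frequency denominator is the total pileup depth at the position (all
#' four bases), the natural reading of "frequency of the dominant allele".
#'
#' @param pile Pileup table from [pileup()] (one library).
#' @param genotype Genotype label recorded in the output.
#' @param min_depth Minimum dominant-base depth (default 7).
#' @param min_fraction Dominant-base frequency must exceed this (default 0.9,
#'   strict).
#' @return Data frame with columns `contig`, `pos`, `allele`,
#'   `depth_dominant`, `depth_total`, `genotype`.
#' @export
call_homozygous <- function(pile, genotype = "g1", min_depth = 7L,
                            min_fraction = 0.9) {
  empty <- data.frame(contig = character(0), pos = integer(0),
                      allele = character(0), depth_dominant = integer(0),
                      depth_total = integer(0), genotype = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(pile) == 0L) return(empty)
  m <- as.matrix(pile[, DNA_BASES])
  tot <- rowSums(m)
  dom <- do.call(pmax, as.data.frame(m))
  n_tie <- rowSums(m == dom)
  ok <- dom >= min_depth & dom / tot > min_fraction & n_tie == 1L
  if (!any(ok)) return(empty)
  out <- data.frame(
    contig = pile$contig[ok], pos = pile$pos[ok],
    allele = DNA_BASES[max.col(m[ok, , drop = FALSE], ties.method = "first")],
    depth_dominant = as.integer(dom[ok]), depth_total = as.integer(tot[ok]),
    genotype = genotype, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Derive diagnostic SNPs from two genotypes' homozygous calls
#'
#' A diagnostic SNP is a position called homozygous in *both* genotypes with
#' different alleles; it is the unit of evidence for assigning a read to its
#' genotype of origin.  Swapping the two inputs yields the same locus set
#' with allele labels swapped.
#'
#' When `gene_models` is supplied each locus is annotated with the
#' overlapping gene(s); a locus inside two overlapping models yields one row
#' per gene, and loci outside any model carry `gene_id = NA` (they are kept
#' for the VCF but excluded from gene-level statistics).
#'
#' @param calls_1,calls_2 Outputs of [call_homozygous()] on the two genotypes
#'   (same reference coordinates).
#' @param reference Optional named character vector (or FASTA path); adds the
#'   reference base, required for VCF export.
#' @param gene_models Optional gene-model table (`gene_id`, `contig`, `start`,
#'   `end`).
#' @return Data frame with columns `contig`, `pos`, `ref`, `genotype_1`,
#'   `allele_1`, `depth_1`, `genotype_2`, `allele_2`, `depth_2`, `gene_id`,
#'   sorted by (`contig`, `pos`).
#' @export
diagnostic_snps <- function(calls_1, calls_2, reference = NULL,
                            gene_models = NULL) {
  if (!is.null(reference) && is.character(reference) &&
      length(reference) == 1L && file.exists(reference))
    reference <- read_fasta_seqs(reference)
  d1 <- as.data.table(calls_1)
  d2 <- as.data.table(calls_2)
  m <- d1[d2, on = c("contig", "pos"), nomatch = NULL]
  m <- m[allele != i.allele]
  out <- data.frame(
    contig = m$contig, pos = m$pos, ref = NA_character_,
    genotype_1 = m$genotype, allele_1 = m$allele,
    depth_1 = m$depth_dominant,
    genotype_2 = m$i.genotype, allele_2 = m$i.allele,
    depth_2 = m$i.depth_dominant,
    gene_id = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(reference) && nrow(out) > 0L)
    out$ref <- substring(reference[out$contig], out$pos, out$pos)
  if (!is.null(gene_models) && nrow(out) > 0L && nrow(gene_models) > 0L) {
    ann <- list()
    for (ct in unique(out$contig)) {
      si <- which(out$contig == ct)
      gi <- which(gene_models$contig == ct)
      if (length(gi) == 0L) { ann[[ct]] <- out[si, , drop = FALSE]; next }
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(out$pos[si], width = 1L),
        IRanges::IRanges(gene_models$start[gi], gene_models$end[gi]))
      res <- out[si, , drop = FALSE]
      hit_q <- S4Vectors::queryHits(ov)
      if (length(hit_q) > 0L) {
        with_gene <- res[hit_q, , drop = FALSE]
        with_gene$gene_id <- gene_models$gene_id[gi][S4Vectors::subjectHits(ov)]
        res <- rbind(res[setdiff(seq_along(si), unique(hit_q)), , drop = FALSE],
                     with_gene)
      }
      ann[[ct]] <- res
    }
    out <- do.call(rbind, ann)
  }
  out <- out[order(out$contig, out$pos, out$gene_id, na.last = TRUE,
                   method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Write diagnostic SNPs to a minimal VCF 4.2
#'
#' One record per locus against the reference genome; the two partners'
#' alleles are stored in `INFO` fields `A1`/`A2` (with genotype ids in
#' `G1`/`G2`) and overlapping genes, if annotated, in `GENE`.
#'
#' @param snps [diagnostic_snps()] output, sorted by (`contig`, `pos`) with a
#'   non-missing `ref` column.
#' @param path Output file.
#' @param reference Optional named character vector; adds contig lengths to
#'   the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snps, path, reference = NULL) {
  loci <- unique(snps[, c("contig", "pos", "ref", "genotype_1", "allele_1",
                          "genotype_2", "allele_2")])
  if (!identical(order(loci$contig, loci$pos, method = "radix"),
                 seq_len(nrow(loci))))
    stop("diagnostic SNPs must be sorted by (contig, pos)")
  if (nrow(loci) > 0L && anyNA(loci$ref))
    stop("reference base required to write VCF; rerun diagnostic_snps() with ",
         "a reference")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=graftrans",
    "##INFO=<ID=A1,Number=1,Type=String,Description=\"Homozygous allele of partner 1\">",
    "##INFO=<ID=A2,Number=1,Type=String,Description=\"Homozygous allele of partner 2\">",
    "##INFO=<ID=G1,Number=1,Type=String,Description=\"Genotype id of partner 1\">",
    "##INFO=<ID=G2,Number=1,Type=String,Description=\"Genotype id of partner 2\">",
    "##INFO=<ID=GENE,Number=.,Type=String,Description=\"Overlapping gene model(s)\">"),
    con)
  if (!is.null(reference))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(reference),
                       nchar(reference)), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(loci) > 0L) {
    genes <- vapply(seq_len(nrow(loci)), function(i) {
      g <- snps$gene_id[snps$contig == loci$contig[i] &
                          snps$pos == loci$pos[i]]
      g <- sort(unique(g[!is.na(g)]))
      if (length(g) == 0L) "" else paste(g, collapse = ",")
    }, "")
    alt <- vapply(seq_len(nrow(loci)), function(i) {
      a <- unique(c(loci$allele_1[i], loci$allele_2[i]))
      paste(setdiff(a, loci$ref[i]), collapse = ",")
    }, "")
    info <- sprintf("A1=%s;A2=%s;G1=%s;G2=%s", loci$allele_1, loci$allele_2,
                    loci$genotype_1, loci$genotype_2)
    info <- ifelse(genes == "", info, paste0(info, ";GENE=", genes))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s", loci$contig, loci$pos,
                       loci$ref, alt, info), con)
  }
  invisible(path)
}

#' Read diagnostic SNPs back from a VCF written by [write_vcf()]
#'
#' Parsed with the independent `vcfR` reader.
#'
#' @param path VCF file.
#' @return A [diagnostic_snps()]-shaped data frame (depth columns `NA`; loci
#'   annotated to several genes expand to one row per gene).
#' @export
read_diagnostic_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), genotype_1 = character(0),
                      allele_1 = character(0), depth_1 = integer(0),
                      genotype_2 = character(0), allele_2 = character(0),
                      depth_2 = integer(0), gene_id = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty)
  info_field <- function(el) {
    x <- vcfR::extract.info(v, element = el)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else x
  }
  out <- data.frame(
    contig = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    genotype_1 = info_field("G1"), allele_1 = info_field("A1"),
    depth_1 = NA_integer_,
    genotype_2 = info_field("G2"), allele_2 = info_field("A2"),
    depth_2 = NA_integer_,
    gene_id = info_field("GENE"), stringsAsFactors = FALSE)
  has_gene <- !is.na(out$gene_id)
  if (any(has_gene)) {
    genes <- strsplit(out$gene_id, ",", fixed = TRUE)
    reps <- vapply(genes, length, 1L)
    out <- out[rep(seq_len(nrow(out)), reps), , drop = FALSE]
    out$gene_id <- unlist(genes)
  }
  out <- out[order(out$contig, out$pos, out$gene_id, na.last = TRUE,
                   method = "radix"), ]
  rownames(out) <- NULL
  out
}
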