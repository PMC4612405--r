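#' Configuration for a synthetic graft experiment
#'
#' Defines the study conditions the generator emulates: two fully homozygous
#' genotypes differing at planted biallelic SNPs, per-gene tissue-of-origin
#' expression, directional mixing of a known fraction of each gene's
#' transcripts into the partner tissue's library, uniform substitution error,
#' and PCR duplication.
#'
#' Defaults describe a desk-scale version of a grafted-grapevine experiment:
#' 101-bp single-end reads, genomic coverage of 30-fold per genotype (well
#' above the 15-fold floor at which homozygous calls saturate), a substitution
#' error rate of 0.001 typical of Illumina data, 5% PCR duplication, 2
#' planted SNPs per kilobase of which half are diagnostic (interspecific
#' *Vitis* material is SNP-dense), and 1.5-kb single-exon genes.
#'
#' @param genome_length Reference length in bases (single contig `chr1`).
#' @param n_genes Number of single-exon, forward-strand genes.
#' @param exon_length Exon length in bases per gene; must be at least
#'   `read_length`.
#' @param snp_density Expected planted SNPs per kilobase.
#' @param diagnostic_fraction Fraction of planted SNPs at which the two
#'   genotypes carry different alleles; the remainder are shared substitutions
#'   (non-diagnostic noise loci).
#' @param read_length Read length in bases (default 101).
#' @param genomic_depth Expected fold-coverage per genotype for the genomic
#'   libraries.
#' @param rnaseq_reads_per_library Transcript draws per tissue library before
#'   directional routing.
#' @param error_rate Per-base substitution probability.
#' @param duplication_rate Probability that a read is emitted twice (PCR
#'   duplicate).
#' @param transmission_fractions Per-gene probability that a transcript is
#'   routed to the partner tissue: `NULL` (draw from the default mixture
#'   `{0, 0.001, 0.01, 0.1, 0.5}` weighted toward small values), a single
#'   number recycled to all genes, an unnamed vector of length `n_genes`, or a
#'   vector named by gene id.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000L, n_genes = 50L,
                       exon_length = 1500L, snp_density = 2,
                       diagnostic_fraction = 0.5, read_length = 101L,
                       genomic_depth = 30, rnaseq_reads_per_library = 100000L,
                       error_rate = 0.001, duplication_rate = 0.05,
                       transmission_fractions = NULL, seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length), n_genes = as.integer(n_genes),
    exon_length = as.integer(exon_length), snp_density = snp_density,
    diagnostic_fraction = diagnostic_fraction,
    read_length = as.integer(read_length), genomic_depth = genomic_depth,
    rnaseq_reads_per_library = as.integer(rnaseq_reads_per_library),
    error_rate = error_rate, duplication_rate = duplication_rate,
    transmission_fractions = transmission_fractions, seed = as.integer(seed))
  for (p in c("error_rate", "duplication_rate", "diagnostic_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("'", p, "' must be in [0, 1]")
  }
  if (!is.null(transmission_fractions) &&
      (any(transmission_fractions < 0) || any(transmission_fractions > 1)))
    stop("'transmission_fractions' must be in [0, 1]")
  if (cfg$read_length < 2L) stop("'read_length' must be >= 2")
  if (cfg$exon_length < cfg$read_length)
    stop("'exon_length' must be >= 'read_length'")
  if (cfg$genome_length < cfg$n_genes * cfg$exon_length)
    stop("'genome_length' must be >= n_genes * exon_length")
  if (cfg$snp_density < 0) stop("'snp_density' must be >= 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$genome_length, "bp genome,", x$n_genes, "genes,",
      x$read_length, "bp reads, depth", x$genomic_depth, "x, error",
      x$error_rate, "\n")
  invisible(x)
}

.resolve_fractions <- function(cfg, gene_ids) {
  tf <- cfg$transmission_fractions
  n <- length(gene_ids)
  if (is.null(tf)) {
    # mixture weighted toward small fractions, mirroring the observed
    # predominance of rates below 0.01 in grafted-plant data
    sample(c(0, 0.001, 0.01, 0.1, 0.5), n, replace = TRUE,
           prob = c(0.30, 0.25, 0.25, 0.15, 0.05))
  } else if (!is.null(names(tf))) {
    out <- tf[gene_ids]
    if (anyNA(out)) stop("transmission_fractions missing for some genes")
    unname(out)
  } else if (length(tf) == 1L) {
    rep(tf, n)
  } else if (length(tf) == n) {
    tf
  } else {
    stop("transmission_fractions must be length 1, n_genes, or named by gene")
  }
}

#' Generate a reference genome and a pair of homozygous genotypes
#'
#' Plants biallelic SNPs at unique positions on a random reference.  At a
#' diagnostic SNP the two genotypes carry different alleles (each genotype is
#' fully homozygous); at a non-diagnostic SNP both genotypes share the same
#' non-reference allele.  Positions are sampled without replacement, so two
#' SNPs can never collide on one position.
#'
#' @param config A [sim_config()].
#' @return A list of class `genotype_pair` with elements `reference`, `hap_A`,
#'   `hap_B` (named character vectors of contig sequences), `genes` (gene
#'   models with source genotype, expression weight and transmission
#'   fraction), `snps` (planted SNP truth: `contig`, `pos`, `ref`, `allele_A`,
#'   `allele_B`, `diagnostic`), and `config`.  Coordinates are 1-based, fully
#'   closed.
#' @export
make_genotype_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  ref <- random_dna(L)
  contig <- "chr1"

  spacing <- L %/% config$n_genes
  gstart <- (seq_len(config$n_genes) - 1L) * spacing +
    ((spacing - config$exon_length) %/% 2L) + 1L
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
    contig = contig, start = gstart, end = gstart + config$exon_length - 1L,
    strand = "+", stringsAsFactors = FALSE)

  n_snp <- min(stats::rpois(1L, config$snp_density * L / 1000), L)
  pos <- sort(sample.int(L, n_snp))
  refb <- if (n_snp > 0L) substring(ref, pos, pos) else character(0)
  diag_flag <- stats::runif(n_snp) < config$diagnostic_fraction
  allele_A <- refb
  allele_B <- refb
  if (any(diag_flag)) {
    # unordered pair of distinct bases; at most one can equal the reference
    i <- which(diag_flag)
    a <- DNA_BASES[sample.int(4L, length(i), replace = TRUE)]
    shift <- sample.int(3L, length(i), replace = TRUE)
    b <- DNA_BASES[((match(a, DNA_BASES) - 1L + shift) %% 4L) + 1L]
    allele_A[i] <- a
    allele_B[i] <- b
  }
  if (any(!diag_flag)) {
    i <- which(!diag_flag)
    shift <- sample.int(3L, length(i), replace = TRUE)
    shared <- DNA_BASES[((match(refb[i], DNA_BASES) - 1L + shift) %% 4L) + 1L]
    allele_A[i] <- shared
    allele_B[i] <- shared
  }
  snps <- data.frame(contig = character(0), pos = integer(0),
                     ref = character(0), allele_A = character(0),
                     allele_B = character(0), diagnostic = logical(0),
                     stringsAsFactors = FALSE)
  if (n_snp > 0L)
    snps <- data.frame(contig = contig, pos = pos, ref = refb,
                       allele_A = allele_A, allele_B = allele_B,
                       diagnostic = allele_A != allele_B,
                       stringsAsFactors = FALSE)

  s <- strsplit(ref, "", fixed = TRUE)[[1L]]
  sA <- s; sA[pos] <- allele_A
  sB <- s; sB[pos] <- allele_B
  hap_A <- paste(sA, collapse = "")
  hap_B <- paste(sB, collapse = "")

  genes$source_genotype <- sample(c("A", "B"), config$n_genes, replace = TRUE)
  genes$expression_weight <- stats::rlnorm(config$n_genes, 0, 1)
  genes$transmission_fraction <- .resolve_fractions(config, genes$gene_id)

  structure(list(
    reference = stats::setNames(ref, contig),
    hap_A = stats::setNames(hap_A, contig),
    hap_B = stats::setNames(hap_B, contig),
    genes = genes, snps = snps, config = config),
    class = "genotype_pair")
}

# draw reads from given (contig, start, strand) positions on a haplotype,
# apply substitution errors in sequenced orientation, then PCR duplication
.emit_reads <- function(hap, contig, starts, strands, R, error_rate,
                        duplication_rate, prefix) {
  n <- length(starts)
  if (n == 0L)
    return(data.frame(read_id = character(0), seq = character(0),
                      contig = character(0), true_start = integer(0),
                      true_strand = character(0), stringsAsFactors = FALSE))
  tpl <- substring(hap[contig], starts, starts + R - 1L)
  tpl[strands == "-"] <- revcomp(tpl[strands == "-"])
  tpl <- add_seq_errors(tpl, error_rate)
  out <- data.frame(read_id = sprintf("%s%07d", prefix, seq_len(n)), seq = tpl,
                    contig = contig, true_start = starts, true_strand = strands,
                    stringsAsFactors = FALSE)
  if (duplication_rate > 0) {
    dup <- stats::runif(n) < duplication_rate
    if (any(dup)) {
      d <- out[dup, , drop = FALSE]
      d$read_id <- paste0(d$read_id, ".dup")
      out <- rbind(out, d)
    }
  }
  rownames(out) <- NULL
  out
}

#' Simulate a genomic sequencing library from one haplotype
#'
#' Reads are drawn uniformly along the haplotype at the configured expected
#' fold-coverage, on random strands, with substitution errors and PCR
#' duplicates.  Truth columns (`true_start`, `true_strand`, 1-based) record
#' each read's origin.
#'
#' @param haplotype Named character vector of contig sequences.
#' @param config A [sim_config()].
#' @param prefix Read-id prefix (keeps libraries distinguishable).
#' @return Data frame with columns `read_id`, `seq`, `contig`, `true_start`,
#'   `true_strand`.
#' @export
simulate_genomic_reads <- function(haplotype, config, prefix = "g") {
  stopifnot(inherits(config, "sim_config"))
  R <- config$read_length
  lens <- nchar(haplotype)
  if (any(lens < R)) stop("haplotype shorter than read length")
  out <- vector("list", length(haplotype))
  for (k in seq_along(haplotype)) {
    n <- round(config$genomic_depth * lens[k] / R)
    starts <- sample.int(lens[k] - R + 1L, n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    out[[k]] <- .emit_reads(haplotype, names(haplotype)[k], starts, strands, R,
                            config$error_rate, config$duplication_rate,
                            paste0(prefix, k, "_"))
  }
  do.call(rbind, out)
}

#' Simulate the two tissue RNA-Seq libraries of a graft
#'
#' Each gene is expressed from its source genotype's haplotype; transcript
#' draws per gene follow a multinomial over expression weights within each
#' tissue's library budget.  Every read is then routed to the partner tissue's
#' library with that gene's transmission fraction (emulating mobility), else
#' kept in the home library.  Tissue 1 ("scion") is the home tissue of
#' genotype A; tissue 2 ("rootstock") of genotype B.
#'
#' @param pair A [make_genotype_pair()] result.
#' @param config A [sim_config()]; defaults to `pair$config`.
#' @return List with `scion` and `rootstock` read tables (columns `read_id`,
#'   `seq`, `contig`, `true_start`, `true_strand`, `gene_id`,
#'   `origin_genotype`), and `per_gene` realized-count truth (`gene_id`,
#'   `n_draws`, `n_home`, `n_partner`; pre-duplication).
#' @export
simulate_graft_transcriptomes <- function(pair, config = pair$config) {
  stopifnot(inherits(pair, "genotype_pair"), inherits(config, "sim_config"))
  genes <- pair$genes
  if (all(genes$expression_weight == 0)) stop("empty transcriptome")
  R <- config$read_length
  haps <- list(A = pair$hap_A, B = pair$hap_B)
  home_tissue <- c(A = "scion", B = "rootstock")

  reads <- list(scion = list(), rootstock = list())
  per_gene <- data.frame(gene_id = genes$gene_id, n_draws = 0L, n_home = 0L,
                         n_partner = 0L, stringsAsFactors = FALSE)

  for (g in c("A", "B")) {
    idx <- which(genes$source_genotype == g)
    w <- genes$expression_weight[idx]
    if (length(idx) == 0L || sum(w) == 0) next
    draws <- as.vector(stats::rmultinom(1L, config$rnaseq_reads_per_library,
                                        w / sum(w)))
    home <- home_tissue[[g]]
    partner <- setdiff(c("scion", "rootstock"), home)
    for (j in seq_along(idx)) {
      gi <- idx[j]
      n <- draws[j]
      per_gene$n_draws[gi] <- n
      if (n == 0L) next
      starts <- genes$start[gi] +
        sample.int(genes$end[gi] - genes$start[gi] - R + 2L, n,
                   replace = TRUE) - 1L
      strands <- sample(c("+", "-"), n, replace = TRUE)
      rd <- .emit_reads(haps[[g]], genes$contig[gi], starts, strands, R,
                        config$error_rate, 0, paste0(genes$gene_id[gi], "_"))
      rd$gene_id <- genes$gene_id[gi]
      rd$origin_genotype <- g
      moved <- stats::runif(n) < genes$transmission_fraction[gi]
      per_gene$n_partner[gi] <- sum(moved)
      per_gene$n_home[gi] <- n - sum(moved)
      if (any(moved))
        reads[[partner]][[length(reads[[partner]]) + 1L]] <-
          rd[moved, , drop = FALSE]
      if (any(!moved))
        reads[[home]][[length(reads[[home]]) + 1L]] <- rd[!moved, , drop = FALSE]
    }
  }

  finish <- function(lst, tissue) {
    if (length(lst) == 0L)
      return(data.frame(read_id = character(0), seq = character(0),
                        contig = character(0), true_start = integer(0),
                        true_strand = character(0), gene_id = character(0),
                        origin_genotype = character(0),
                        stringsAsFactors = FALSE))
    df <- do.call(rbind, lst)
    df$read_id <- paste0(tissue, "_", df$read_id)
    # PCR duplication acts on the library after routing
    if (config$duplication_rate > 0) {
      dup <- stats::runif(nrow(df)) < config$duplication_rate
      if (any(dup)) {
        d <- df[dup, , drop = FALSE]
        d$read_id <- paste0(d$read_id, ".dup")
        df <- rbind(df, d)
      }
    }
    rownames(df) <- NULL
    df
  }
  list(scion = finish(reads$scion, "scion"),
       rootstock = finish(reads$rootstock, "rootstock"),
       per_gene = per_gene)
}

#' Simulate a complete graft experiment, optionally writing it to disk
#'
#' Convenience wrapper: genotype pair, two genomic libraries, two tissue
#' RNA-Seq libraries, plus (when `dir` is given) FASTA/FASTQ/GFF3/TSV/YAML
#' files for the whole experiment.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return List with `pair`, `genomic` (list `A`, `B` of read tables), `rna`
#'   (list `scion`, `rootstock`, `per_gene`) and, when written, `paths`.
#' @export
simulate_graft_experiment <- function(config, dir = NULL) {
  pair <- make_genotype_pair(config)
  genomic <- list(A = simulate_genomic_reads(pair$hap_A, config, "gA_"),
                  B = simulate_genomic_reads(pair$hap_B, config, "gB_"))
  rna <- simulate_graft_transcriptomes(pair, config)
  out <- list(pair = pair, genomic = genomic, rna = rna)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- list(
      reference = file.path(dir, "reference.fa"),
      hap_A = file.path(dir, "genotype_A.fa"),
      hap_B = file.path(dir, "genotype_B.fa"),
      gdna_A = file.path(dir, "gdna_A.fastq"),
      gdna_B = file.path(dir, "gdna_B.fastq"),
      rna_scion = file.path(dir, "rna_scion.fastq"),
      rna_rootstock = file.path(dir, "rna_rootstock.fastq"),
      gff3 = file.path(dir, "genes.gff3"),
      truth_genes = file.path(dir, "truth_genes.tsv"),
      truth_snps = file.path(dir, "truth_snps.tsv"),
      truth_per_gene = file.path(dir, "truth_per_gene_counts.tsv"),
      config = file.path(dir, "sim_config.yml"))
    write_fasta(pair$reference, p$reference)
    write_fasta(pair$hap_A, p$hap_A)
    write_fasta(pair$hap_B, p$hap_B)
    write_fastq(genomic$A, p$gdna_A)
    write_fastq(genomic$B, p$gdna_B)
    write_fastq(rna$scion, p$rna_scion)
    write_fastq(rna$rootstock, p$rna_rootstock)
    write_gff3(pair$genes, p$gff3)
    write_tsv(pair$genes, p$truth_genes)
    write_tsv(pair$snps, p$truth_snps)
    write_tsv(rna$per_gene, p$truth_per_gene)
    write_sim_config(config, p$config)
    out$paths <- p
  }
  out
}

#' Write gene models to GFF3
#'
#' @param genes Data frame with `gene_id`, `contig`, `start`, `end`, `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$contig, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$Name <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps `gene` records (or all records when no `type` column matches) as a
#' plain 1-based gene-model table.
#'
#' @param path GFF3 file.
#' @return Data frame with `gene_id`, `contig`, `start`, `end`, `strand`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "gene"))
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  id <- S4Vectors::mcols(gr)$ID
  if (is.null(id)) id <- S4Vectors::mcols(gr)$Name
  data.frame(gene_id = as.character(id),
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write / read a simulation configuration (YAML key-value file)
#'
#' The schema is exactly the argument list of [sim_config()]; per-gene
#' transmission fractions are stored as a named mapping.
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return `path` (write) or a [sim_config()] (read).
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$transmission_fractions))
    x$transmission_fractions <- as.list(x$transmission_fractions)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$transmission_fractions))
    x$transmission_fractions <- unlist(x$transmission_fractions)
  do.call(sim_config, x)
}
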