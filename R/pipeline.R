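#' Pipeline configuration
#'
#' Bundles inputs and thresholds for [run_graft_pipeline()].  Inputs may be
#' file paths (FASTA reference, GFF3 gene models, SAM alignments or FASTQ
#' reads per library) or the equivalent in-memory objects produced by the
#' simulator; FASTQ/read-table inputs go through the built-in test aligner.
#'
#' Threshold defaults are the conventional ones for this analysis: dominant
#' allele depth at least 7 and frequency strictly above 0.9 for homozygous
#' calls, 50 donor reads for reportable rates, 101-bp reads, and an aligner
#' edit limit of 4 (6 for 151-bp reads).
#'
#' @param reference FASTA path or named character vector.
#' @param gene_models GFF3 path or gene-model data frame.
#' @param genomic Named list of length 2: genotype id -> SAM path, FASTQ
#'   path, or read table (`read_id`, `seq`).
#' @param rna Named list: tissue -> SAM/FASTQ path or read table.  Exactly
#'   two tissues.
#' @param tissue_genotype Named character vector mapping each tissue in
#'   `rna` to its resident genotype in `genomic`.
#' @param min_dominant_depth,min_dominant_fraction Homozygous-call
#'   thresholds.
#' @param min_donor_reads Reporting floor for gene rates.
#' @param read_length Read length (window extension; aligner default edits
#'   derive from it).
#' @param max_edit Aligner mismatch limit (`NULL` = length-based default).
#' @param window_rule `"informative"` or `"contained"` (see
#'   [snp_transmission_rates()]).
#' @param rna_dedup Remove coordinate duplicates from RNA libraries before
#'   classification.  Default `FALSE`: the unique-read requirement of the
#'   detection rules is enforced on coordinate keys regardless, while rate
#'   estimation keeps all reads (coordinate dedup of deeply covered exons
#'   censors counts and biases rates downward).
#' @param exclude_read_ids Optional read ids excluded from expression
#'   counting (rRNA hook).
#' @param outdir Optional output directory for tables, VCF and manifest.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(reference, gene_models, genomic, rna,
                            tissue_genotype,
                            min_dominant_depth = 7L,
                            min_dominant_fraction = 0.9,
                            min_donor_reads = 50L, read_length = 101L,
                            max_edit = NULL,
                            window_rule = c("informative", "contained"),
                            rna_dedup = FALSE, exclude_read_ids = NULL,
                            outdir = NULL, seed = 1L) {
  window_rule <- match.arg(window_rule)
  if (length(genomic) != 2L || is.null(names(genomic)))
    stop("'genomic' must be a named list of two genotypes")
  if (length(rna) != 2L || is.null(names(rna)))
    stop("'rna' must be a named list of two tissues")
  if (!setequal(names(tissue_genotype), names(rna)) ||
      !all(tissue_genotype %in% names(genomic)))
    stop("'tissue_genotype' must map each tissue to a genotype in 'genomic'")
  for (th in c(min_dominant_depth, min_dominant_fraction, min_donor_reads,
               read_length))
    if (th <= 0) stop("thresholds must be positive")
  for (x in c(list(reference, gene_models), genomic, rna))
    if (.is_path(x) && !file.exists(x))
      stop("input path does not exist: ", x)
  structure(list(
    reference = reference, gene_models = gene_models, genomic = genomic,
    rna = rna, tissue_genotype = tissue_genotype,
    min_dominant_depth = as.integer(min_dominant_depth),
    min_dominant_fraction = min_dominant_fraction,
    min_donor_reads = as.integer(min_donor_reads),
    read_length = as.integer(read_length), max_edit = max_edit,
    window_rule = window_rule, rna_dedup = isTRUE(rna_dedup),
    exclude_read_ids = exclude_read_ids, outdir = outdir,
    seed = as.integer(seed)), class = "pipeline_config")
}

.load_alignments <- function(x, library_id, reference, max_edit) {
  if (.is_path(x)) {
    first <- readLines(x, n = 1L)
    if (startsWith(first, "@HD") || startsWith(first, "@SQ") ||
        grepl("\t", first))
      return(read_sam(x, library_id = library_id, reference = reference))
    return(test_align(x, reference, max_edit = max_edit,
                      library_id = library_id))
  }
  if (is.data.frame(x) && "start" %in% names(x)) {
    x$library <- library_id
    return(x)
  }
  test_align(x, reference, max_edit = max_edit, library_id = library_id)
}

#' Run the graft-mobility pipeline end to end
#'
#' Stages, in order: alignment ingestion and filters, genomic pileups,
#' homozygous calls for both genotypes, diagnostic SNPs (and VCF), per-
#' direction read classification and transmitting-gene detection,
#' window-based transmission rates (restricted to the transmitting genes),
#' RPKM expression, and direction/rate summaries.  Any stage error aborts
#' with the stage name; when writing to disk a `STALE` marker flags partial
#' output, and a machine-readable manifest records every threshold, input
#' checksum and per-stage count.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit per-stage progress messages.
#' @return List of class `graft_result`: `diagnostic` (calls, SNP table),
#'   `evidence` (per direction), `snp_rates`, `gene_rates`, `expression`,
#'   `summary` (direction counts), `distribution` (per direction),
#'   `manifest`, and `counts` (per-stage read counts).
#' @export
run_graft_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_stage <- function(name, expr) {
    if (verbose) message("[graftrans] ", name)
    tryCatch(expr, error = function(e) {
      if (!is.null(config$outdir)) {
        dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
        writeLines(paste("stale: pipeline failed at stage", name),
                   file.path(config$outdir, "STALE"))
      }
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  counts <- list()

  reference <- t_stage("load reference", {
    if (.is_path(config$reference))
      read_fasta_seqs(config$reference) else config$reference
  })
  gene_models <- t_stage("load gene models", {
    if (.is_path(config$gene_models))
      read_gff3(config$gene_models) else config$gene_models
  })

  genotypes <- names(config$genomic)
  tissues <- names(config$rna)

  calls <- list()
  gpile <- list()
  for (g in genotypes) {
    aln <- t_stage(paste0("align genomic ", g), .load_alignments(
      config$genomic[[g]], paste0("gdna_", g), reference, config$max_edit))
    counts[[paste0("genomic_", g, "_aligned")]] <- nrow(aln)
    aln <- t_stage(paste0("dedup genomic ", g), remove_duplicates(aln))
    counts[[paste0("genomic_", g, "_dedup")]] <- nrow(aln)
    gpile[[g]] <- t_stage(paste0("pileup ", g), pileup(aln))
    calls[[g]] <- t_stage(paste0("homozygous calls ", g), call_homozygous(
      gpile[[g]], genotype = g, min_depth = config$min_dominant_depth,
      min_fraction = config$min_dominant_fraction))
    counts[[paste0("homozygous_calls_", g)]] <- nrow(calls[[g]])
  }

  snps <- t_stage("diagnostic SNPs", diagnostic_snps(
    calls[[genotypes[1L]]], calls[[genotypes[2L]]], reference = reference,
    gene_models = gene_models))
  counts$diagnostic_loci <- length(unique(paste(snps$contig, snps$pos)))

  consensi <- t_stage("consensus haplotypes", {
    stats::setNames(lapply(genotypes, function(g)
      consensus_haplotype(reference, calls[[g]])), genotypes)
  })

  rna_aln <- list()
  for (tt in tissues) {
    aln <- t_stage(paste0("align RNA ", tt), .load_alignments(
      config$rna[[tt]], paste0("rna_", tt), reference, config$max_edit))
    counts[[paste0("rna_", tt, "_aligned")]] <- nrow(aln)
    if (config$rna_dedup) {
      aln <- t_stage(paste0("dedup RNA ", tt), remove_duplicates(aln))
      counts[[paste0("rna_", tt, "_dedup")]] <- nrow(aln)
    }
    rna_aln[[tt]] <- aln
  }

  evidence <- list()
  snp_rates <- list()
  gene_rates <- list()
  classified <- list()
  for (receptor_tissue in tissues) {
    donor_tissue <- setdiff(tissues, receptor_tissue)
    donor_g <- config$tissue_genotype[[donor_tissue]]
    dir_label <- paste0(donor_tissue, "_to_", receptor_tissue)
    cls_r <- t_stage(paste0("classify ", dir_label), classify_reads(
      rna_aln[[receptor_tissue]], snps, consensi, donor = donor_g))
    cls_d <- t_stage(paste0("classify donor lib ", dir_label), classify_reads(
      rna_aln[[donor_tissue]], snps, consensi, donor = donor_g))
    classified[[dir_label]] <- list(receptor = cls_r, donor = cls_d)
    ev <- t_stage(paste0("detect ", dir_label), detect_transmitting_genes(
      cls_r, snps, direction = dir_label))
    evidence[[dir_label]] <- ev
    counts[[paste0("transmitting_", dir_label)]] <- sum(ev$transmitting)
    trans_genes <- ev$gene_id[ev$transmitting]
    sr <- t_stage(paste0("snp rates ", dir_label), snp_transmission_rates(
      cls_r, cls_d, snps, read_length = config$read_length,
      genes = trans_genes, rule = config$window_rule,
      contig_lengths = nchar(reference)))
    snp_rates[[dir_label]] <- sr
    gene_rates[[dir_label]] <- if (nrow(sr) > 0L)
      t_stage(paste0("gene rates ", dir_label), gene_transmission_rates(
        sr, direction = dir_label,
        min_donor_reads = config$min_donor_reads))
    else
      data.frame(gene_id = character(0), direction = character(0),
                 rate = numeric(0), n_snps = integer(0),
                 donor_reads = integer(0), receptor_reads = integer(0),
                 reportable = logical(0), stringsAsFactors = FALSE)
  }

  expression <- t_stage("rpkm", rpkm(
    do.call(rbind, rna_aln), gene_models,
    exclude_read_ids = config$exclude_read_ids))

  summary_tab <- t_stage("direction summary",
                         direction_summary(list(graft = evidence)))
  distribution <- lapply(gene_rates, rate_distribution)

  manifest <- list(
    package = "graftrans",
    seed = config$seed,
    thresholds = list(
      min_dominant_depth = config$min_dominant_depth,
      min_dominant_fraction = config$min_dominant_fraction,
      min_donor_reads = config$min_donor_reads,
      read_length = config$read_length,
      max_edit = config$max_edit, window_rule = config$window_rule,
      rna_dedup = config$rna_dedup),
    tissue_genotype = as.list(config$tissue_genotype),
    inputs = lapply(c(list(reference = config$reference,
                           gene_models = config$gene_models),
                      stats::setNames(config$genomic,
                                      paste0("genomic_", genotypes)),
                      stats::setNames(config$rna, paste0("rna_", tissues))),
                    function(x)
                      if (.is_path(x) && file.exists(x))
                        unname(tools::md5sum(x)) else "in-memory"),
    stage_counts = counts)

  result <- structure(list(
    calls = calls, snps = snps, evidence = evidence, snp_rates = snp_rates,
    gene_rates = gene_rates, expression = expression, summary = summary_tab,
    distribution = distribution, classified = classified,
    manifest = manifest, counts = counts), class = "graft_result")

  if (!is.null(config$outdir)) {
    t_stage("write outputs", {
      od <- config$outdir
      dir.create(od, recursive = TRUE, showWarnings = FALSE)
      unlink(file.path(od, "STALE"))
      for (g in genotypes)
        write_tsv(calls[[g]], file.path(od, paste0("homozygous_", g, ".tsv")))
      write_tsv(snps, file.path(od, "diagnostic_snps.tsv"))
      write_vcf(snps, file.path(od, "diagnostic_snps.vcf"),
                reference = reference)
      for (d in names(evidence)) {
        write_tsv(evidence[[d]], file.path(od, paste0("evidence_", d, ".tsv")))
        write_tsv(snp_rates[[d]], file.path(od, paste0("snp_rates_", d, ".tsv")))
        write_tsv(gene_rates[[d]],
                  file.path(od, paste0("gene_rates_", d, ".tsv")))
        write_tsv(distribution[[d]]$histogram,
                  file.path(od, paste0("rate_histogram_", d, ".tsv")))
      }
      write_tsv(expression, file.path(od, "expression_rpkm.tsv"))
      write_tsv(summary_tab$per_graft, file.path(od, "direction_summary.tsv"))
      jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    })
  }
  result
}

#' @export
print.graft_result <- function(x, ...) {
  cat("graft_result\n")
  cat("  diagnostic loci:", x$counts$diagnostic_loci, "\n")
  for (d in names(x$evidence))
    cat("  ", d, ": ", sum(x$evidence[[d]]$transmitting),
        " transmitting genes\n", sep = "")
  invisible(x)
}

#' Benchmark detection and rate recovery over a simulation grid
#'
#' For each grid cell a synthetic graft is generated in which half the genes
#' are non-mobile (fraction 0, the negatives) and half transmit at the cell's
#' fraction, then the full pipeline is run and compared with the truth:
#' detection sensitivity (over mobile genes with at least one diagnostic SNP
#' in their exon — genes without diagnostic loci are invisible to the
#' method), specificity over non-mobile genes, and bias and RMSE of the
#' reportable gene-rate estimates.
#'
#' @param base_config A [sim_config()] used as template.
#' @param fractions,depths,error_rates Grid values; the full crossing is run.
#' @return Data frame, one row per cell: grid values, `n_mobile_detectable`,
#'   `sensitivity`, `specificity`, `rate_bias`, `rate_rmse`.
#' @export
run_benchmark <- function(base_config, fractions = c(0.01, 0.1),
                          depths = base_config$genomic_depth,
                          error_rates = base_config$error_rate) {
  grid <- expand.grid(fraction = fractions, depth = depths,
                      error_rate = error_rates)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fr <- rep(c(0, grid$fraction[i]), length.out = base_config$n_genes)
    cfg <- sim_config(
      genome_length = base_config$genome_length,
      n_genes = base_config$n_genes, exon_length = base_config$exon_length,
      snp_density = base_config$snp_density,
      diagnostic_fraction = base_config$diagnostic_fraction,
      read_length = base_config$read_length, genomic_depth = grid$depth[i],
      rnaseq_reads_per_library = base_config$rnaseq_reads_per_library,
      error_rate = grid$error_rate[i],
      duplication_rate = base_config$duplication_rate,
      transmission_fractions = fr, seed = base_config$seed + i)
    sim <- simulate_graft_experiment(cfg)
    res <- run_graft_pipeline(pipeline_config(
      reference = sim$pair$reference, gene_models = sim$pair$genes,
      genomic = sim$genomic, rna = sim$rna[c("scion", "rootstock")],
      tissue_genotype = c(scion = "A", rootstock = "B"),
      read_length = cfg$read_length, seed = cfg$seed), verbose = FALSE)
    truth <- sim$pair$genes
    diag_loci <- sim$pair$snps[sim$pair$snps$diagnostic, , drop = FALSE]
    has_snp <- vapply(seq_len(nrow(truth)), function(k)
      any(diag_loci$contig == truth$contig[k] &
            diag_loci$pos >= truth$start[k] &
            diag_loci$pos <= truth$end[k]), TRUE)
    called <- unique(unlist(lapply(res$evidence, function(ev)
      ev$gene_id[ev$transmitting])))
    detectable <- truth$transmission_fraction > 0 & has_snp
    negatives <- truth$transmission_fraction == 0
    est <- do.call(rbind, res$gene_rates)
    est <- est[est$reportable, , drop = FALSE]
    est$truth <- truth$transmission_fraction[match(est$gene_id,
                                                   truth$gene_id)]
    err <- est$rate - est$truth
    rows[[i]] <- data.frame(
      fraction = grid$fraction[i], depth = grid$depth[i],
      error_rate = grid$error_rate[i],
      n_mobile_detectable = sum(detectable),
      sensitivity = if (sum(detectable) > 0)
        mean(truth$gene_id[detectable] %in% called) else NA_real_,
      specificity = if (sum(negatives) > 0)
        mean(!truth$gene_id[negatives] %in% called) else NA_real_,
      rate_bias = if (length(err) > 0) mean(err) else NA_real_,
      rate_rmse = if (length(err) > 0) sqrt(mean(err^2)) else NA_real_)
  }
  do.call(rbind, rows)
}
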