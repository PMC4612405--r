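#' @title Alignment tables
#' @description
#' Alignments flow through the package as plain data frames with columns
#' `read_id`, `library`, `contig`, `start` (1-based, fully closed), `strand`
#' (`+`/`-`), `seq` (the aligned sequence in reference-forward orientation)
#' and `nm` (edit distance to the reference; ungapped model, so `nm` equals
#' the number of mismatched positions).  Only unique-best, ungapped, fully
#' contained alignments are represented.
#' @name alignment-table
#' @keywords internal
NULL

.empty_alignments <- function() {
  data.frame(read_id = character(0), library = character(0),
             contig = character(0), start = integer(0), strand = character(0),
             seq = character(0), nm = integer(0), stringsAsFactors = FALSE)
}

.as_reads_df <- function(reads) {
  if (.is_path(reads) && file.exists(reads))
    return(read_fastq(reads))
  if (inherits(reads, "DNAStringSet"))
    return(data.frame(read_id = names(reads), seq = as.character(reads),
                      stringsAsFactors = FALSE))
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)))
  reads[, c("read_id", "seq")]
}

# exact k-mer index of the reference: data.table(kmer, contig, rpos)
.ref_kmer_index <- function(reference, k) {
  idx <- lapply(names(reference), function(ct) {
    L <- nchar(reference[[ct]])
    if (L < k) return(NULL)
    pos <- seq_len(L - k + 1L)
    data.table(kmer = substring(reference[[ct]], pos, pos + k - 1L),
               contig = ct, rpos = pos)
  })
  rbindlist(idx)
}

#' Built-in ungapped test aligner
#'
#' A minimal seed-and-verify aligner so synthetic FASTQ can be processed with
#' no external mapper.  Candidate loci come from exact k-mer seeds
#' (`max_edit + 1` disjoint seeds per read, so any alignment with at most
#' `max_edit` mismatches is guaranteed a candidate by pigeonhole); candidates
#' are verified by Hamming distance on both strands.  A read is emitted only
#' if it has exactly one best-scoring location with at most `max_edit`
#' mismatches; ties for best (including across strands) drop the read,
#' mirroring a "reads with one single best hit" filter.
#'
#' `max_edit` defaults to 4 for reads up to about 100 bp and 6 for 151-bp
#' reads, the conventional BWA settings for those lengths.
#'
#' @param reads FASTQ path, `DNAStringSet`, or data frame with `read_id`,
#'   `seq`.  All reads must share one length.
#' @param reference Named character vector of contig sequences, or FASTA path.
#' @param max_edit Maximum mismatches; `NULL` for the length-based default.
#' @param library_id Library label recorded in the output.
#' @return An alignment table (see [alignment-table]) sorted by
#'   (`contig`, `start`, `strand`, `read_id`).
#' @export
test_align <- function(reads, reference, max_edit = NULL, library_id = "lib") {
  reads <- .as_reads_df(reads)
  if (.is_path(reference) && file.exists(reference))
    reference <- read_fasta_seqs(reference)
  if (nrow(reads) == 0L) return(.empty_alignments())
  w <- unique(nchar(reads$seq))
  if (length(w) != 1L) stop("test_align requires a single read length")
  R <- w
  if (is.null(max_edit)) max_edit <- if (R >= 151L) 6L else 4L
  if (any(nchar(reference) < R)) stop("reference contig shorter than reads")

  useq <- unique(reads$seq)
  nu <- length(useq)
  # patterns in reference-forward orientation: the read itself (+) and its
  # reverse complement (-)
  pat_dt <- data.table(
    uread = rep(seq_len(nu), 2L),
    orient = rep(c("+", "-"), each = nu),
    pat = c(useq, revcomp(useq)))

  ns <- max_edit + 1L
  k <- R %/% ns
  if (k >= 8L) {
    refidx <- .ref_kmer_index(reference, k)
    off <- (seq_len(ns) - 1L) * k
    seeds <- data.table(
      pi = rep(seq_len(nrow(pat_dt)), each = ns),
      off = rep(off, nrow(pat_dt)),
      kmer = substring(rep(pat_dt$pat, each = ns),
                       rep(off, nrow(pat_dt)) + 1L,
                       rep(off, nrow(pat_dt)) + k))
    hits <- refidx[seeds, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
    hits[, cand_start := rpos - off]
    cand <- unique(hits[, .(pi, contig, cand_start)])
  } else {
    # tiny reads: exhaustively verify every position (test-scale inputs only)
    cand <- rbindlist(lapply(names(reference), function(ct) {
      n_pos <- nchar(reference[[ct]]) - R + 1L
      data.table(pi = rep(seq_len(nrow(pat_dt)), each = n_pos),
                 contig = ct,
                 cand_start = rep(seq_len(n_pos), nrow(pat_dt)))
    }))
  }
  clen <- nchar(reference)
  cand <- cand[cand_start >= 1L & cand_start + R - 1L <= clen[contig]]
  if (nrow(cand) == 0L) return(.empty_alignments())

  cand[, mm := NA_integer_]
  for (ct in unique(cand$contig)) {
    sel <- which(cand$contig == ct)
    cand$mm[sel] <- hamming_to_subject(pat_dt$pat[cand$pi[sel]],
                                       cand$cand_start[sel], reference[[ct]])
  }
  cand <- cand[mm <= max_edit]
  if (nrow(cand) == 0L) return(.empty_alignments())

  cand[, `:=`(uread = pat_dt$uread[pi], orient = pat_dt$orient[pi])]
  best <- cand[, .SD[mm == min(mm)], by = uread]
  n_best <- best[, .N, by = uread]
  best <- best[uread %in% n_best[N == 1L, uread]]
  if (nrow(best) == 0L) return(.empty_alignments())

  hit <- best[data.table(uread = match(reads$seq, useq),
                         read_id = reads$read_id),
              on = "uread", nomatch = NULL]
  out <- data.frame(read_id = hit$read_id, library = library_id,
                    contig = hit$contig, start = hit$cand_start,
                    strand = hit$orient, seq = pat_dt$pat[hit$pi],
                    nm = hit$mm, stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start, out$strand, out$read_id), ]
  rownames(out) <- NULL
  out
}

#' Read alignments from a SAM file
#'
#' Unmapped, secondary and supplementary records are excluded.  Gapped or
#' clipped records (CIGAR other than a single match run) fall outside the
#' ungapped model and are dropped with a warning.  Edit distance is
#' recomputed against `reference` when provided; otherwise the `NM` tag is
#' required.
#'
#' @param path SAM file (a proper `@SQ` header is required).
#' @param library_id Library label recorded in the output.
#' @param reference Optional named character vector (or FASTA path) used to
#'   recompute mismatches.
#' @return An alignment table (see [alignment-table]).
#' @export
read_sam <- function(path, library_id = "lib", reference = NULL) {
  if (!is.null(reference) && is.character(reference) &&
      length(reference) == 1L && file.exists(reference))
    reference <- read_fasta_seqs(reference)
  bam <- tryCatch(
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE),
    error = function(e) stop("malformed SAM '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "seq", "cigar"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(x$qname)
  if (n == 0L) return(.empty_alignments())
  nm_tag <- x$tag$NM
  if (is.null(nm_tag)) nm_tag <- rep(NA_integer_, n)
  out <- data.frame(read_id = x$qname, library = library_id,
                    contig = as.character(x$rname), start = x$pos,
                    strand = as.character(x$strand),
                    seq = as.character(x$seq), nm = as.integer(nm_tag),
                    stringsAsFactors = FALSE)
  ungapped <- grepl("^[0-9]+M$", x$cigar)
  if (any(!ungapped)) {
    warning(sum(!ungapped), " gapped/clipped record(s) dropped (ungapped model)")
    out <- out[ungapped, , drop = FALSE]
  }
  if (!is.null(reference)) {
    for (ct in unique(out$contig)) {
      sel <- which(out$contig == ct)
      out$nm[sel] <- hamming_to_subject(out$seq[sel], out$start[sel],
                                        reference[[ct]])
    }
  } else if (anyNA(out$nm)) {
    stop("cannot derive mismatches: no NM tags and no reference given")
  }
  rownames(out) <- NULL
  out
}

#' Write an alignment table to SAM
#'
#' Emits minimal single-end ungapped records with `NM` and `MD` tags.
#'
#' @param aln Alignment table.
#' @param reference Named character vector of contig sequences (for the
#'   header and the `MD` tag).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ct in names(reference))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ct, nchar(reference[[ct]])), con)
  if (nrow(aln) > 0L) {
    md <- .md_tags(aln, reference)
    w <- nchar(aln$seq)
    rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d\tMD:Z:%s",
                   aln$read_id, ifelse(aln$strand == "-", 16L, 0L), aln$contig,
                   aln$start, w, aln$seq, strrep("I", w), aln$nm, md)
    writeLines(rec, con)
  }
  invisible(path)
}

# MD tag strings for ungapped alignments
.md_tags <- function(aln, reference) {
  mism <- alignment_mismatches(aln, reference)
  md <- as.character(nchar(aln$seq))
  if (nrow(mism) == 0L) return(md)
  sp <- split(mism, mism$row)
  for (nm_row in names(sp)) {
    m <- sp[[nm_row]]
    i <- as.integer(nm_row)
    o <- order(m$pos)
    rel <- m$pos[o] - aln$start[i] + 1L
    runs <- diff(c(0L, rel)) - 1L
    md[i] <- paste0(paste0(runs, m$ref_base[o], collapse = ""),
                    nchar(aln$seq[i]) - rel[length(rel)])
  }
  md
}

#' Mismatch positions of alignments against the reference
#'
#' @param aln Alignment table.
#' @param reference Named character vector of contig sequences.
#' @return Data frame with one row per mismatched base: `row` (row index in
#'   `aln`), `read_id`, `contig`, `pos` (1-based reference position),
#'   `ref_base`, `read_base`.
#' @export
alignment_mismatches <- function(aln, reference) {
  out <- list()
  for (ct in unique(aln$contig)) {
    sel <- which(aln$contig == ct)
    widths <- nchar(aln$seq[sel])
    subj <- Biostrings::DNAString(reference[[ct]])
    for (wk in unique(widths)) {
      s2 <- sel[widths == wk]
      m1 <- as.matrix(Biostrings::DNAStringSet(aln$seq[s2]))
      m2 <- as.matrix(Biostrings::extractAt(
        subj, IRanges::IRanges(aln$start[s2], width = wk)))
      hit <- which(m1 != m2, arr.ind = TRUE)
      if (nrow(hit) == 0L) next
      r <- s2[hit[, 1L]]
      out[[length(out) + 1L]] <- data.frame(
        row = r, read_id = aln$read_id[r], contig = ct,
        pos = aln$start[r] + hit[, 2L] - 1L,
        ref_base = m2[hit], read_base = m1[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(row = integer(0), read_id = character(0),
                      contig = character(0), pos = integer(0),
                      ref_base = character(0), read_base = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$row, res$pos), ]
  rownames(res) <- NULL
  res
}

#' Remove PCR duplicates by mapping coordinates
#'
#' Among records sharing (`library`, `contig`, `start`, `strand`) exactly one
#' representative is kept — the lexicographically smallest `read_id`, so the
#' output is deterministic.  Idempotent by construction.
#'
#' @param aln Alignment table.
#' @return Alignment table with duplicates removed, sorted by
#'   (`library`, `contig`, `start`, `strand`).
#' @export
remove_duplicates <- function(aln) {
  dt <- as.data.table(aln)
  setorder(dt, library, contig, start, strand, read_id)
  out <- as.data.frame(dt[!duplicated(dt,
    by = c("library", "contig", "start", "strand"))])
  rownames(out) <- NULL
  out
}

#' Per-position base coverage (pileup)
#'
#' Counts, for every covered reference position and library, the number of
#' retained reads supporting each of A, C, G and T.  Positions with zero
#' coverage are omitted.  Upstream filters (unique-best alignment, duplicate
#' removal) are the caller's responsibility.
#'
#' @param aln Alignment table.
#' @return Data frame with columns `library`, `contig`, `pos`, `A`, `C`, `G`,
#'   `T`, sorted by (`library`, `contig`, `pos`).
#' @export
pileup <- function(aln) {
  empty <- data.frame(library = character(0), contig = character(0),
                      pos = integer(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), stringsAsFactors = FALSE)
  if (nrow(aln) == 0L) return(empty)
  w <- nchar(aln$seq)
  bases <- strsplit(aln$seq, "", fixed = TRUE)
  dt <- data.table(
    library = rep(aln$library, w), contig = rep(aln$contig, w),
    pos = rep(aln$start, w) + sequence(w) - 1L, base = unlist(bases))
  dt <- dt[base %in% DNA_BASES]
  if (nrow(dt) == 0L) return(empty)
  counts <- dcast(dt, library + contig + pos ~ base, fun.aggregate = length,
                  value.var = "base")
  for (b in DNA_BASES) if (is.null(counts[[b]])) counts[, (b) := 0L]
  setorder(counts, library, contig, pos)
  out <- as.data.frame(counts[, c("library", "contig", "pos", DNA_BASES),
                              with = FALSE])
  rownames(out) <- NULL
  out
}
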