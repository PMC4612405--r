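#' Random DNA sequence
#'
#' Uniform i.i.d. base composition; used by the simulator for reference
#' genomes.
#'
#' @param n Sequence length in bases.
#' @return A single character string of `n` bases.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse-complement character sequences
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

DNA_BASES <- c("A", "C", "G", "T")

# Vectorized uniform substitution errors on equal-width sequences.
# The total error count is binomial over all sequenced bases; positions are
# then placed uniformly, so several errors can hit one read.
add_seq_errors <- function(seqs, error_rate) {
  n <- length(seqs)
  if (n == 0L || error_rate <= 0) return(seqs)
  w <- nchar(seqs)
  stopifnot(length(unique(w)) == 1L)
  R <- w[1L]
  total <- stats::rbinom(1L, n * R, error_rate)
  if (total == 0L) return(seqs)
  idx <- sample.int(n * R, total)
  read_i <- (idx - 1L) %/% R + 1L
  pos_i <- (idx - 1L) %% R + 1L
  shift <- sample.int(3L, total, replace = TRUE)
  # substr<- drops all but the last assignment for duplicated read indices,
  # so apply one error per read per round
  rank <- stats::ave(seq_len(total), read_i, FUN = seq_along)
  for (r in seq_len(max(rank))) {
    sel <- rank == r
    ri <- read_i[sel]; pi <- pos_i[sel]
    cur <- substr(seqs[ri], pi, pi)
    new <- DNA_BASES[((match(cur, DNA_BASES) - 1L + shift[sel]) %% 4L) + 1L]
    s <- seqs[ri]
    substr(s, pi, pi) <- new
    seqs[ri] <- s
  }
  seqs
}

# Hamming distances of equal-width sequences against windows of a single
# subject sequence, chunked to bound memory.
hamming_to_subject <- function(seqs, starts, subject, chunk = 100000L) {
  n <- length(seqs)
  if (n == 0L) return(integer(0))
  subj <- Biostrings::DNAString(subject)
  w <- nchar(seqs)
  out <- integer(n)
  for (i in seq(1L, n, by = chunk)) {
    j <- min(i + chunk - 1L, n)
    ww <- unique(w[i:j])
    for (width_k in ww) {
      sel <- which(w[i:j] == width_k) + i - 1L
      m1 <- as.matrix(Biostrings::DNAStringSet(seqs[sel]))
      m2 <- as.matrix(Biostrings::extractAt(
        subj, IRanges::IRanges(starts[sel], width = width_k)))
      out[sel] <- as.integer(rowSums(m1 != m2))
    }
  }
  out
}

# single unnamed character string = candidate file path (named character
# vectors are in-memory sequences)
.is_path <- function(x) {
  is.character(x) && length(x) == 1L && is.null(names(x)) && nchar(x) < 500L
}

# read a FASTA file into a named character vector of contig sequences
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write simulated reads to FASTQ
#'
#' Qualities are a constant placeholder ("I", Q40): the simulator models
#' substitution error directly, not quality-score realism.
#'
#' @param reads Data frame with columns `read_id` and `seq`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  q <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a reads table
#'
#' @param path FASTQ file.
#' @return Data frame with columns `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(x)), seq = as.character(x))
}

# deterministic TSV writer (fixed options so runs are byte-identical)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
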