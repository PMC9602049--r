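DNA_BASES <- c("A", "C", "G", "T")

# non-import use of data.table's `[` syntax
.datatable.aware <- TRUE

#' Stable sequence-derived piRNA identifier
#'
#' Maps a tag sequence to an identifier of the form `piR-ame-<digits>` via a
#' 32-bit FNV-1a hash of the DNA string. The mapping is deterministic and
#' independent of genomic position, so the same sequence receives the same
#' identifier across runs and data sets. Collisions among distinct sequences
#' are resolved deterministically by appending `.2`, `.3`, ... in
#' lexicographic sequence order.
#'
#' @param sequences character vector of DNA sequences (A/C/G/T).
#' @return character vector of identifiers, one per sequence.
#' @export
#' @examples
#' pirna_id(c("ACGTACGTACGTACGTACGTACGT"))
pirna_id <- function(sequences) {
  stopifnot(is.character(sequences))
  if (!length(sequences)) return(character(0))
  us <- sort(unique(sequences))
  base <- sprintf("piR-ame-%07d", fnv1a_hash(us) %% 1e7)
  nth <- stats::ave(seq_along(base), base, FUN = seq_along)
  uid <- ifelse(nth > 1L, paste0(base, ".", nth), base)
  uid[match(sequences, us)]
}

# reverse complement for plain character vectors
rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

dna_to_rna <- function(x) chartr("T", "U", x)

#' Write reads to a FASTQ file with constant qualities
#'
#' @param sequences character vector of read sequences.
#' @param path output file.
#' @param prefix read-name prefix.
#' @param qual single quality character (Phred+33) applied to every base.
#' @return `path`, invisibly.
#' @keywords internal
write_fastq <- function(sequences, path, prefix = "read", qual = "I") {
  dna <- Biostrings::DNAStringSet(sequences)
  names(dna) <- sprintf("%s_%06d", prefix, seq_along(dna))
  quals <- Biostrings::BStringSet(strrep(qual, Biostrings::width(dna)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = quals)
  invisible(path)
}

# Structural FASTQ check so parse failures report a line number.
validate_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4 (near line %d)",
                 path, n, n), call. = FALSE)
  }
  if (n == 0L) return(invisible(TRUE))
  at <- seq(1L, n, by = 4L)
  bad_hdr <- at[!startsWith(lines[at], "@")]
  if (length(bad_hdr)) {
    stop(sprintf("malformed FASTQ '%s': record header at line %d does not start with '@'",
                 path, bad_hdr[1]), call. = FALSE)
  }
  bad_sep <- (at + 2L)[!startsWith(lines[at + 2L], "+")]
  if (length(bad_sep)) {
    stop(sprintf("malformed FASTQ '%s': separator at line %d does not start with '+'",
                 path, bad_sep[1]), call. = FALSE)
  }
  invisible(TRUE)
}

read_fastq_sequences <- function(path) {
  validate_fastq(path)
  if (length(readLines(path, n = 1L)) == 0L) return(character(0))
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
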