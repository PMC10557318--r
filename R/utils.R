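# Internal helpers. All genomic coordinates inside the package are 0-based,
# half-open; conversion to 1-based happens only at rendering boundaries.

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (ACGTN alphabet).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAGG"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based half-open substring of a single sequence
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

# one character at 0-based position i
char_at <- function(seq, i) substr(seq, i + 1L, i + 1L)

check_dna <- function(x, what = "sequence", allow_empty = FALSE) {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf("%s contains non-ACGTN characters (first offender: %s)",
                  what, x[bad][1]))
  }
  if (!allow_empty && any(nchar(x) == 0)) {
    abort(sprintf("%s must be non-empty", what))
  }
  invisible(x)
}

#' Load or coerce a reference sequence set
#'
#' Accepts a named character vector, a [Biostrings::DNAStringSet], or the path
#' to a (multi-record) FASTA file, and returns a named uppercase character
#' vector of sequences keyed by chromosome/amplicon name.
#'
#' @param ref Named character vector, `DNAStringSet`, or FASTA path.
#' @return Named character vector of uppercase DNA sequences.
#' @export
load_reference <- function(ref) {
  if (inherits(ref, "DNAStringSet")) {
    out <- as.character(ref)
  } else if (is.character(ref) && length(ref) == 1 && file.exists(ref) &&
             is.null(names(ref))) {
    out <- as.character(Biostrings::readDNAStringSet(ref))
    # FASTA headers may carry descriptions; keep the first word as the name
    names(out) <- sub("\\s.*$", "", names(out))
  } else if (is.character(ref)) {
    if (is.null(names(ref)) || any(names(ref) == "")) {
      abort("reference sequences must be named")
    }
    out <- ref
  } else {
    abort("`ref` must be a named character vector, DNAStringSet, or FASTA path")
  }
  out <- toupper(out)
  check_dna(out, "reference")
  out
}

ref_seq <- function(ref, chrom) {
  if (!chrom %in% names(ref)) {
    abort(sprintf("chromosome '%s' not present in reference", chrom))
  }
  unname(ref[[chrom]])
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Apply uniform substitution errors at per-base rate `err` to a character
# vector of reads. Only reads drawing >= 1 error are touched.
add_substitution_errors <- function(reads, err) {
  if (err <= 0 || length(reads) == 0) return(reads)
  lens <- nchar(reads)
  n_err <- rbinom(length(reads), lens, err)
  idx <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(lens[i], n_err[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

# Lower-middle median: for even n the lower of the two central order
# statistics is reported (documented choice for size summaries).
median_lower <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Write reads to FASTQ
#'
#' Writes a read tibble (columns `read_id`, `seq`) to an uncompressed FASTQ
#' file with a constant Q30-equivalent quality string; base qualities are not
#' used by any downstream step.
#'
#' @param reads Tibble with columns `read_id` and `seq`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  dss <- Biostrings::DNAStringSet(reads$seq)
  names(dss) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("?", nchar(reads$seq)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ (or FASTA) file into a read tibble
#'
#' @param path FASTQ or FASTA path.
#' @param format `"fastq"` (default) or `"fasta"`.
#' @return Tibble with columns `read_id`, `seq`.
#' @export
read_fastq <- function(path, format = "fastq") {
  dss <- Biostrings::readDNAStringSet(path, format = format)
  tibble(read_id = sub("\\s.*$", "", names(dss)),
         seq = unname(toupper(as.character(dss))))
}

# Coerce reads given as tibble / named character / DNAStringSet / FASTQ path
as_read_tbl <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "seq") %in% names(reads)))
    return(as_tibble(reads[, c("read_id", "seq")]))
  }
  if (inherits(reads, "DNAStringSet")) {
    return(tibble(read_id = names(reads) %||% as.character(seq_along(reads)),
                  seq = as.character(reads)))
  }
  if (is.character(reads) && length(reads) == 1 && file.exists(reads) &&
      is.null(names(reads))) {
    return(read_fastq(reads))
  }
  if (is.character(reads)) {
    ids <- names(reads) %||% paste0("read", seq_along(reads))
    return(tibble(read_id = ids, seq = unname(toupper(reads))))
  }
  abort("`reads` must be a tibble, named character vector, DNAStringSet, or FASTQ path")
}
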