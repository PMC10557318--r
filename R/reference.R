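# Target-site model: sgRNA targets on a reference mini-genome / amplicon set.
#
# A target site is one row of a tibble with columns gene_id, chrom, strand,
# protospacer (20 nt, protospacer-strand orientation), pam (NGG), and
# protospacer_start (0-based plus-strand offset of the leftmost base of the
# protospacer footprint). The Cas9 cut coordinate is derived, never stored in
# the input table.

target_cols <- c("gene", "chrom", "strand", "protospacer", "pam",
                 "protospacer_start")

#' Infer the Cas9 cut coordinate for target sites
#'
#' SpCas9 cuts bluntly 3 bp 5' of the PAM, i.e. between protospacer bases 17
#' and 18 (1-based) on the protospacer strand. The returned coordinate is a
#' 0-based inter-base position on the plus strand of the reference: for a
#' plus-strand protospacer starting at `p` the cut is `p + 17`; for a
#' minus-strand protospacer occupying plus-strand bases `[p, p + 20)` the cut
#' maps back to `p + 3`.
#'
#' @param targets Tibble with columns `strand` and `protospacer_start`.
#' @return `targets` with a `cut_pos` column added (0-based inter-base).
#' @export
infer_cut_site <- function(targets) {
  stopifnot(all(c("strand", "protospacer_start") %in% names(targets)))
  targets$cut_pos <- ifelse(targets$strand == "+",
                            targets$protospacer_start + 17L,
                            targets$protospacer_start + 3L)
  targets$cut_pos <- as.integer(targets$cut_pos)
  targets
}

#' Load and validate sgRNA target sites
#'
#' Reads a tab-separated target-definition table (columns `gene`, `chrom`,
#' `strand`, `protospacer`, `pam`, `protospacer_start`) or an equivalent
#' data frame, validates every row against the reference, and fills in the
#' Cas9 cut coordinate.
#'
#' Validation per row: the protospacer matches the reference at the stated
#' 0-based coordinates on the stated strand (reverse-complemented for minus
#' strand), the PAM is immediately 3' of the protospacer on the protospacer
#' strand and matches NGG, and gene identifiers are unique. Targets sharing
#' a cut coordinate are retained with a warning.
#'
#' @param path TSV path or a data frame with the columns above.
#' @param ref Reference, as accepted by [load_reference()].
#' @param window_halfwidth Classification window half-width around the cut,
#'   in bp (default 25; covers the longest expected deletion with margin).
#' @return Tibble of validated target sites with columns `gene_id`, `chrom`,
#'   `strand`, `protospacer`, `pam`, `protospacer_start`, `cut_pos`,
#'   `window_halfwidth`.
#' @export
load_targets <- function(path, ref, window_halfwidth = 25L) {
  ref <- load_reference(ref)
  tbl <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  missing_cols <- setdiff(target_cols, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("target table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  tbl <- tbl[, target_cols]
  names(tbl)[names(tbl) == "gene"] <- "gene_id"
  if (nrow(tbl) == 0) {
    out <- tbl
    out$cut_pos <- integer(0)
    out$window_halfwidth <- integer(0)
    return(out)
  }
  tbl$protospacer <- toupper(tbl$protospacer)
  tbl$pam <- toupper(tbl$pam)
  tbl$protospacer_start <- as.integer(tbl$protospacer_start)

  if (anyDuplicated(tbl$gene_id)) {
    abort(sprintf("duplicate gene_id in target table: '%s'",
                  tbl$gene_id[duplicated(tbl$gene_id)][1]))
  }
  for (i in seq_len(nrow(tbl))) {
    row <- tbl[i, ]
    where <- sprintf("target table row %d (%s)", i, row$gene_id)
    if (!row$strand %in% c("+", "-")) {
      abort(sprintf("%s: malformed strand '%s'", where, row$strand))
    }
    if (nchar(row$protospacer) != 20 || grepl("[^ACGT]", row$protospacer)) {
      abort(sprintf("%s: protospacer must be 20-nt ACGT", where))
    }
    if (!grepl("^[ACGT]GG$", row$pam)) {
      abort(sprintf("%s: PAM '%s' does not match NGG", where, row$pam))
    }
    chrom_seq <- ref_seq(ref, row$chrom)
    ps <- row$protospacer_start
    if (row$strand == "+") {
      if (ps < 0 || ps + 23 > nchar(chrom_seq)) {
        abort(sprintf("%s: protospacer+PAM outside reference bounds", where))
      }
      if (subseq0(chrom_seq, ps, ps + 20) != row$protospacer) {
        abort(sprintf("%s: protospacer does not match the reference", where))
      }
      if (subseq0(chrom_seq, ps + 20, ps + 23) != row$pam) {
        abort(sprintf("%s: PAM does not match the reference", where))
      }
    } else {
      if (ps - 3 < 0 || ps + 20 > nchar(chrom_seq)) {
        abort(sprintf("%s: protospacer+PAM outside reference bounds", where))
      }
      if (subseq0(chrom_seq, ps, ps + 20) != revcomp(row$protospacer)) {
        abort(sprintf("%s: protospacer does not match the reference", where))
      }
      if (subseq0(chrom_seq, ps - 3, ps) != revcomp(row$pam)) {
        abort(sprintf("%s: PAM does not match the reference", where))
      }
    }
  }
  out <- infer_cut_site(tbl)
  out$window_halfwidth <- as.integer(window_halfwidth)
  dup_cut <- duplicated(out[, c("chrom", "cut_pos")])
  if (any(dup_cut)) {
    warn(sprintf("targets share a cut coordinate: %s",
                 paste(out$gene_id[out$chrom %in% out$chrom[dup_cut] &
                                     out$cut_pos %in% out$cut_pos[dup_cut]],
                       collapse = ", ")))
  }
  out
}

#' Write target sites back to the tab-separated table format
#'
#' Writes the canonical input columns so that [load_targets()] on the result
#' round-trips to identical records.
#'
#' @param targets Target tibble from [load_targets()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  out <- targets[, c("gene_id", "chrom", "strand", "protospacer", "pam",
                     "protospacer_start")]
  names(out)[1] <- "gene"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Export classification windows as BED6
#'
#' One record per target: the window `[cut_pos - w, cut_pos + w)` in 0-based
#' half-open BED coordinates, named by `gene_id`, scored 0, with the
#' protospacer strand.
#'
#' @param targets Target tibble.
#' @param path Optional output path; when `NULL` the BED tibble is returned.
#' @return BED6 tibble (invisibly, when `path` is given).
#' @export
targets_to_bed <- function(targets, path = NULL) {
  bed <- tibble(
    chrom = targets$chrom,
    start = targets$cut_pos - targets$window_halfwidth,
    end = targets$cut_pos + targets$window_halfwidth,
    name = targets$gene_id,
    score = 0L,
    strand = targets$strand
  )
  if (!is.null(path)) {
    readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
    return(invisible(bed))
  }
  bed
}

# Protospacer-strand amplicon around a site's cut. Returns the sequence, the
# cut offset within it, and the plus-strand bounds it came from. The window
# is symmetric, so minus-strand handling is a plain reverse complement.
site_amplicon <- function(ref, site, halfwidth = 110L) {
  chrom_seq <- ref_seq(ref, site$chrom)
  lo <- max(0L, site$cut_pos - halfwidth)
  hi <- min(nchar(chrom_seq), site$cut_pos + halfwidth)
  seq <- subseq0(chrom_seq, lo, hi)
  if (site$strand == "+") {
    list(seq = seq, cut_offset = site$cut_pos - lo, lo = lo, hi = hi)
  } else {
    list(seq = revcomp(seq), cut_offset = hi - site$cut_pos, lo = lo, hi = hi)
  }
}

#' Load genic annotation intervals
#'
#' Accepts a data frame with columns `chrom`, `start`, `end`, `type`
#' (0-based half-open), a BED path whose name column carries the feature
#' type, or a GFF3 path (requires the rtracklayer package; GFF 1-based
#' coordinates are converted). Feature types beyond
#' `promoter`, `5'UTR`, `exon`, `3'UTR`, `intron` are dropped with a warning.
#'
#' @param x Data frame or file path.
#' @return Tibble with columns `chrom`, `start`, `end`, `type`.
#' @export
load_annotation <- function(x) {
  known <- c("promoter", "5'UTR", "exon", "3'UTR", "intron")
  if (is.data.frame(x)) {
    tbl <- as_tibble(x[, c("chrom", "start", "end", "type")])
  } else if (grepl("\\.gff3?$", x, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GFF3 annotation requires the rtracklayer package")
    }
    df <- as.data.frame(rtracklayer::import(x))
    tbl <- tibble(
      chrom = as.character(df$seqnames),
      start = df$start - 1L,
      end = df$end,
      type = as.character(df$type)
    )
  } else {
    tbl <- readr::read_tsv(x, col_names = c("chrom", "start", "end", "type"),
                           show_col_types = FALSE, progress = FALSE)
  }
  bad <- !tbl$type %in% known
  if (any(bad)) {
    warn(sprintf("dropping %d annotation interval(s) with unknown type", sum(bad)))
    tbl <- tbl[!bad, ]
  }
  if (any(tbl$start < 0) || any(tbl$end <= tbl$start)) {
    abort("annotation intervals must be non-negative, half-open, non-empty")
  }
  tbl
}
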