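# Read-to-amplicon alignment and cut-anchored edit classification.
#
# Reads are aligned globally (with affine gaps) to their target amplicon,
# the amplicon being local so partial-length reads fit anywhere inside it.
# Indels inside the classification window around the Cas9 cut are
# canonicalized to the placement nearest the cut and reported in the
# "Del a|b" / "Ins n seq" notation.

default_scoring <- function() {
  list(match = 2, mismatch = -4, gap_open = 10, gap_ext = 1)
}

sub_matrix <- function(scoring) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- scoring$match
  m["N", ] <- scoring$mismatch
  m[, "N"] <- scoring$mismatch
  m
}

#' Align reads to an amplicon
#'
#' Optimal alignment under configurable affine-gap scoring (defaults:
#' match +2, mismatch -4, gap open -10, gap extension -1 per base; a gap
#' of length L costs open + L * extension), computed by a compiled
#' affine-gap dynamic program. The read is aligned end-to-end
#' against a local region of the amplicon, so reads shorter than the
#' amplicon are placed freely within it.
#'
#' @param reads Reads as a tibble (`read_id`, `seq`), named character vector,
#'   `DNAStringSet`, or FASTQ path.
#' @param amplicon Amplicon/reference DNA string.
#' @param scoring Named list with `match`, `mismatch`, `gap_open`, `gap_ext`.
#' @param cigar Compute CIGAR strings (skipped internally for speed).
#' @return Tibble with one row per read: `read_id`, `seq`, `score`,
#'   `subj_start`/`subj_end` (0-based half-open aligned span on the
#'   amplicon), `cigar`, and the gapped `pattern_aln`/`subject_aln` strings.
#' @export
align_reads <- function(reads, amplicon, scoring = default_scoring(),
                        cigar = TRUE) {
  tbl <- as_read_tbl(reads)
  check_dna(amplicon, "amplicon")
  check_dna(tbl$seq, "reads")
  if (nrow(tbl) == 0) {
    return(tibble(read_id = character(0), seq = character(0),
                  score = numeric(0), subj_start = integer(0),
                  subj_end = integer(0), cigar = character(0),
                  pattern_aln = character(0), subject_aln = character(0)))
  }
  uniq <- unique(tbl$seq)
  aln <- .fit_align_cpp(uniq, amplicon, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_ext)
  cigars <- if (cigar) {
    purrr::map2_chr(aln$pattern_aln, aln$subject_aln, aln_cigar)
  } else {
    NA_character_
  }
  per_uniq <- tibble(seq = uniq, score = aln$score,
                     subj_start = aln$subj_start, subj_end = aln$subj_end,
                     cigar = cigars, pattern_aln = aln$pattern_aln,
                     subject_aln = aln$subject_aln)
  left_join(tbl, per_uniq, by = "seq")
}

aln_ops <- function(pattern_aln, subject_aln) {
  p <- strsplit(pattern_aln, "", fixed = TRUE)[[1]]
  s <- strsplit(subject_aln, "", fixed = TRUE)[[1]]
  op <- ifelse(p == "-", "D", ifelse(s == "-", "I", "M"))
  list(p = p, s = s, op = op, rle = rle(op))
}

aln_cigar <- function(pattern_aln, subject_aln) {
  r <- aln_ops(pattern_aln, subject_aln)$rle
  paste0(r$lengths, r$values, collapse = "")
}

# Extract indel/substitution events from one gapped alignment.
# Coordinates are 0-based on the subject (amplicon), offset by subj_start.
aln_events <- function(pattern_aln, subject_aln, subj_start) {
  a <- aln_ops(pattern_aln, subject_aln)
  ends <- cumsum(a$rle$lengths)
  starts <- ends - a$rle$lengths + 1L
  # subject coordinate before each column
  subj_pos <- subj_start + c(0L, cumsum(a$s != "-"))
  dels <- list(); inss <- list()
  for (k in seq_along(a$rle$values)) {
    v <- a$rle$values[k]
    if (v == "M") next
    i0 <- starts[k]; i1 <- ends[k]
    if (v == "D") {
      dels[[length(dels) + 1L]] <- c(subj_pos[i0], subj_pos[i1 + 1L])
    } else {
      inss[[length(inss) + 1L]] <- list(
        pos = subj_pos[i0],
        seq = paste(a$p[i0:i1], collapse = "")
      )
    }
  }
  m <- a$op == "M" & a$p != a$s
  subst_pos <- subj_pos[which(m)]  # 0-based positions of mismatches
  list(dels = dels, inss = inss, subst_pos = subst_pos,
       subst_read = a$p[which(m)])
}

#' Classify edits in reads relative to a cut position
#'
#' Aligns reads to an amplicon (in protospacer-strand orientation) and
#' classifies the editing outcome inside the window
#' `[cut - window_halfwidth, cut + window_halfwidth)`. Indels inside the
#' window are canonicalized to the score-equivalent placement nearest the
#' cut (ties resolved to the 5' side); indels outside the window are
#' ignored; substitution-only reads count as `WT` (with `n_subst` retained
#' for QC). Reads are discarded, with a reason code, when the alignment
#' score falls below `min_score_frac * match * read length`
#' (`poor_alignment`), when the aligned span does not cover the full window
#' (`incomplete_window`), or when more than one disjoint deletion or more
#' than one insertion lies inside the window (`complex`).
#'
#' @inheritParams align_reads
#' @param cut 0-based inter-base cut offset within `amplicon`.
#' @param window_halfwidth Window half-width in bp (default 25).
#' @param min_score_frac Alignment score floor as a fraction of the maximal
#'   score of a read of that length (default 0.4).
#' @param orientation `"auto"` retries reads failing the score floor as
#'   reverse complements (orientation normalization to the protospacer
#'   strand); `"forward"` does not.
#' @param min_promote_ins Minimum inserted length for reinterpreting a
#'   deletion with adjacent window substitutions as a combined
#'   deletion+insertion outcome (default 2: at the read level a 1-bp insert
#'   next to a deletion is indistinguishable from a deletion read with one
#'   adjacent sequencing error; error-free Sanger clones use 1).
#' @return Tibble with columns `read_id`, `category`
#'   (`WT`/`DEL`/`INS`/`DELINS`/`DISCARD`), `del_left`, `del_right`,
#'   `ins_seq`, `label`, `reason`, `n_subst`, `score`.
#' @export
classify_edits <- function(reads, amplicon, cut,
                           window_halfwidth = 25L,
                           scoring = default_scoring(),
                           min_score_frac = 0.4,
                           orientation = c("auto", "forward"),
                           min_promote_ins = 2L) {
  orientation <- match.arg(orientation)
  tbl <- as_read_tbl(reads)
  if (nrow(tbl) == 0) {
    return(empty_calls())
  }
  w <- as.integer(window_halfwidth)
  cut <- as.integer(cut)
  if (cut - w < 0 || cut + w > nchar(amplicon)) {
    abort("classification window extends past the amplicon")
  }
  uniq <- tibble(seq = unique(tbl$seq))
  aln <- align_reads(uniq$seq, amplicon, scoring = scoring, cigar = FALSE)
  floor_score <- min_score_frac * scoring$match * nchar(uniq$seq)
  poor <- aln$score < floor_score
  if (orientation == "auto" && any(poor)) {
    rc <- revcomp(uniq$seq[poor])
    aln_rc <- align_reads(rc, amplicon, scoring = scoring, cigar = FALSE)
    better <- aln_rc$score > aln$score[poor]
    idx <- which(poor)[better]
    keep_cols <- setdiff(names(aln), c("read_id", "seq"))
    aln[idx, keep_cols] <- aln_rc[better, keep_cols]
    poor <- aln$score < floor_score
  }
  nu <- nrow(aln)
  category <- character(nu); del_left <- rep(NA_integer_, nu)
  del_right <- rep(NA_integer_, nu); ins_seq <- rep(NA_character_, nu)
  lab <- rep(NA_character_, nu); reason <- rep(NA_character_, nu)
  n_subst <- rep(NA_integer_, nu)
  for (k in seq_len(nu)) {
    cl <- classify_one(aln$pattern_aln[k], aln$subject_aln[k],
                       aln$subj_start[k], aln$subj_end[k], poor[k],
                       aln$score[k], amplicon, cut, w, min_promote_ins)
    category[k] <- cl$category
    del_left[k] <- cl$del_left; del_right[k] <- cl$del_right
    ins_seq[k] <- cl$ins_seq; lab[k] <- cl$label; reason[k] <- cl$reason
    n_subst[k] <- cl$n_subst
  }
  per_uniq <- tibble(seq = aln$seq, category = category, del_left = del_left,
                     del_right = del_right, ins_seq = ins_seq, label = lab,
                     reason = reason, n_subst = n_subst, score = aln$score)
  out <- left_join(tbl, per_uniq, by = "seq")
  out$seq <- NULL
  out
}

empty_calls <- function() {
  tibble(read_id = character(0), category = character(0),
         del_left = integer(0), del_right = integer(0),
         ins_seq = character(0), label = character(0),
         reason = character(0), n_subst = integer(0), score = numeric(0))
}

discard_call <- function(reason, score) {
  list(category = "DISCARD", del_left = NA_integer_, del_right = NA_integer_,
       ins_seq = NA_character_, label = NA_character_, reason = reason,
       n_subst = NA_integer_, score = score)
}


# read bases aligned over the subject range [i0, i1) (M/mismatch columns)
read_bases_over <- function(pattern_aln, subject_aln, subj_start, i0, i1) {
  a <- aln_ops(pattern_aln, subject_aln)
  subj_pos <- subj_start + c(0L, cumsum(a$s != "-"))
  keep <- a$op == "M" & subj_pos[-length(subj_pos)] >= i0 &
    subj_pos[-length(subj_pos)] < i1
  paste(a$p[keep], collapse = "")
}

# longest common prefix/suffix trim of two segments (non-overlapping)
trim_common_ends <- function(ref, read) {
  p <- 0L
  nmin <- min(nchar(ref), nchar(read))
  while (p < nmin && substr(ref, p + 1, p + 1) == substr(read, p + 1, p + 1)) {
    p <- p + 1L
  }
  s <- 0L
  while (s < nmin - p &&
         substr(ref, nchar(ref) - s, nchar(ref) - s) ==
           substr(read, nchar(read) - s, nchar(read) - s)) {
    s <- s + 1L
  }
  list(prefix = p, suffix = s,
       ref = substr(ref, p + 1, nchar(ref) - s),
       read = substr(read, p + 1, nchar(read) - s))
}

classify_one <- function(pattern_aln, subject_aln, subj_start, subj_end,
                         is_poor, score, amplicon, cut, w,
                         min_promote_ins = 2L) {
  if (is_poor) return(discard_call("poor_alignment", score))
  if (subj_start > cut - w || subj_end < cut + w) {
    return(discard_call("incomplete_window", score))
  }
  ev <- aln_events(pattern_aln, subject_aln, subj_start)
  # Under affine-gap scoring a deletion-plus-insertion at the break aligns
  # more cheaply as a shorter deletion with the inserted bases mismatched
  # against adjacent reference bases. Reinterpret that signature -- one
  # deletion whose window substitutions form runs touching the gap -- as
  # the combined outcome, recovering "Del a|b Ins n" labels.
  promoted <- NULL
  win_sub <- ev$subst_pos >= cut - w & ev$subst_pos < cut + w
  if (length(ev$dels) == 1 && length(ev$inss) == 0 && any(win_sub)) {
    d <- ev$dels[[1]]
    sp <- sort(ev$subst_pos[win_sub])
    i0 <- min(d[1], sp[1]); i1 <- max(d[2], sp[length(sp)] + 1L)
    n_between <- (i1 - i0) - (d[2] - d[1]) - length(sp)
    if (i0 >= cut - w && i1 <= cut + w && n_between <= 4L &&
        length(sp) <= 8L) {
      refseg <- subseq0(amplicon, i0, i1)
      readseg <- read_bases_over(pattern_aln, subject_aln, subj_start, i0, i1)
      tr <- trim_common_ends(refseg, readseg)
      if (nchar(tr$ref) > 0 && nchar(tr$read) >= min_promote_ins &&
          nchar(tr$read) <= 8) {
        promoted <- list(del = c(i0 + tr$prefix, i1 - tr$suffix),
                         ins = tr$read)
      }
    }
  }
  if (!is.null(promoted)) {
    dels <- list(promoted$del)
    inss <- list(list(pos = promoted$del[1], seq = promoted$ins))
    n_subst <- 0L
  } else {
    # canonicalize, then keep indels whose footprint touches the window
    dels <- purrr::map(ev$dels, function(d) {
      canonical_deletion(amplicon, d[1], d[2], cut)
    })
    dels <- purrr::keep(dels, function(d) d[1] < cut + w && d[2] > cut - w)
    inss <- purrr::map(ev$inss, function(i) {
      canonical_insertion(amplicon, i$pos, i$seq, cut)
    })
    inss <- purrr::keep(inss, function(i) i$pos >= cut - w && i$pos < cut + w)
    n_subst <- sum(win_sub)
  }
  if (length(dels) > 1 || length(inss) > 1) {
    return(discard_call("complex", score))
  }
  del_left <- 0L; del_right <- 0L; ins_seq <- ""
  if (length(dels) == 1) {
    d <- dels[[1]]
    del_left <- max(0L, min(d[2], cut) - d[1])
    del_right <- max(0L, d[2] - max(d[1], cut))
  }
  if (length(inss) == 1) ins_seq <- inss[[1]]$seq
  category <- if (del_left + del_right > 0 && nchar(ins_seq) > 0) "DELINS"
  else if (del_left + del_right > 0) "DEL"
  else if (nchar(ins_seq) > 0) "INS"
  else "WT"
  list(category = category, del_left = del_left, del_right = del_right,
       ins_seq = ins_seq,
       label = format_allele_label(del_left, del_right, ins_seq),
       reason = NA_character_, n_subst = as.integer(n_subst), score = score)
}

#' Call alleles for reads at a target site
#'
#' Convenience wrapper over [classify_edits()]: extracts the
#' protospacer-strand amplicon around the site's cut from the reference and
#' classifies the reads against it, attaching the gene identifier.
#'
#' @inheritParams classify_edits
#' @param site One-row target tibble (see [load_targets()]).
#' @param ref Reference accepted by [load_reference()].
#' @param amp_halfwidth Half-width of the amplicon extracted around the cut
#'   (default 110 bp).
#' @param window_halfwidth Defaults to the site's `window_halfwidth`.
#' @return Allele-call tibble as from [classify_edits()], with a `gene_id`
#'   column.
#' @export
call_alleles <- function(reads, site, ref, amp_halfwidth = 110L,
                         window_halfwidth = NULL, ...) {
  stopifnot(nrow(site) == 1)
  ref <- load_reference(ref)
  amp <- site_amplicon(ref, site, halfwidth = amp_halfwidth)
  w <- window_halfwidth %||% site$window_halfwidth
  out <- classify_edits(reads, amp$seq, amp$cut_offset,
                        window_halfwidth = w, ...)
  out$gene_id <- site$gene_id
  out[, c("read_id", "gene_id", setdiff(names(out), c("read_id", "gene_id")))]
}

#' Frame-shift reporter phenotype of a net length change
#'
#' In a frame-shift reporter whose open reading frame is restored by a
#' "3n + 1"-bp shift, an indel re-frames the downstream marker exactly when
#' the net length change is congruent to 1 modulo 3.
#'
#' @param net_len_change Signed integer vector of net inserted minus deleted
#'   bases.
#' @return Character vector: `"reporter_positive"` or `"reporter_negative"`.
#' @export
#' @examples
#' frameshift_phenotype(c(1, 3, -2))
frameshift_phenotype <- function(net_len_change) {
  ifelse(((net_len_change %% 3) + 3) %% 3 == 1,
         "reporter_positive", "reporter_negative")
}

#' Write alignments as a minimal SAM file
#'
#' Inspection aid: writes single-end records against one amplicon with
#' mapped/unmapped flags, 1-based positions, and CIGAR strings.
#'
#' @param alignments Tibble from [align_reads()].
#' @param amplicon Amplicon sequence the reads were aligned to.
#' @param amplicon_name Reference name to record.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, amplicon, amplicon_name, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", amplicon_name, nchar(amplicon)))
  recs <- sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*",
                  alignments$read_id, amplicon_name,
                  alignments$subj_start + 1L, alignments$cigar,
                  alignments$seq)
  writeLines(c(hdr, recs), path)
  invisible(path)
}
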