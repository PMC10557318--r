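# Cut-anchored allele notation.
#
# An editing outcome at a Cas9 cut is written "Del a|b" for a deletion
# removing `a` bases 5' (left) and `b` bases 3' (right) of the break on the
# protospacer strand, "Ins n SEQ" for an n-bp insertion at the break, and
# "Del a|b Ins n SEQ" for a combined outcome; unedited reads are "WT".

label_regex <- "^(?:WT|Del(\\d+)\\|(\\d+)(?: Ins(\\d+)([ACGTN]+))?|Ins(\\d+)([ACGTN]+))$"

#' Format a cut-anchored allele label
#'
#' Pure function from `(del_left, del_right, ins_seq)` to the canonical
#' allele label text. All arguments are recycled.
#'
#' @param del_left,del_right Non-negative integers: bases deleted 5' / 3' of
#'   the cut on the protospacer strand.
#' @param ins_seq Inserted sequence (empty string for none).
#' @return Character vector of labels (`"WT"`, `"Del2|0"`, `"Ins1A"`,
#'   `"Del8|0 Ins4CCCG"`, ...).
#' @export
#' @examples
#' format_allele_label(1, 0, "")
#' format_allele_label(8, 0, "CCCG")
format_allele_label <- function(del_left, del_right, ins_seq = "") {
  n <- max(length(del_left), length(del_right), length(ins_seq))
  del_left <- rep_len(as.integer(del_left), n)
  del_right <- rep_len(as.integer(del_right), n)
  ins_seq <- rep_len(toupper(ins_seq), n)
  stopifnot(all(del_left >= 0), all(del_right >= 0))
  has_del <- del_left + del_right > 0
  has_ins <- nchar(ins_seq) > 0
  out <- rep("WT", n)
  del_part <- sprintf("Del%d|%d", del_left, del_right)
  ins_part <- sprintf("Ins%d%s", nchar(ins_seq), ins_seq)
  out[has_del & !has_ins] <- del_part[has_del & !has_ins]
  out[!has_del & has_ins] <- ins_part[!has_del & has_ins]
  both <- has_del & has_ins
  out[both] <- paste(del_part[both], ins_part[both])
  out
}

#' Parse cut-anchored allele labels
#'
#' Inverse of [format_allele_label()]. Rejects labels outside the grammar
#' (including inconsistent insertion lengths such as `"Ins2A"`).
#'
#' @param label Character vector of labels.
#' @return Tibble with columns `label`, `category` (`WT`/`DEL`/`INS`/`DELINS`),
#'   `del_left`, `del_right`, `ins_seq`.
#' @export
parse_allele_label <- function(label) {
  ok <- grepl(label_regex, label, perl = TRUE)
  if (any(!ok)) {
    abort(sprintf("invalid allele label: '%s'", label[!ok][1]))
  }
  m <- regmatches(label, regexec(label_regex, label, perl = TRUE))
  parsed <- purrr::map(m, function(g) {
    del_left <- if (g[2] != "") as.integer(g[2]) else 0L
    del_right <- if (g[3] != "") as.integer(g[3]) else 0L
    ins_n <- if (g[4] != "") as.integer(g[4]) else if (g[6] != "") as.integer(g[6]) else 0L
    ins_seq <- if (g[5] != "") g[5] else if (g[7] != "") g[7] else ""
    if (nchar(ins_seq) != ins_n) {
      abort(sprintf("insertion length does not match sequence in label '%s'", g[1]))
    }
    list(del_left = del_left, del_right = del_right, ins_seq = ins_seq)
  })
  out <- tibble(
    label = label,
    del_left = purrr::map_int(parsed, "del_left"),
    del_right = purrr::map_int(parsed, "del_right"),
    ins_seq = purrr::map_chr(parsed, "ins_seq")
  )
  has_del <- out$del_left + out$del_right > 0
  has_ins <- nchar(out$ins_seq) > 0
  out$category <- dplyr::case_when(
    has_del & has_ins ~ "DELINS",
    has_del ~ "DEL",
    has_ins ~ "INS",
    TRUE ~ "WT"
  )
  out[, c("label", "category", "del_left", "del_right", "ins_seq")]
}

#' Apply an allele label to an amplicon sequence
#'
#' Edits `amplicon` at the 0-based inter-base cut offset `cut`: removes
#' `del_left` bases 5' and `del_right` bases 3' of the cut, then inserts
#' `ins_seq` at the breakpoint.
#'
#' @param amplicon DNA string in protospacer-strand orientation.
#' @param cut 0-based inter-base cut offset within `amplicon`.
#' @param label Allele label (see [parse_allele_label()]).
#' @return The edited sequence.
#' @export
#' @examples
#' apply_allele("AAACCCGGGTTT", 6, "Del1|0")
#' apply_allele("AAACCCGGGTTT", 6, "Ins1A")
apply_allele <- function(amplicon, cut, label) {
  p <- parse_allele_label(label)
  if (cut - p$del_left < 0 || cut + p$del_right > nchar(amplicon)) {
    abort(sprintf("allele '%s' extends past the amplicon (cut %d, length %d)",
                  label, cut, nchar(amplicon)))
  }
  paste0(subseq0(amplicon, 0L, cut - p$del_left),
         p$ins_seq,
         subseq0(amplicon, cut + p$del_right, nchar(amplicon)))
}

# ---- indel placement canonicalization -------------------------------------
#
# A deletion or insertion inside a repeat can be placed at several
# score-equivalent positions. The canonical placement is the one whose indel
# interval is closest to the cut; residual ties assign bases to the 5' (left)
# side, i.e. take the leftmost of the distance-tied placements. This anchors
# the "Del a|b" label deterministically at the break.

# distance from an inter-base/interval indel footprint to the cut
interval_cut_dist <- function(start, end, cut) {
  ifelse(cut < start, start - cut, ifelse(cut > end, cut - end, 0L))
}

# All placements of a deletion of [d0, d1) (0-based half-open, on `seq`)
# yielding the same edited sequence; returns canonical c(d0, d1).
canonical_deletion <- function(seq, d0, d1, cut) {
  L <- d1 - d0
  # shift left while the base before the gap equals the last base of the gap
  while (d0 > 0 && char_at(seq, d0 - 1L) == char_at(seq, d1 - 1L)) {
    d0 <- d0 - 1L; d1 <- d1 - 1L
  }
  starts <- d0
  while (d1 < nchar(seq) && char_at(seq, d0) == char_at(seq, d1)) {
    d0 <- d0 + 1L; d1 <- d1 + 1L
    starts <- c(starts, d0)
  }
  dists <- interval_cut_dist(starts, starts + L, cut)
  best <- starts[dists == min(dists)][1]  # leftmost among ties
  c(best, best + L)
}

# All placements of inserting `ins` at inter-base position p on `seq` that
# yield the same edited sequence; returns canonical list(pos, seq).
canonical_insertion <- function(seq, p, ins, cut) {
  L <- nchar(ins)
  # shift left: valid when the insert's last base equals the reference base
  # just 5' of the insertion point
  repeat {
    if (p == 0) break
    prev <- char_at(seq, p - 1L)
    if (substr(ins, L, L) != prev) break
    ins <- paste0(prev, substr(ins, 1L, L - 1L))
    p <- p - 1L
  }
  cand_p <- p
  cand_s <- ins
  p2 <- p; ins2 <- ins
  repeat {
    if (p2 >= nchar(seq)) break
    nxt <- char_at(seq, p2)
    if (substr(ins2, 1L, 1L) != nxt) break
    ins2 <- paste0(substr(ins2, 2L, L), nxt)
    p2 <- p2 + 1L
    cand_p <- c(cand_p, p2)
    cand_s <- c(cand_s, ins2)
  }
  dists <- abs(cand_p - cut)
  i <- which(dists == min(dists))[1]  # leftmost among ties
  list(pos = cand_p[i], seq = cand_s[i])
}
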