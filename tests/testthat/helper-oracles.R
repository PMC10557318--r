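# Independent oracles and shared fixtures. Everything here is brute force
# or plain string arithmetic, kept deliberately separate from the package's
# alignment/canonicalization code paths.

subs0 <- function(s, a, b) substr(s, a + 1, b)

# Brute-force canonical label for a pure deletion of a|b at `cut`:
# enumerate every placement of an equal-length deletion that yields the
# same mutant sequence, then apply the documented rule (closest to cut,
# ties to the 5' side).
oracle_del <- function(amp, cut, a, b) {
  L <- a + b
  mut <- paste0(subs0(amp, 0, cut - a), subs0(amp, cut + b, nchar(amp)))
  qs <- Filter(function(q) {
    paste0(subs0(amp, 0, q), subs0(amp, q + L, nchar(amp))) == mut
  }, 0:(nchar(amp) - L))
  d <- vapply(qs, function(q) {
    if (cut >= q && cut <= q + L) 0 else min(abs(cut - q), abs(cut - (q + L)))
  }, numeric(1))
  q <- qs[d == min(d)][1]
  aa <- max(0, min(q + L, cut) - q)
  bb <- max(0, q + L - max(q, cut))
  list(mut = mut, label = format_allele_label(aa, bb, ""),
       shiftable = length(qs) > 1)
}

# Brute-force canonical label for a pure insertion of `seq` at `cut`.
oracle_ins <- function(amp, cut, seq) {
  L <- nchar(seq)
  mut <- paste0(subs0(amp, 0, cut), seq, subs0(amp, cut, nchar(amp)))
  ps <- Filter(function(p) {
    paste0(subs0(amp, 0, p), substr(mut, p + 1, p + L),
           subs0(amp, p, nchar(amp))) == mut
  }, 0:nchar(amp))
  d <- abs(ps - cut)
  p <- ps[d == min(d)][1]
  list(mut = mut, label = format_allele_label(0, 0, substr(mut, p + 1, p + L)),
       shiftable = length(ps) > 1)
}

# Brute-force canonical junction placement. A shifted pair (s+j, e+j)
# describes the same junction when it reproduces the identical junction-read
# content: the fixed string (K bases inside each flank of the original
# placement) re-parsed with the junction point moved by j.
oracle_junction <- function(seq, s, e, K = 20) {
  ref_j <- paste0(subs0(seq, e - K, e), subs0(seq, s, s + K))
  cand <- (-min(s, K)):K
  valid <- cand[vapply(cand, function(j) {
    s + j >= 0 && e + j <= nchar(seq) &&
      paste0(subs0(seq, e - K, e + j), subs0(seq, s + j, s + K)) == ref_j
  }, logical(1))]
  runs <- split(valid, cumsum(c(1, diff(valid) != 1)))
  run <- runs[[which(vapply(runs, function(r) 0 %in% r, logical(1)))]]
  list(start = s + min(run), end = e + min(run),
       mh_len = max(run) - min(run))
}

# Canonical form of a cut-anchored allele label at a specific locus
# (protospacer-strand orientation), via the brute-force oracles.
canonical_label <- function(chrom, cut, label, strand = "+") {
  if (strand == "-") {
    chrom <- revcomp(chrom)
    cut <- nchar(chrom) - cut
  }
  p <- parse_allele_label(label)
  if (p$category == "DEL") {
    oracle_del(chrom, cut, p$del_left, p$del_right)$label
  } else if (p$category == "INS") {
    oracle_ins(chrom, cut, p$ins_seq)$label
  } else {
    label
  }
}

# Biostrings global-local alignment score, used as the independent
# dynamic-programming oracle for the compiled aligner.
oracle_score <- function(read, amp) {
  scoring <- list(match = 2, mismatch = -4, gap_open = 10, gap_ext = 1)
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- scoring$match
  m["N", ] <- scoring$mismatch; m[, "N"] <- scoring$mismatch
  Biostrings::score(Biostrings::pairwiseAlignment(
    read, amp, type = "global-local", substitutionMatrix = m,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext))
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Small shared mini-genome fixture (5 targets, mixed strands).
fixture_sim <- function(n_targets = 5, seed = 42) {
  simulate_reference(n_targets = n_targets, seed = seed)
}

# The printed tumor-nodule allele spectra used as worked examples:
# per-target allele labels with read counts scaled to 10,000 reads.
printed_spectra <- function() {
  list(
    p53 = tibble::tibble(
      label = c("WT", "Del1|0", "Del0|7", "Ins1A"),
      read_count = c(4188L, 2812L, 1613L, 1387L)
    ),
    Atm = tibble::tibble(
      label = c("WT", "Del6|0", "Ins1C"),
      read_count = c(5612L, 2381L, 2007L)
    ),
    Rb1 = tibble::tibble(
      label = "WT",
      read_count = 10000L
    )
  )
}

# Turn a label/read_count spectrum into synthetic per-read calls.
spectrum_calls <- function(spec) {
  labels <- rep(spec$label, spec$read_count)
  parsed <- parse_allele_label(labels)
  tibble::tibble(
    read_id = sprintf("r%05d", seq_along(labels)),
    category = parsed$category,
    del_left = parsed$del_left,
    del_right = parsed$del_right,
    ins_seq = parsed$ins_seq,
    label = labels,
    reason = NA_character_,
    n_subst = 0L,
    score = 300
  )
}
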