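# Split-read detection of eccDNA circularization junctions, microhomology
# canonicalization, circle annotation and size statistics, and
# junction-to-cut distances.
#
# A circularization junction is evidenced by reads whose 5' part maps at
# higher reference coordinates and whose 3' part continues at lower
# coordinates on the same chromosome and strand (suffix -> prefix). Only
# such simple circles are called; translocation-joined or inverted circles
# are out of scope.

#' Microhomology and canonical placement of a circularization junction
#'
#' When the two joined ends of a circle share a short identical sequence
#' (microhomology), the junction coordinate pair is ambiguous within the
#' shared length. This computes the longest exact shared k-mer immediately
#' inside the two boundaries and the canonical (leftmost) placement of the
#' `(start, end)` pair: the pair is shifted left while the bases just
#' before `start` and `end` agree, then the microhomology is read off to
#' the right.
#'
#' @param ref Reference accepted by [load_reference()].
#' @param start,end 0-based half-open junction coordinates (circle
#'   interval).
#' @param chrom Chromosome (may be omitted for a single-sequence
#'   reference).
#' @param max_mh Cap on reported/shifted microhomology length (default 20);
#'   degenerate repeats hitting the cap raise a warning.
#' @return List with `mh_len`, `mh_seq`, and canonical `start`, `end`.
#' @export
microhomology_at_junction <- function(ref, start, end, chrom = NULL,
                                      max_mh = 20L) {
  ref <- load_reference(ref)
  if (is.null(chrom)) {
    if (length(ref) != 1) abort("`chrom` required for a multi-sequence reference")
    chrom <- names(ref)[1]
  }
  seq <- ref_seq(ref, chrom)
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(start >= 0, end > start, end <= nchar(seq))
  shifts <- 0L
  while (start > 0 && char_at(seq, start - 1L) == char_at(seq, end - 1L)) {
    start <- start - 1L; end <- end - 1L
    shifts <- shifts + 1L
    if (shifts >= max_mh) {
      warn("junction shift capped at max_mh (degenerate repeat)")
      break
    }
  }
  k <- 0L
  while (k < max_mh && start + k < end && end + k < nchar(seq) &&
         char_at(seq, start + k) == char_at(seq, end + k)) {
    k <- k + 1L
  }
  if (k == max_mh) warn("microhomology length capped at max_mh")
  list(mh_len = k,
       mh_seq = if (k > 0) subseq0(seq, start, start + k) else "",
       start = start, end = end)
}

# Exact-match k-mer index of one sequence: hashed environment mapping each
# min_seg-mer to its 0-based start positions.
build_kmer_index <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list2env(list(), hash = TRUE))
  kmers <- substring(seq, seq_len(n - k + 1L), k:n)
  list2env(split(0:(n - k), kmers), hash = TRUE)
}

# all exact occurrences of `pat` (nchar >= k) in `seq`, via the k-mer index
exact_hits <- function(pat, seq, idx, k) {
  cand <- get0(substr(pat, 1L, k), envir = idx, ifnotfound = NULL)
  if (is.null(cand)) return(integer(0))
  L <- nchar(pat)
  cand <- cand[cand + L <= nchar(seq)]
  cand[substring(seq, cand + 1L, cand + L) == pat]
}

# Map one read against the reference: exact seed at the read 5' end,
# maximal exact extension, then exact placement of the remainder. Returns
# a list(status, chrom, start, end).
map_read_split <- function(read, ref, indexes, min_seg) {
  n <- nchar(read)
  if (n < 2L * min_seg) return(list(status = "too_short"))
  seed <- substr(read, 1L, min_seg)
  hit_chrom <- NULL; hit_pos <- NULL; n_hits <- 0L
  for (ch in names(indexes)) {
    p <- get0(seed, envir = indexes[[ch]], ifnotfound = NULL)
    n_hits <- n_hits + length(p)
    if (n_hits > 1L) return(list(status = "ambiguous"))
    if (length(p) == 1L) { hit_chrom <- ch; hit_pos <- p }
  }
  if (n_hits == 0L) return(list(status = "unmapped"))
  ch <- hit_chrom; pos <- hit_pos
  seq <- ref[[ch]]
  ref_seg <- subseq0(seq, pos, min(nchar(seq), pos + n))
  a <- charToRaw(read); b <- charToRaw(ref_seg)
  L <- length(b)
  mism <- which(a[seq_len(L)] != b)
  ext <- if (length(mism) == 0) L else mism[1] - 1L
  if (ext == n) {
    return(list(status = "collinear", chrom = ch, start = pos, end = pos + n))
  }
  if (ext < min_seg || n - ext < min_seg) return(list(status = "unsplit"))
  rem <- substr(read, ext + 1L, n)
  s2 <- exact_hits(rem, seq, indexes[[ch]], min_seg)
  if (length(s2) != 1) return(list(status = "unsplit"))
  e1 <- pos + ext
  if (s2 >= e1) return(list(status = "unsplit"))
  list(status = "junction", chrom = ch, start = s2, end = e1)
}

#' Detect eccDNA circularization junctions from reads
#'
#' Split-read junction caller for small (desk-scale) references: each read
#' is seeded by an exact match of its first `min_seg` bases, extended
#' maximally, and the remainder placed exactly; a read whose two parts map
#' suffix-then-prefix on the same chromosome defines a candidate junction.
#' Candidates are canonicalized under microhomology
#' ([microhomology_at_junction()]) and clustered exactly by coordinate
#' pair; clusters reaching `min_support` junction reads are emitted.
#' Reads are tried in both orientations; collinear, unmapped, and
#' ambiguous reads are counted but ignored.
#'
#' @param reads Reads as accepted by [align_reads()] (tibble, named
#'   character, `DNAStringSet`, or FASTQ path).
#' @param ref Reference accepted by [load_reference()].
#' @param min_seg Minimum exact segment length on each side of the
#'   junction, bp (default 20).
#' @param min_support Minimum junction-spanning reads per circle
#'   (default 2).
#' @return A `circle_set`: tibble with `circle_id`, `chrom`, `start`,
#'   `end`, `size`, `support`, `mh_len`, `mh_seq`; read-fate counts are
#'   kept in the `read_counts` attribute.
#' @export
detect_junctions <- function(reads, ref, min_seg = 20L, min_support = 2L) {
  ref <- load_reference(ref)
  tbl <- as_read_tbl(reads)
  indexes <- purrr::map(ref, build_kmer_index, k = min_seg)
  rc_seq <- revcomp(tbl$seq)
  status <- character(nrow(tbl))
  cand <- vector("list", nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    r <- map_read_split(tbl$seq[i], ref, indexes, min_seg)
    if (!r$status %in% c("junction", "collinear")) {
      r2 <- map_read_split(rc_seq[i], ref, indexes, min_seg)
      if (r2$status %in% c("junction", "collinear")) r <- r2
    }
    status[i] <- r$status
    if (r$status == "junction") {
      can <- microhomology_at_junction(ref, r$start, r$end, chrom = r$chrom)
      cand[[i]] <- tibble(chrom = r$chrom, start = can$start, end = can$end)
    }
  }
  counts <- table(factor(status, levels = c("junction", "collinear",
                                            "unmapped", "ambiguous",
                                            "unsplit", "too_short")))
  cand <- dplyr::bind_rows(cand)
  if (nrow(cand) == 0) {
    out <- tibble(circle_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), size = integer(0),
                  support = integer(0), mh_len = integer(0),
                  mh_seq = character(0))
    return(new_circle_set(out, counts))
  }
  clust <- cand |>
    count(.data$chrom, .data$start, .data$end, name = "support") |>
    filter(.data$support >= min_support) |>
    arrange(.data$chrom, .data$start, .data$end)
  if (nrow(clust) == 0) {
    out <- clust |>
      mutate(circle_id = character(0), size = integer(0),
             mh_len = integer(0), mh_seq = character(0))
    return(new_circle_set(out[, c("circle_id", "chrom", "start", "end",
                                  "size", "support", "mh_len", "mh_seq")],
                          counts))
  }
  mh <- purrr::pmap(list(clust$chrom, clust$start, clust$end),
                    function(ch, s, e) {
                      microhomology_at_junction(ref, s, e, chrom = ch)
                    })
  out <- clust |>
    mutate(size = .data$end - .data$start,
           mh_len = purrr::map_int(mh, "mh_len"),
           mh_seq = purrr::map_chr(mh, "mh_seq"),
           circle_id = sprintf("ecc_%s_%d_%d", .data$chrom, .data$start,
                               .data$end)) |>
    select("circle_id", "chrom", "start", "end", "size", "support",
           "mh_len", "mh_seq")
  new_circle_set(out, counts)
}

new_circle_set <- function(tbl, counts) {
  structure(tbl, class = c("circle_set", class(tbl)),
            read_counts = counts)
}

#' @export
print.circle_set <- function(x, ...) {
  cat(sprintf("<circle_set> %d circle(s)\n", nrow(x)))
  rc <- attr(x, "read_counts")
  if (!is.null(rc)) {
    cat("reads:", paste(sprintf("%s=%d", names(rc), as.integer(rc)),
                        collapse = " "), "\n")
  }
  print(as_tibble(x), ...)
  invisible(x)
}

#' @rdname tidy.circle_set
#' @method glance circle_set
#' @export
glance.circle_set <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(n_circles = 0L, min_size = NA_integer_,
                  max_size = NA_integer_, median_size = NA_integer_,
                  total_support = 0L))
  }
  tibble(n_circles = nrow(x), min_size = min(x$size), max_size = max(x$size),
         median_size = median_lower(x$size), total_support = sum(x$support))
}

#' Tidiers for circle sets
#'
#' `tidy()` returns the per-circle rows; `glance()` a one-row summary.
#'
#' @param x A `circle_set`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy circle_set
#' @export
tidy.circle_set <- function(x, ...) as_tibble(x)

#' Classify target-site alleles carried by detected circles
#'
#' For every target site whose cut lies inside a circle, reads anchored to
#' the site's flanks are classified against the wild-type amplicon
#' ([call_alleles()]) and the consensus (most frequent retained) label is
#' reported. Sites inside a circle but without classifiable coverage are
#' reported as `"uncalled"`.
#'
#' @param circles A `circle_set` (or compatible tibble).
#' @param reads Read set the circles were detected from.
#' @param targets Target tibble from [load_targets()].
#' @param ref Reference accepted by [load_reference()].
#' @param anchor_len Exact flank anchor used to pre-select reads, bp.
#' @param ... Passed to [call_alleles()].
#' @return Tibble with `circle_id`, `gene_id`, `label`, `support`
#'   (reads carrying the top label), `coverage` (classified reads), and
#'   `label_frequency` (percent of classified reads).
#' @export
assign_target_alleles <- function(circles, reads, targets, ref,
                                  anchor_len = 16L, ...) {
  ref <- load_reference(ref)
  tbl <- as_read_tbl(reads)
  purrr::map_dfr(seq_len(nrow(circles)), function(i) {
    ci <- circles[i, ]
    sites <- targets[targets$chrom == ci$chrom &
                       targets$cut_pos > ci$start &
                       targets$cut_pos < ci$end, ]
    if (nrow(sites) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(sites)), function(j) {
      site <- sites[j, ]
      chrom_seq <- ref_seq(ref, site$chrom)
      w <- site$window_halfwidth
      a5 <- subseq0(chrom_seq, site$cut_pos - w - anchor_len, site$cut_pos - w)
      a3 <- subseq0(chrom_seq, site$cut_pos + w, site$cut_pos + w + anchor_len)
      sel <- stringr::str_detect(tbl$seq, stringr::fixed(a5)) |
        stringr::str_detect(tbl$seq, stringr::fixed(a3)) |
        stringr::str_detect(tbl$seq, stringr::fixed(revcomp(a5))) |
        stringr::str_detect(tbl$seq, stringr::fixed(revcomp(a3)))
      base <- tibble(circle_id = ci$circle_id, gene_id = site$gene_id)
      if (!any(sel)) {
        return(mutate(base, label = "uncalled", support = 0L, coverage = 0L,
                      label_frequency = NA_real_))
      }
      calls <- call_alleles(tbl[sel, ], site, ref, ...)
      kept <- calls[!is.na(calls$category) & calls$category != "DISCARD", ]
      if (nrow(kept) == 0) {
        return(mutate(base, label = "uncalled", support = 0L, coverage = 0L,
                      label_frequency = NA_real_))
      }
      top <- kept |>
        count(label = .data$label, sort = TRUE, name = "support") |>
        dplyr::slice(1)
      mutate(base, label = top$label, support = top$support,
             coverage = nrow(kept),
             label_frequency = top$support / nrow(kept) * 100)
    })
  })
}

#' Distance from a circle's junction coordinates to a Cas9 cut
#'
#' Distances (bp) from the cut to the nearer (proximal) and farther
#' (distal) junction coordinate, with log10 values for distances of at
#' least 1 bp (log10 is undefined at distance 0 and reported NA).
#'
#' @param circles Circle tibble (`circle_id`, `chrom`, `start`, `end`).
#' @param site One-row target tibble.
#' @return Tibble `gene_id`, `circle_id`, `dist_proximal`, `dist_distal`,
#'   `log10_proximal`, `log10_distal`.
#' @export
junction_distance_to_cut <- function(circles, site) {
  stopifnot(nrow(site) == 1)
  if (any(circles$chrom != site$chrom)) {
    abort("circle and target site lie on different chromosomes")
  }
  d1 <- abs(site$cut_pos - circles$start)
  d2 <- abs(circles$end - site$cut_pos)
  prox <- pmin(d1, d2); dist <- pmax(d1, d2)
  tibble(gene_id = site$gene_id, circle_id = circles$circle_id,
         dist_proximal = prox, dist_distal = dist,
         log10_proximal = ifelse(prox >= 1, log10(prox), NA_real_),
         log10_distal = ifelse(dist >= 1, log10(dist), NA_real_))
}

#' Summary statistics of circle sizes
#'
#' Count, range, median (lower-middle for even counts), percentages below
#' 1 kb and 2 kb, and a size histogram (`bin_width` bp bins, stored in the
#' `histogram` attribute).
#'
#' @param circles Circle tibble with a `size` column (or numeric sizes).
#' @param bin_width Histogram bin width, bp.
#' @return One-row tibble `n`, `min_size`, `max_size`, `median_size`,
#'   `pct_lt_1kb`, `pct_lt_2kb`, with attribute `histogram`.
#' @export
circle_length_stats <- function(circles, bin_width = 250L) {
  sizes <- if (is.data.frame(circles)) circles$size else circles
  if (length(sizes) == 0) abort("no circles to summarise")
  brks <- seq(0L, (max(sizes) %/% bin_width + 1L) * bin_width, by = bin_width)
  h <- tibble(bin_start = head(brks, -1), bin_end = tail(brks, -1))
  h$count <- purrr::map2_int(h$bin_start, h$bin_end,
                             function(a, b) sum(sizes >= a & sizes < b))
  out <- tibble(n = length(sizes), min_size = min(sizes),
                max_size = max(sizes), median_size = median_lower(sizes),
                pct_lt_1kb = mean(sizes < 1000) * 100,
                pct_lt_2kb = mean(sizes < 2000) * 100)
  attr(out, "histogram") <- h
  out
}

annotation_priority <- c("promoter", "5'UTR", "exon", "3'UTR", "intron")

#' Annotate circles against genic features
#'
#' Assigns each circle one category. By default the circle midpoint
#' decides: the highest-priority feature (promoter > 5'UTR > exon > 3'UTR
#' > intron) containing the midpoint, or `"distal intergenic"` when none
#' does. With `method = "any_overlap"` the whole circle interval is
#' intersected instead.
#'
#' @param circles Circle tibble.
#' @param annotation Annotation tibble from [load_annotation()].
#' @param method `"midpoint"` (default) or `"any_overlap"`.
#' @return `circles` with an `annotation` column.
#' @export
annotate_circle <- function(circles, annotation,
                            method = c("midpoint", "any_overlap")) {
  method <- match.arg(method)
  cat_of <- function(chrom, s, e) {
    if (method == "midpoint") {
      mid <- (s + e) %/% 2L
      ov <- annotation[annotation$chrom == chrom & annotation$start <= mid &
                         annotation$end > mid, ]
    } else {
      ov <- annotation[annotation$chrom == chrom & annotation$start < e &
                         annotation$end > s, ]
    }
    if (nrow(ov) == 0) return("distal intergenic")
    annotation_priority[min(match(ov$type, annotation_priority))]
  }
  circles$annotation <- purrr::pmap_chr(
    list(circles$chrom, circles$start, circles$end), cat_of)
  circles
}

#' Classify a Sanger junction clone
#'
#' Classifies a Sanger-style sequence spanning both the circularization
#' junction and the target site of a circle: the target window is
#' classified against the wild-type locus (protospacer orientation) and
#' the junction against the canonical junction string, both with the
#' cut-anchored grammar.
#'
#' @param seq Sanger sequence (must span both landmarks).
#' @param circle One-row circle tibble (`chrom`, `start`, `end`).
#' @param site One-row target tibble whose cut lies inside the circle.
#' @param ref Reference accepted by [load_reference()].
#' @param window_halfwidth Classification window half-width, bp.
#' @return One-row tibble `target_label`, `junction_label`.
#' @export
classify_junction_clone <- function(seq, circle, site, ref,
                                    window_halfwidth = 20L) {
  ref <- load_reference(ref)
  stopifnot(nrow(circle) == 1, nrow(site) == 1)
  chrom_seq <- ref_seq(ref, circle$chrom)
  size <- circle$end - circle$start
  if (site$cut_pos <= circle$start || site$cut_pos >= circle$end) {
    abort("target cut does not lie inside the circle")
  }
  S <- subseq0(chrom_seq, circle$start, circle$end)
  c0 <- site$cut_pos - circle$start
  k <- (c0 + size %/% 2L) %% size
  rot <- substr(strrep(S, 2L), k + 1L, k + size)
  j_off <- (size - k) %% size
  t_off <- (c0 - k) %% size
  jn <- classify_edits(c(clone = toupper(seq)), rot, j_off,
                       window_halfwidth = window_halfwidth,
                       min_promote_ins = 1L)
  if (site$strand == "+") {
    tg <- classify_edits(c(clone = toupper(seq)), rot, t_off,
                         window_halfwidth = window_halfwidth,
                         min_promote_ins = 1L)
  } else {
    tg <- classify_edits(c(clone = toupper(seq)), revcomp(rot), size - t_off,
                         window_halfwidth = window_halfwidth,
                         min_promote_ins = 1L)
  }
  if (jn$category == "DISCARD" && tg$category == "DISCARD") {
    abort("sequence covers neither the junction nor the target window")
  }
  if (jn$category == "DISCARD") {
    abort(sprintf("sequence does not cover the junction window (%s)", jn$reason))
  }
  if (tg$category == "DISCARD") {
    abort(sprintf("sequence does not cover the target window (%s)", tg$reason))
  }
  tibble(target_label = tg$label, junction_label = jn$label)
}

#' Export circles as BED6+
#'
#' Columns: chrom, start, end, circle_id, support (score), strand (`+`),
#' then size, mh_len, and annotation when present.
#'
#' @param circles Circle tibble.
#' @param path Optional output TSV path.
#' @return The BED tibble (invisibly when written).
#' @export
circles_to_bed <- function(circles, path = NULL) {
  bed <- tibble(chrom = circles$chrom, start = circles$start,
                end = circles$end, name = circles$circle_id,
                score = circles$support, strand = "+",
                size = circles$size, mh_len = circles$mh_len)
  if ("annotation" %in% names(circles)) bed$annotation <- circles$annotation
  if (!is.null(path)) {
    readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
    return(invisible(bed))
  }
  bed
}
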