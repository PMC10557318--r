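# Synthetic-data generators with known ground truth: a mini-genome with
# embedded sgRNA target sites, amplicon read sets at specified allele
# frequencies, clonal lineages with discrete allele gain/loss, and
# rolling-circle-amplified eccDNA libraries with circularization junctions.
#
# All generators take an explicit `seed` and restore the caller's RNG state,
# so fixed seeds give byte-identical output.

#' Simulate a reference mini-genome with embedded target sites
#'
#' Generates a random mini-genome carrying `n_targets` sgRNA target sites
#' (random protospacers with an NGG PAM forced into the sequence, random
#' strand) spaced evenly along one chromosome, plus a simple genic
#' annotation (promoter, 5'UTR, exon, intron, 3'UTR intervals around each
#' target; everything else intergenic). By default 35 sites are created,
#' named like a tumor-suppressor panel with one control locus.
#'
#' @param n_targets Number of target sites (default 35).
#' @param spacing Distance between consecutive cut sites, bp (default 600).
#' @param margin Sequence margin at both chromosome ends, bp.
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return List with `ref` (named character), `target_table` (raw table for
#'   [load_targets()]), and `annotation` (tibble).
#' @export
simulate_reference <- function(n_targets = 35, spacing = 600L, margin = 500L,
                               chrom = "mini1", seed = 1L) {
  withr::local_seed(seed)
  len <- 2L * margin + n_targets * spacing
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  gene_ids <- if (n_targets >= 2) {
    c(sprintf("TSG%02d", seq_len(n_targets - 1)), "Setd5")
  } else {
    sprintf("TSG%02d", seq_len(n_targets))
  }
  strand <- sample(c("+", "-"), n_targets, replace = TRUE)
  cut_target <- margin + spacing * (seq_len(n_targets) - 1L) + spacing %/% 2L
  ps <- ifelse(strand == "+", cut_target - 17L, cut_target - 3L)
  # force the PAM (GG on the protospacer strand) into the genome
  for (i in seq_len(n_targets)) {
    if (strand[i] == "+") {
      chars[ps[i] + 21L + 1L] <- "G"; chars[ps[i] + 22L + 1L] <- "G"
    } else {
      chars[ps[i] - 3L + 1L] <- "C"; chars[ps[i] - 2L + 1L] <- "C"
    }
  }
  seq <- paste(chars, collapse = "")
  proto <- purrr::map2_chr(ps, strand, function(p, s) {
    raw <- subseq0(seq, p, p + 20L)
    if (s == "+") raw else revcomp(raw)
  })
  pam <- purrr::map2_chr(ps, strand, function(p, s) {
    if (s == "+") subseq0(seq, p + 20L, p + 23L) else revcomp(subseq0(seq, p - 3L, p))
  })
  target_table <- tibble(gene = gene_ids, chrom = chrom, strand = strand,
                         protospacer = proto, pam = pam,
                         protospacer_start = as.integer(ps))
  annotation <- purrr::map_dfr(seq_len(n_targets), function(i) {
    g <- cut_target[i]
    tibble(
      chrom = chrom,
      start = g + c(-250L, -150L, -100L, 40L, 120L),
      end = g + c(-150L, -100L, 40L, 120L, 170L),
      type = c("promoter", "5'UTR", "exon", "intron", "3'UTR")
    )
  })
  list(ref = setNames(seq, chrom), target_table = target_table,
       annotation = annotation)
}

check_allele_spec <- function(alleles) {
  stopifnot(all(c("label", "frequency") %in% names(alleles)))
  parse_allele_label(alleles$label)  # grammar check
  if (abs(sum(alleles$frequency) - 1) > 1e-9) {
    abort("allele frequencies must sum to 1")
  }
  if (any(alleles$frequency < 0)) abort("allele frequencies must be >= 0")
  invisible(alleles)
}

#' Simulate amplicon reads carrying specified alleles
#'
#' Draws `depth` reads multinomially from the allele frequencies, applies
#' each allele label to the protospacer-strand amplicon around the site's
#' cut, samples a read-length window that always covers the classification
#' window, and adds uniform substitution errors at per-base rate `err`.
#'
#' @param site One-row target tibble (see [load_targets()]).
#' @param ref Reference accepted by [load_reference()].
#' @param alleles Tibble with columns `label`, `frequency` (fractions
#'   summing to 1).
#' @param depth Number of reads (>= 1).
#' @param read_len Read length, bp.
#' @param err Per-base substitution error rate.
#' @param seed Integer seed (NULL leaves the RNG state alone).
#' @param amp_halfwidth Amplicon half-width around the cut, bp.
#' @return List with `reads` (tibble `read_id`, `seq`) and `truth`
#'   (tibble `read_id`, `gene_id`, `label`).
#' @export
simulate_amplicon_reads <- function(site, ref, alleles, depth,
                                    read_len = 150L, err = 0.003,
                                    seed = NULL, amp_halfwidth = 110L) {
  stopifnot(nrow(site) == 1, depth >= 1)
  check_allele_spec(alleles)
  if (!is.null(seed)) withr::local_seed(seed)
  ref <- load_reference(ref)
  amp <- site_amplicon(ref, site, halfwidth = amp_halfwidth)
  cut <- amp$cut_offset
  w <- site$window_halfwidth
  counts <- as.vector(rmultinom(1, depth, alleles$frequency))
  reads <- character(depth)
  labels <- character(depth)
  k <- 0L
  for (i in seq_len(nrow(alleles))) {
    if (counts[i] == 0) next
    lab <- alleles$label[i]
    p <- parse_allele_label(lab)
    mutated <- apply_allele(amp$seq, cut, lab)  # errors if past amplicon
    len_m <- nchar(mutated)
    shift <- nchar(p$ins_seq) - (p$del_left + p$del_right)
    if (len_m <= read_len) {
      starts <- rep(0L, counts[i])
      rl <- len_m
    } else {
      smax <- min(cut - w, len_m - read_len)
      smin <- max(0L, cut + w + shift - read_len)
      if (smin > smax) {
        abort(sprintf("read_len %d too short to cover the window for allele '%s'",
                      read_len, lab))
      }
      starts <- smin + floor(runif(counts[i]) * (smax - smin + 1L))
      rl <- read_len
    }
    for (j in seq_len(counts[i])) {
      k <- k + 1L
      reads[k] <- subseq0(mutated, starts[j], starts[j] + rl)
      labels[k] <- lab
    }
  }
  ord <- sample.int(depth)
  reads <- add_substitution_errors(reads[ord], err)
  labels <- labels[ord]
  ids <- sprintf("%s_r%06d", site$gene_id, seq_len(depth))
  list(
    reads = tibble(read_id = ids, seq = reads),
    truth = tibble(read_id = ids, gene_id = site$gene_id, label = labels)
  )
}

#' Simulate a clonal lineage with allele gain/loss and drift
#'
#' Derives `n_subclones` samples from a parent allele profile. Per subclone
#' and target, each allele present at or above `tau` is lost (frequency set
#' to 0) independently with probability `p_loss`; with probability `p_gain`
#' one new or dormant allele is raised to a frequency drawn uniformly from
#' `gain_freq`; Gaussian jitter with SD `drift_sd` (truncated at 0) is
#' added; frequencies are then renormalized to 1. Every gain/loss is
#' recorded in an event log.
#'
#' @param parent Tibble with columns `gene_id`, `label`, `frequency`
#'   (fractions summing to 1 per gene).
#' @param n_subclones Number of derived samples.
#' @param p_loss,p_gain Per-allele loss / per-gene gain probabilities.
#' @param gain_freq Range of the raw gained frequency (fraction).
#' @param drift_sd Per-sample frequency jitter SD (fraction scale).
#' @param tau Presence threshold in percent (default 5).
#' @param seed Integer seed.
#' @param subclone_ids Optional sample names (default `subclone_1`, ...).
#' @return List with `samples` (tibble `sample_id`, `gene_id`, `label`,
#'   `frequency`) including the parent as sample `"parent"`, and `events`
#'   (tibble `sample_id`, `gene_id`, `label`, `event`).
#' @export
simulate_lineage <- function(parent, n_subclones, p_loss = 0.1, p_gain = 0.05,
                             gain_freq = c(0.25, 0.4), drift_sd = 0,
                             tau = 5, seed = 1L, subclone_ids = NULL) {
  stopifnot(all(c("gene_id", "label", "frequency") %in% names(parent)))
  stopifnot(p_loss >= 0, p_loss <= 1, p_gain >= 0, p_gain <= 1, drift_sd >= 0)
  for (g in unique(parent$gene_id)) {
    check_allele_spec(parent[parent$gene_id == g, ])
  }
  withr::local_seed(seed)
  tau_frac <- tau / 100
  ids <- subclone_ids %||% sprintf("subclone_%d", seq_len(n_subclones))
  stopifnot(length(ids) == n_subclones)
  events <- list()
  samples <- list(dplyr::mutate(parent, sample_id = "parent"))
  for (s in ids) {
    per_gene <- purrr::map(unique(parent$gene_id), function(g) {
      p <- parent[parent$gene_id == g, c("label", "frequency")]
      freq <- setNames(p$frequency, p$label)
      present <- names(freq)[freq >= tau_frac]
      lost <- present[runif(length(present)) < p_loss]
      freq[lost] <- 0
      if (sum(freq) <= 0) {
        abort(sprintf("all alleles lost at target %s in sample %s", g, s))
      }
      gained <- character(0)
      if (runif(1) < p_gain) {
        # an allele lost this generation cannot also be regained: the pair
        # of events would cancel and be unobservable in the profile
        dormant <- setdiff(names(freq)[freq < tau_frac], lost)
        new_lab <- if (length(dormant) > 0 && runif(1) < 0.5) {
          sample(dormant, 1)
        } else {
          random_indel_label(exclude = names(freq))
        }
        g_freq <- runif(1, gain_freq[1], gain_freq[2])
        freq[new_lab] <- g_freq
        gained <- new_lab
      }
      if (drift_sd > 0) {
        # keep allele names: pmax takes attributes from its first argument
        freq <- pmax(freq + rnorm(length(freq), 0, drift_sd), 0)
      }
      freq <- freq / sum(freq)
      ev <- dplyr::bind_rows(
        if (length(lost)) tibble(gene_id = g, label = lost, event = "loss"),
        if (length(gained)) tibble(gene_id = g, label = gained, event = "gain")
      )
      list(freq = tibble(gene_id = g, label = names(freq),
                         frequency = unname(freq)),
           events = ev)
    })
    samples[[length(samples) + 1L]] <-
      dplyr::mutate(purrr::map_dfr(per_gene, "freq"), sample_id = s)
    ev <- purrr::map_dfr(per_gene, "events")
    if (nrow(ev) > 0) {
      events[[length(events) + 1L]] <- dplyr::mutate(ev, sample_id = s)
    }
  }
  samples <- dplyr::bind_rows(samples)[, c("sample_id", "gene_id", "label",
                                           "frequency")]
  events <- if (length(events) > 0) {
    dplyr::bind_rows(events)[, c("sample_id", "gene_id", "label", "event")]
  } else {
    tibble(sample_id = character(0), gene_id = character(0),
           label = character(0), event = character(0))
  }
  list(samples = samples, events = events)
}

random_indel_label <- function(exclude = character(0), max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    lab <- if (runif(1) < 0.5) {
      a <- sample(0:8, 1); b <- sample(0:8, 1)
      if (a + b == 0) a <- 1L
      format_allele_label(a, b, "")
    } else {
      n <- sample(1:3, 1)
      format_allele_label(0, 0, random_dna(n))
    }
    if (!lab %in% exclude) return(lab)
  }
  abort("could not draw a novel allele label")
}

# Transform a protospacer-strand allele label into a plus-strand edit.
apply_allele_genomic <- function(seq, cut, label, strand = "+") {
  if (strand == "+") return(apply_allele(seq, cut, label))
  p <- parse_allele_label(label)
  ins <- if (nchar(p$ins_seq) > 0) revcomp(p$ins_seq) else ""
  apply_allele(seq, cut, format_allele_label(p$del_right, p$del_left, ins))
}

#' Simulate a rolling-circle-amplified eccDNA sequencing library
#'
#' Each circle is concatemerized (at least 3 tandem copies, more for
#' circles shorter than the fragment), fragmented uniformly, and sequenced
#' as read pairs; a known fraction of reads span the circularization
#' junction. When `mh_len > 0` the reference is locally edited so that the
#' two junction flanks share an exact `mh_len`-mer (microhomology-mediated
#' joining); when a target site lies inside a circle and
#' `allele_at_target` is set, the circle sequence carries that allele while
#' the reference stays wild type.
#'
#' @param circles Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open, size 150-10000 bp), `copy_number`, `mh_len`, and optionally
#'   `allele_at_target`.
#' @param ref Reference accepted by [load_reference()].
#' @param targets Target tibble (needed when `allele_at_target` is used).
#' @param frag_len Fragment length, bp (must be >= `read_len`).
#' @param read_len Read length, bp.
#' @param depth_per_copy Per-copy fold fragment coverage; the number of
#'   fragments per circle is `depth_per_copy * copy_number * size/frag_len`.
#' @param err Per-base substitution error rate.
#' @param seed Integer seed.
#' @return List with `reads` (tibble, both mates as rows), `truth` (tibble
#'   `read_id`, `circle_id`, `mate`, `junction_spanning`, `multi_junction`),
#'   `circles` (input augmented with `circle_id`, `size`, and canonical
#'   junction coordinates), and `ref` (the possibly microhomology-edited
#'   reference the reads were drawn from).
#' @export
simulate_eccdna_library <- function(circles, ref, targets = NULL,
                                    frag_len = 300L, read_len = 120L,
                                    depth_per_copy = 10, err = 0,
                                    seed = 1L) {
  if (frag_len < read_len) abort("frag_len must be >= read_len")
  ref <- load_reference(ref)
  withr::local_seed(seed)
  if (nrow(circles) == 0) {
    return(list(reads = tibble(read_id = character(0), seq = character(0)),
                truth = tibble(read_id = character(0), circle_id = character(0),
                               mate = integer(0), junction_spanning = logical(0),
                               multi_junction = logical(0)),
                circles = circles, ref = ref))
  }
  circles <- as_tibble(circles)
  circles$size <- circles$end - circles$start
  if (any(circles$size < 150 | circles$size > 10000)) {
    abort("circle sizes must lie in [150, 10000] bp")
  }
  if (!"copy_number" %in% names(circles)) circles$copy_number <- 1L
  if (!"mh_len" %in% names(circles)) circles$mh_len <- 0L
  if (!"allele_at_target" %in% names(circles)) {
    circles$allele_at_target <- NA_character_
  }
  circles$circle_id <- sprintf("circle_%03d", seq_len(nrow(circles)))
  # edit the reference so junction flanks share the requested microhomology
  for (i in seq_len(nrow(circles))) {
    m <- circles$mh_len[i]
    if (m > 0) {
      ch <- circles$chrom[i]
      s0 <- circles$start[i]; e0 <- circles$end[i]
      chrom_seq <- ref_seq(ref, ch)
      if (e0 + m > nchar(chrom_seq)) abort("microhomology extends past reference")
      mh_seq <- subseq0(chrom_seq, s0, s0 + m)
      ref[[ch]] <- paste0(subseq0(chrom_seq, 0L, e0), mh_seq,
                          subseq0(chrom_seq, e0 + m, nchar(chrom_seq)))
    }
  }
  all_reads <- list(); all_truth <- list()
  can <- purrr::map(seq_len(nrow(circles)), function(i) {
    microhomology_at_junction(ref, circles$start[i], circles$end[i],
                              chrom = circles$chrom[i])
  })
  circles$canonical_start <- purrr::map_int(can, "start")
  circles$canonical_end <- purrr::map_int(can, "end")
  for (i in seq_len(nrow(circles))) {
    ci <- circles[i, ]
    chrom_seq <- ref_seq(ref, ci$chrom)
    if (ci$start < 0 || ci$end > nchar(chrom_seq)) {
      abort(sprintf("circle %s outside reference bounds", ci$circle_id))
    }
    S <- subseq0(chrom_seq, ci$start, ci$end)
    if (!is.na(ci$allele_at_target)) {
      if (is.null(targets)) abort("allele_at_target given but no targets supplied")
      hit <- targets[targets$chrom == ci$chrom &
                       targets$cut_pos > ci$start & targets$cut_pos < ci$end, ]
      if (nrow(hit) == 0) {
        abort(sprintf("circle %s has allele_at_target but contains no cut site",
                      ci$circle_id))
      }
      S <- apply_allele_genomic(S, hit$cut_pos[1] - ci$start,
                                ci$allele_at_target, hit$strand[1])
    }
    size_m <- nchar(S)
    n_copies <- max(3L, as.integer(ceiling((frag_len + read_len) / size_m)) + 1L)
    concat <- strrep(S, n_copies)
    n_frags <- max(1L, as.integer(round(depth_per_copy * ci$copy_number *
                                          size_m / frag_len)))
    fs <- floor(runif(n_frags) * (nchar(concat) - frag_len + 1L))
    boundaries <- size_m * seq_len(n_copies - 1L)
    r1_start <- fs; r2_start <- fs + frag_len - read_len
    spans <- function(rs, len) {
      vapply(rs, function(x) sum(boundaries > x & boundaries < x + len),
             integer(1))
    }
    n1 <- spans(r1_start, read_len); n2 <- spans(r2_start, read_len)
    n_frag <- spans(fs, frag_len)  # fragment-level junction wraps
    r1 <- substring(concat, r1_start + 1L, r1_start + read_len)
    r2 <- revcomp(substring(concat, r2_start + 1L, r2_start + read_len))
    ids1 <- sprintf("%s_f%05d/1", ci$circle_id, seq_len(n_frags))
    ids2 <- sprintf("%s_f%05d/2", ci$circle_id, seq_len(n_frags))
    all_reads[[i]] <- tibble(read_id = c(ids1, ids2), seq = c(r1, r2))
    all_truth[[i]] <- tibble(
      read_id = c(ids1, ids2),
      circle_id = ci$circle_id,
      mate = rep(c(1L, 2L), each = n_frags),
      junction_spanning = c(n1 > 0, n2 > 0),
      multi_junction = rep(n_frag > 1, 2)
    )
  }
  reads <- dplyr::bind_rows(all_reads)
  reads$seq <- add_substitution_errors(reads$seq, err)
  list(reads = reads, truth = dplyr::bind_rows(all_truth),
       circles = circles, ref = ref)
}

#' Simulate junction-free linear reads from a reference
#'
#' Control material for the junction caller: reads sampled collinearly from
#' the reference (random positions and strands), never spanning any
#' circularization junction.
#'
#' @inheritParams simulate_eccdna_library
#' @param n Number of reads.
#' @return Tibble with `read_id`, `seq`.
#' @export
simulate_linear_reads <- function(ref, n, read_len = 120L, err = 0,
                                  seed = 1L) {
  ref <- load_reference(ref)
  withr::local_seed(seed)
  lens <- nchar(ref)
  chroms <- sample(names(ref), n, replace = TRUE, prob = lens / sum(lens))
  starts <- floor(runif(n) * (lens[chroms] - read_len + 1L))
  seqs <- substring(ref[chroms], starts + 1L, starts + read_len)
  rc <- runif(n) < 0.5
  seqs[rc] <- revcomp(seqs[rc])
  tibble(read_id = sprintf("lin_%06d", seq_len(n)),
         seq = add_substitution_errors(unname(seqs), err))
}
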