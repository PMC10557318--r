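test_that("error-free amplicon reads round-trip exactly through classification", {
  sim <- fixture_sim()
  targets <- load_targets(sim$target_table, sim$ref)
  site <- targets[targets$strand == "+", ][1, ]
  alleles <- tibble::tibble(label = c("WT", "Del1|0"), frequency = c(0.5, 0.5))
  s <- simulate_amplicon_reads(site, sim$ref, alleles, depth = 1000,
                               err = 0, seed = 5)
  expect_equal(nrow(s$reads), 1000)
  expect_equal(nrow(s$truth), 1000)
  calls <- call_alleles(s$reads, site, sim$ref)
  # compare against the cut-anchored canonical form of each drawn allele
  chrom <- load_reference(sim$ref)[[site$chrom]]
  truth_canon <- vapply(s$truth$label, function(l) {
    canonical_label(chrom, site$cut_pos, l, site$strand)
  }, character(1))
  merged <- dplyr::inner_join(
    calls, dplyr::mutate(s$truth, label = truth_canon),
    by = "read_id", suffix = c("_called", "_true"))
  expect_true(all(merged$label_called == merged$label_true))
  expect_identical(sort(as.vector(table(calls$label))),
                   sort(as.vector(table(truth_canon))))
})

test_that("degenerate allele specifications behave as specified", {
  sim <- fixture_sim()
  targets <- load_targets(sim$target_table, sim$ref)
  site <- targets[targets$strand == "+", ][1, ]
  s <- simulate_amplicon_reads(site, sim$ref,
                               tibble::tibble(label = "WT", frequency = 1),
                               depth = 200, err = 0, seed = 1)
  calls <- call_alleles(s$reads, site, sim$ref)
  expect_true(all(calls$label == "WT"))

  expect_error(simulate_amplicon_reads(
    site, sim$ref, tibble::tibble(label = "WT", frequency = 0.9),
    depth = 10, seed = 1), "sum to 1")
  expect_error(simulate_amplicon_reads(
    site, sim$ref, tibble::tibble(label = "Del200|0", frequency = 1),
    depth = 10, seed = 1), "past the amplicon")
})

test_that("fixed seeds give byte-identical FASTQ output", {
  sim <- fixture_sim()
  targets <- load_targets(sim$target_table, sim$ref)
  site <- targets[1, ]
  alleles <- tibble::tibble(label = c("WT", "Ins1A"), frequency = c(0.7, 0.3))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  s1 <- simulate_amplicon_reads(site, sim$ref, alleles, depth = 500,
                                err = 0.01, seed = 99)
  s2 <- simulate_amplicon_reads(site, sim$ref, alleles, depth = 500,
                                err = 0.01, seed = 99)
  write_fastq(s1$reads, f1)
  write_fastq(s2$reads, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and FASTQ IO round-trips the sequences
  back <- read_fastq(f1)
  expect_identical(back$seq, s1$reads$seq)
})

test_that("lineage simulation is the identity when all event rates are zero", {
  parent <- tibble::tibble(
    gene_id = rep(c("g1", "g2"), each = 2),
    label = rep(c("WT", "Del1|0"), 2),
    frequency = rep(c(0.6, 0.4), 2)
  )
  lin <- simulate_lineage(parent, n_subclones = 3, p_loss = 0, p_gain = 0,
                          drift_sd = 0, seed = 1)
  for (s in unique(lin$samples$sample_id)) {
    sub <- lin$samples[lin$samples$sample_id == s, c("gene_id", "label",
                                                     "frequency")]
    expect_equal(sub$frequency, parent$frequency, tolerance = 1e-12)
  }
  expect_equal(nrow(lin$events), 0)
})

test_that("loss events follow the binomial oracle and losses zero alleles out", {
  parent <- purrr::map_dfr(sprintf("g%02d", 1:30), function(g) {
    tibble::tibble(gene_id = g, label = c("WT", "Del1|0", "Ins1A"),
                   frequency = c(0.4, 0.35, 0.25))
  })
  lin <- simulate_lineage(parent, n_subclones = 8, p_loss = 0.1, p_gain = 0,
                          drift_sd = 0, seed = 12)
  n_loss <- sum(lin$events$event == "loss")
  # Binomial(30 genes x 3 alleles x 8 subclones, 0.1)
  n_trials <- 30 * 3 * 8
  expect_lt(abs(n_loss - n_trials * 0.1), 3 * sqrt(n_trials * 0.1 * 0.9))
  # every lost allele has frequency 0 in that sample
  for (i in seq_len(nrow(lin$events))) {
    ev <- lin$events[i, ]
    f <- lin$samples$frequency[lin$samples$sample_id == ev$sample_id &
                                 lin$samples$gene_id == ev$gene_id &
                                 lin$samples$label == ev$label]
    expect_equal(f, 0)
  }
})

test_that("losing every allele at a target is an error", {
  parent <- tibble::tibble(gene_id = "g1", label = c("WT", "Del1|0"),
                           frequency = c(0.5, 0.5))
  expect_error(simulate_lineage(parent, n_subclones = 1, p_loss = 1,
                                p_gain = 0, seed = 1), "all alleles lost")
})

test_that("junction-spanning eccDNA reads contain the exact junction string", {
  sim <- fixture_sim()
  ref <- load_reference(sim$ref)
  circ <- tibble::tibble(chrom = names(ref)[1], start = 1000L, end = 1400L,
                         copy_number = 1L, mh_len = 0L)
  ecc <- simulate_eccdna_library(circ, ref, frag_len = 300, read_len = 120,
                                 depth_per_copy = 20, err = 0, seed = 4)
  chrom <- ref[[1]]
  junction_kmer <- paste0(substr(chrom, 1400 - 20 + 1, 1400),
                          substr(chrom, 1001, 1020))
  jr <- ecc$truth$read_id[ecc$truth$junction_spanning]
  expect_gt(length(jr), 4)
  seqs <- ecc$reads$seq[match(jr, ecc$reads$read_id)]
  # a junction read (in one orientation) contains junction-adjacent sequence;
  # those with >= 20 bases on each side carry the exact junction 40-mer
  hit <- grepl(junction_kmer, seqs, fixed = TRUE) |
    grepl(revcomp(junction_kmer), seqs, fixed = TRUE)
  expect_gt(sum(hit), 0)
  # non-junction reads never contain it
  other <- ecc$reads$seq[!ecc$reads$read_id %in% jr]
  expect_false(any(grepl(junction_kmer, other, fixed = TRUE) |
                     grepl(revcomp(junction_kmer), other, fixed = TRUE)))
})

test_that("eccDNA library edge cases: empty list, bad fragment length, wraps", {
  sim <- fixture_sim()
  ref <- load_reference(sim$ref)
  empty <- simulate_eccdna_library(tibble::tibble(chrom = character(0),
                                                  start = integer(0),
                                                  end = integer(0)),
                                   ref, seed = 1)
  expect_equal(nrow(empty$reads), 0)

  circ <- tibble::tibble(chrom = names(ref)[1], start = 500L, end = 700L)
  expect_error(simulate_eccdna_library(circ, ref, frag_len = 80,
                                       read_len = 120, seed = 1),
               "frag_len")

  # a circle smaller than the fragment wraps the junction more than once
  small <- tibble::tibble(chrom = names(ref)[1], start = 2000L, end = 2160L)
  ecc <- simulate_eccdna_library(small, ref, frag_len = 300, read_len = 150,
                                 depth_per_copy = 30, err = 0, seed = 2)
  expect_gt(sum(ecc$truth$multi_junction), 0)

  bad_size <- tibble::tibble(chrom = names(ref)[1], start = 0L, end = 100L)
  expect_error(simulate_eccdna_library(bad_size, ref, seed = 1), "150")
})

test_that("planted microhomology is recovered at the canonical junction", {
  sim <- fixture_sim(seed = 31)
  ref <- load_reference(sim$ref)
  circ <- tibble::tibble(chrom = names(ref)[1], start = 1200L, end = 1800L,
                         copy_number = 1L, mh_len = 4L)
  ecc <- simulate_eccdna_library(circ, ref, seed = 3)
  edited <- ecc$ref[[1]]
  # the two junction flanks share the requested 4-mer
  expect_identical(substr(edited, 1201, 1204), substr(edited, 1801, 1804))
  mh <- microhomology_at_junction(ecc$ref, 1200, 1800, chrom = names(ref)[1])
  expect_gte(mh$mh_len, 4)
  expect_equal(ecc$circles$canonical_start, mh$start)
  expect_equal(ecc$circles$canonical_end, mh$end)
})

test_that("linear read simulation is collinear and deterministic", {
  sim <- fixture_sim()
  r1 <- simulate_linear_reads(sim$ref, 100, read_len = 100, err = 0, seed = 8)
  r2 <- simulate_linear_reads(sim$ref, 100, read_len = 100, err = 0, seed = 8)
  expect_identical(r1, r2)
  chrom <- load_reference(sim$ref)[[1]]
  hit <- vapply(r1$seq, function(s) {
    grepl(s, chrom, fixed = TRUE) || grepl(revcomp(s), chrom, fixed = TRUE)
  }, logical(1))
  expect_true(all(hit))
})
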