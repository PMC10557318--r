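test_that("microhomology canonicalization matches a brute-force shift oracle", {
  set.seed(71)
  for (i in 1:15) {
    chrom <- random_seq(3000)
    s <- sample(500:1200, 1)
    e <- s + sample(300:1200, 1)
    mh <- sample(0:5, 1)
    if (mh > 0) {
      # plant a shared mh-mer just inside both boundaries
      substr(chrom, e + 1, e + mh) <- substr(chrom, s + 1, s + mh)
    }
    got <- microhomology_at_junction(c(chr = chrom), s, e)
    ora <- oracle_junction(chrom, s, e)
    expect_equal(got$start, ora$start)
    expect_equal(got$end, ora$end)
    expect_equal(got$mh_len, ora$mh_len)
    expect_gte(got$mh_len, mh)
    expect_identical(got$mh_seq,
                     substr(chrom, got$start + 1, got$start + got$mh_len))
  }
})

test_that("junction flanks with no shared base give zero microhomology", {
  set.seed(75)
  chrom <- random_seq(400)
  # block the left shift and the shared k-mer explicitly (1-based substr):
  # bases before start/end differ, and bases at start/end differ
  substr(chrom, 100, 101) <- "AG"
  substr(chrom, 200, 201) <- "CT"
  mh <- microhomology_at_junction(c(chr = chrom), 100, 200)
  expect_equal(mh$mh_len, 0)
  expect_identical(mh$mh_seq, "")
  expect_equal(mh$start, 100)
  expect_equal(mh$end, 200)
})

test_that("degenerate homopolymer junctions are capped with a warning", {
  chrom <- strrep("A", 400)
  w <- testthat::capture_warnings(
    mh <- microhomology_at_junction(c(chr = chrom), 100, 300, max_mh = 10)
  )
  expect_true(any(grepl("capped", w)))
  expect_lte(mh$mh_len, 10)
})

test_that("constructed junction reads yield one exact circle record", {
  set.seed(72)
  chrom <- random_seq(4000)
  s <- 1000L; e <- 1600L
  jread <- function(left, right) {
    paste0(substr(chrom, e - left + 1, e), substr(chrom, s + 1, s + right))
  }
  reads <- c(j1 = jread(60, 60), j2 = jread(40, 80), j3 = jread(75, 45),
             lin1 = substr(chrom, 201, 320), lin2 = substr(chrom, 2001, 2120))
  det <- detect_junctions(reads, c(chr = chrom))
  expect_equal(nrow(det), 1)
  can <- oracle_junction(chrom, s, e)
  expect_equal(det$start, can$start)
  expect_equal(det$end, can$end)
  expect_equal(det$size, 600L)
  expect_equal(det$support, 3L)
  expect_equal(det$size, det$end - det$start)

  # collinear-only input yields nothing
  none <- detect_junctions(reads[c("lin1", "lin2")], c(chr = chrom))
  expect_equal(nrow(none), 0)
})

test_that("circles sharing a start but differing in end stay separate", {
  set.seed(73)
  chrom <- random_seq(5000)
  s <- 1500L
  jread <- function(e) {
    paste0(substr(chrom, e - 60 + 1, e), substr(chrom, s + 1, s + 60))
  }
  reads <- c(a1 = jread(2200L), a2 = jread(2200L),
             b1 = jread(3100L), b2 = jread(3100L))
  det <- detect_junctions(reads, c(chr = chrom))
  expect_equal(nrow(det), 2)
  expect_equal(sort(det$end - det$start), c(700L, 1600L))
})

test_that("detection recovers simulated circles and assigns their alleles", {
  sim <- fixture_sim(n_targets = 6, seed = 17)
  targets <- load_targets(sim$target_table, sim$ref)
  site <- targets[targets$strand == "+", ][1, ]
  circ <- tibble::tibble(chrom = site$chrom,
                         start = site$cut_pos - 250L,
                         end = site$cut_pos + 350L,
                         copy_number = 2L, mh_len = 2L,
                         allele_at_target = "Del0|7")
  ecc <- simulate_eccdna_library(circ, sim$ref, targets = targets,
                                 depth_per_copy = 25, err = 0, seed = 9)
  det <- detect_junctions(ecc$reads, ecc$ref)
  expect_equal(nrow(det), 1)
  expect_equal(det$start, ecc$circles$canonical_start)
  expect_equal(det$end, ecc$circles$canonical_end)
  expect_gte(det$support, 2)

  hits <- assign_target_alleles(det, ecc$reads, targets, ecc$ref)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$gene_id, site$gene_id)
  chrom_seq <- load_reference(sim$ref)[[site$chrom]]
  expected <- oracle_del(chrom_seq, site$cut_pos, 0, 7)$label
  expect_identical(hits$label, expected)
  expect_gte(hits$coverage, 20)
})

test_that("junction distances to the cut follow interval arithmetic", {
  circles <- tibble::tibble(circle_id = c("c1", "c2", "c3"),
                            chrom = "chr",
                            start = c(1000L, 1000L, 1000L),
                            end = c(1400L, 1400L, 1400L))
  site <- tibble::tibble(gene_id = "g", chrom = "chr", cut_pos = 1200L)
  d <- junction_distance_to_cut(circles[1, ], site)
  expect_equal(d$dist_proximal, 200)
  expect_equal(d$dist_distal, 200)
  expect_equal(d$log10_distal, log10(200), tolerance = 1e-6)
  expect_equal(round(d$log10_distal, 3), 2.301)

  at_junction <- junction_distance_to_cut(
    circles[1, ], dplyr::mutate(site, cut_pos = 1000L))
  expect_equal(at_junction$dist_proximal, 0)
  expect_true(is.na(at_junction$log10_proximal))

  off <- junction_distance_to_cut(circles[1, ],
                                  dplyr::mutate(site, cut_pos = 1100L))
  expect_equal(off$dist_proximal, 100)
  expect_equal(off$dist_distal, 300)
  # cut inside the circle: proximal + distal equals the circle size
  expect_equal(off$dist_proximal + off$dist_distal, 400)
  expect_true(all(d$dist_proximal <= d$dist_distal))

  expect_error(junction_distance_to_cut(
    circles[1, ], dplyr::mutate(site, chrom = "other")), "chromosome")
})

test_that("circle length statistics use the lower-middle median", {
  s <- circle_length_stats(tibble::tibble(size = c(200, 300, 400, 5000)))
  expect_equal(s$median_size, 300)
  expect_equal(s$pct_lt_1kb, 75)
  expect_equal(s$pct_lt_2kb, 75)
  expect_equal(circle_length_stats(tibble::tibble(size = 344))$median_size, 344)
  all_small <- circle_length_stats(tibble::tibble(size = c(150, 500, 999)))
  expect_equal(all_small$pct_lt_1kb, 100)
  expect_error(circle_length_stats(tibble::tibble(size = numeric(0))),
               "no circles")
  h <- attr(s, "histogram")
  expect_equal(sum(h$count), 4)
})

test_that("circle annotation follows midpoint category priority", {
  ann <- tibble::tibble(
    chrom = "chr",
    start = c(1000L, 1000L, 5000L),
    end = c(1200L, 1200L, 5400L),
    type = c("intron", "promoter", "exon")
  )
  circles <- tibble::tibble(chrom = "chr",
                            start = c(1050L, 5100L, 8000L),
                            end = c(1150L, 5300L, 8200L))
  out <- annotate_circle(circles, ann)
  expect_identical(out$annotation,
                   c("promoter", "exon", "distal intergenic"))
  # any-overlap mode picks up features the midpoint misses
  wide <- tibble::tibble(chrom = "chr", start = 900L, end = 1010L)
  expect_identical(annotate_circle(wide, ann)$annotation, "distal intergenic")
  expect_identical(annotate_circle(wide, ann, method = "any_overlap")$annotation,
                   "promoter")
})

test_that("Sanger junction clones classify target and junction jointly", {
  set.seed(74)
  sim <- fixture_sim(n_targets = 6, seed = 17)
  targets <- load_targets(sim$target_table, sim$ref)
  site <- targets[targets$strand == "+", ][1, ]
  ref <- load_reference(sim$ref)
  chrom <- ref[[site$chrom]]
  s <- site$cut_pos - 250L; e <- site$cut_pos + 350L
  circle <- tibble::tibble(chrom = site$chrom, start = s, end = e)

  # clone 1: WT target, 1-G insertion at the junction
  wt_clone <- paste0(substr(chrom, e - 50 + 1, e), "G",
                     substr(chrom, s + 1, s + 300))
  r1 <- classify_junction_clone(wt_clone, circle, site, ref)
  expect_identical(r1$target_label, "WT")
  expect_identical(r1$junction_label, "Ins1G")

  # clone 2: deletion at the target, exact junction
  delseq <- apply_allele(chrom, site$cut_pos, "Del0|7")
  del_clone <- paste0(substr(chrom, e - 50 + 1, e),
                      substr(delseq, s + 1, s + 300 - 7))
  r2 <- classify_junction_clone(del_clone, circle, site, ref)
  expect_identical(r2$target_label,
                   oracle_del(chrom, site$cut_pos, 0, 7)$label)
  expect_identical(r2$junction_label, "WT")

  expect_error(classify_junction_clone(random_seq(300), circle, site, ref),
               "cover")
})

test_that("BED export carries coordinates, support, and annotation", {
  circles <- tibble::tibble(circle_id = "c1", chrom = "chr", start = 100L,
                            end = 500L, size = 400L, support = 7L,
                            mh_len = 2L, mh_seq = "AT",
                            annotation = "exon")
  bed <- circles_to_bed(circles)
  expect_identical(names(bed)[1:6],
                   c("chrom", "start", "end", "name", "score", "strand"))
  expect_equal(bed$score, 7L)
  expect_equal(bed$size, 400L)
  path <- withr::local_tempfile(fileext = ".bed")
  circles_to_bed(circles, path)
  expect_equal(length(readLines(path)), 1)
})
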