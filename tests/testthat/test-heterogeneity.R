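prof_from_specs <- function(...) {
  # build a lineage profile from named per-sample (gene, label, frequency%)
  samples <- list(...)
  tbl <- purrr::imap_dfr(samples, function(x, nm) {
    dplyr::mutate(x, sample_id = nm)
  })
  profile_matrix(tbl, sample_order = names(samples))
}

test_that("profile matrices fill the union of labels with zeros", {
  a <- tibble::tibble(gene_id = "g1", label = c("WT", "Del1|0"),
                      frequency = c(60, 40))
  b <- tibble::tibble(gene_id = "g1", label = c("WT", "Ins1A"),
                      frequency = c(70, 30))
  prof <- prof_from_specs(s1 = a, s2 = b)
  x <- tidy(prof)
  expect_equal(nrow(x), 3 * 2)  # 3 labels x 2 samples
  expect_equal(x$frequency[x$label == "Ins1A" & x$sample_id == "s1"], 0)
  expect_equal(x$frequency[x$label == "Del1|0" & x$sample_id == "s2"], 0)
  expect_identical(profile_samples(prof), c("s1", "s2"))

  single <- prof_from_specs(only = a)
  expect_equal(nrow(tidy(single)), 2)
  expect_equal(sort(tidy(single)$frequency), c(40, 60))

  dup <- dplyr::bind_rows(dplyr::mutate(a, sample_id = "s1"),
                          dplyr::mutate(a, sample_id = "s1"))
  expect_error(profile_matrix(dup), "duplicated")
})

test_that("profile dimensions follow the simulated lineage", {
  parent <- purrr::map_dfr(sprintf("g%02d", 1:6), function(g) {
    tibble::tibble(gene_id = g, label = c("WT", "Del1|0", "Ins1A"),
                   frequency = c(0.4, 0.35, 0.25))
  })
  lin <- simulate_lineage(parent, n_subclones = 12, p_loss = 0.1,
                          p_gain = 0.1, drift_sd = 0, seed = 3)
  samples <- dplyr::mutate(lin$samples, frequency = frequency * 100)
  prof <- profile_matrix(samples)
  n_pairs <- nrow(dplyr::distinct(lin$samples[, c("gene_id", "label")]))
  expect_equal(nrow(tidy(prof)), n_pairs * 13)  # parent + 12 subclones
  expect_equal(glance(prof)$n_samples, 13)
})

test_that("clone counts per mutation type respect the threshold", {
  mk <- function(f) tibble::tibble(gene_id = "g1",
                                   label = c("WT", "Del1|0"),
                                   frequency = c(100 - f, f))
  prof <- prof_from_specs(s1 = mk(10), s2 = mk(6), s3 = mk(5), s4 = mk(4.9),
                          s5 = mk(0))
  cc <- clone_count_per_type(prof, tau = 5)
  expect_equal(cc$n_clones[cc$label == "Del1|0"], 3)
  expect_equal(cc$proportion_pct[cc$label == "Del1|0"], 60)
  expect_equal(cc$n_clones[cc$label == "WT"], 5)
  absent <- clone_count_per_type(prof, tau = 200)
  expect_true(all(absent$n_clones == 0))
})

test_that("allelic richness counts alleles at threshold and flags >2", {
  a <- tibble::tibble(gene_id = "g1", label = c("WT", "Del1|0"),
                      frequency = c(50, 50))
  b <- tibble::tibble(gene_id = "g1",
                      label = c("WT", "Del1|0", "Ins1A", "Del0|7"),
                      frequency = c(30, 30, 25, 15))
  c_ <- tibble::tibble(gene_id = "g1",
                       label = c("WT", "Del1|0", "Ins1A"),
                       frequency = c(92, 4, 4))
  prof <- prof_from_specs(diploid = a, amplified = b, quiet = c_)
  r <- allele_richness(prof, tau = 5)
  expect_equal(r$richness[r$sample_id == "diploid"], 2)
  expect_false(r$flag_gt2[r$sample_id == "diploid"])
  expect_equal(r$richness[r$sample_id == "amplified"], 4)
  expect_true(r$flag_gt2[r$sample_id == "amplified"])
  expect_equal(r$richness[r$sample_id == "quiet"], 1)
})

test_that("oscillation events capture threshold crossings in both directions", {
  parent <- tibble::tibble(gene_id = c("Rb1", "Rb1", "Rb1"),
                           label = c("WT", "Ins1T", "Del22|5"),
                           frequency = c(71, 0, 29))
  child <- tibble::tibble(gene_id = c("Rb1", "Rb1", "Rb1"),
                          label = c("WT", "Ins1T", "Del22|5"),
                          frequency = c(64.5, 35, 0.5))
  prof <- prof_from_specs(parent = parent, child = child)
  ev <- oscillation_events(prof, "parent", "child")
  expect_equal(nrow(ev), 2)
  expect_identical(ev$event[ev$label == "Ins1T"], "gain")
  expect_identical(ev$event[ev$label == "Del22|5"], "loss")

  none <- oscillation_events(prof_from_specs(p = parent, c = parent), "p", "c")
  expect_equal(nrow(none), 0)
  expect_error(oscillation_events(prof, "parent", "ghost"), "not in profile")
})

test_that("swapping parent and child mirrors every event", {
  set.seed(61)
  mk_sample <- function() {
    purrr::map_dfr(c("g1", "g2", "g3"), function(g) {
      f <- runif(4); f <- f / sum(f) * 100
      tibble::tibble(gene_id = g,
                     label = c("WT", "Del1|0", "Ins1A", "Del0|7"),
                     frequency = f)
    })
  }
  for (i in 1:10) {
    prof <- prof_from_specs(a = mk_sample(), b = mk_sample())
    fwd <- oscillation_events(prof, "a", "b")
    rev <- oscillation_events(prof, "b", "a")
    expect_equal(nrow(fwd), nrow(rev))
    if (nrow(fwd) > 0) {
      key_f <- paste(fwd$gene_id, fwd$label, fwd$event)
      key_r <- paste(rev$gene_id, rev$label,
                     ifelse(rev$event == "gain", "loss", "gain"))
      expect_setequal(key_f, key_r)
    }
  }
})

test_that("time courses are compared consecutively", {
  mk <- function(f) tibble::tibble(gene_id = "Rb1",
                                   label = c("WT", "Ins1T"),
                                   frequency = c(100 - f, f))
  prof <- prof_from_specs(D0 = mk(2.47), D15 = mk(35.09), D30 = mk(34.09),
                          Mon12 = mk(2))
  ev <- timecourse_events(prof)
  expect_equal(nrow(ev), 2)
  expect_identical(ev$event[ev$parent_id == "D0"], "gain")
  expect_identical(ev$event[ev$parent_id == "D30"], "loss")
  expect_error(timecourse_events(prof, chain = "D0"), "at least two")
})

test_that("square-root wide export matches the transform", {
  a <- tibble::tibble(gene_id = "g1", label = c("WT", "Del1|0"),
                      frequency = c(64, 36))
  prof <- prof_from_specs(s1 = a)
  w <- profile_wide(prof, scale = "sqrt")
  expect_equal(sort(w$s1), c(0.6, 0.8))
})
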