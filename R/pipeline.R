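# End-to-end orchestration: a configurable simulate -> quantify -> compare
# -> eccdna -> report chain with deterministic, file-based outputs. The
# exported functions back the thin command-line wrapper installed at
# `exec/crispecc`.

#' Build a pipeline run configuration
#'
#' Central defaults for the demonstration pipeline; every field can be
#' overridden. All randomness in a run derives from `seed`, so identical
#' configurations produce byte-identical outputs.
#'
#' @param seed Integer seed.
#' @param outdir Output directory.
#' @param n_targets Number of simulated target sites.
#' @param n_subclones Subclones derived from the parent clone.
#' @param depth Reads per sample and target.
#' @param read_len Read length, bp.
#' @param err Per-base substitution error rate.
#' @param tau True-mutation / presence threshold, percent.
#' @param window_halfwidth Classification window half-width, bp.
#' @param min_support Junction-read support threshold for circles.
#' @param min_coverage Minimum retained reads to quantify a site.
#' @param n_circles Simulated eccDNA circles.
#' @param p_loss,p_gain,drift_sd Lineage simulator event parameters.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, outdir = "crispecc_run",
                       n_targets = 4L, n_subclones = 2L, depth = 300L,
                       read_len = 150L, err = 0.002, tau = 5,
                       window_halfwidth = 25L, min_support = 2L,
                       min_coverage = 100L, n_circles = 4L,
                       p_loss = 0.08, p_gain = 0.15, drift_sd = 0.005) {
  cfg <- list(seed = as.integer(seed), outdir = outdir,
              n_targets = as.integer(n_targets),
              n_subclones = as.integer(n_subclones),
              depth = as.integer(depth), read_len = as.integer(read_len),
              err = err, tau = tau,
              window_halfwidth = as.integer(window_halfwidth),
              min_support = as.integer(min_support),
              min_coverage = as.integer(min_coverage),
              n_circles = as.integer(n_circles),
              p_loss = p_loss, p_gain = p_gain, drift_sd = drift_sd)
  stopifnot(cfg$tau >= 0, cfg$tau <= 100, cfg$err >= 0, cfg$err < 1,
            cfg$depth >= 1, cfg$n_targets >= 1)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}

write_provenance <- function(cfg, path) {
  lines <- c(
    sprintf("crispecc %s", as.character(utils::packageVersion("crispecc"))),
    sprintf("seed: %d", cfg$seed),
    vapply(setdiff(names(cfg), c("seed", "outdir")),
           function(nm) sprintf("%s: %s", nm, format(cfg[[nm]])),
           character(1))
  )
  writeLines(lines, path)
}

#' Run the pipeline (or one stage of it)
#'
#' Stages: `simulate` writes the mini-genome, target table, per-sample
#' FASTQ files, and ground truth; `quantify` classifies the reads and
#' writes per-sample allele tables; `compare` builds the lineage profile
#' and gain/loss events against the parent; `eccdna` simulates an RCA
#' eccDNA library, detects circles, and writes circle records, size stats,
#' and junction distances; `report` writes a combined summary. `all` runs
#' every stage. Each stage is a pure function of the configuration: a
#' fixed seed reproduces every output byte for byte. On error, files
#' created by the failing run are removed.
#'
#' @param config A `run_config` from [run_config()].
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisibly, a list with the in-memory results per stage.
#' @export
run_pipeline <- function(config = run_config(), stages = "all") {
  all_stages <- c("simulate", "quantify", "compare", "eccdna", "report")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  out <- config$outdir
  created <- !dir.exists(out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- withCallingHandlers(
    tryCatch(run_stages(config, stages),
             error = function(e) {
               if (created) unlink(out, recursive = TRUE)
               stop(e)
             }),
    message = function(m) m
  )
  invisible(res)
}

run_stages <- function(cfg, stages) {
  out <- cfg$outdir
  write_provenance(cfg, file.path(out, "run_info.txt"))
  res <- list()

  # -- simulate ----------------------------------------------------------
  sim <- simulate_reference(n_targets = cfg$n_targets, seed = cfg$seed)
  targets <- load_targets(sim$target_table, sim$ref,
                          window_halfwidth = cfg$window_halfwidth)
  withr::local_seed(cfg$seed + 1L)
  parent <- purrr::map_dfr(targets$gene_id, function(g) {
    labs <- "WT"
    while (length(labs) < 4) {
      labs <- unique(c(labs, random_indel_label(exclude = labs)))
    }
    tibble(gene_id = g, label = labs, frequency = c(0.34, 0.28, 0.22, 0.16))
  })
  lin <- simulate_lineage(parent, cfg$n_subclones, p_loss = cfg$p_loss,
                          p_gain = cfg$p_gain, drift_sd = cfg$drift_sd,
                          tau = cfg$tau, seed = cfg$seed + 2L)
  sample_ids <- unique(lin$samples$sample_id)
  read_sets <- list()
  for (si in seq_along(sample_ids)) {
    s <- sample_ids[si]
    per_gene <- purrr::map(seq_len(nrow(targets)), function(ti) {
      site <- targets[ti, ]
      spec <- lin$samples[lin$samples$sample_id == s &
                            lin$samples$gene_id == site$gene_id,
                          c("label", "frequency")]
      spec <- spec[spec$frequency > 0, ]
      spec$frequency <- spec$frequency / sum(spec$frequency)
      sim_r <- simulate_amplicon_reads(site, sim$ref, spec, cfg$depth,
                                       read_len = cfg$read_len, err = cfg$err,
                                       seed = cfg$seed + 100L * si + ti)
      sim_r$reads$read_id <- paste0(s, "_", sim_r$reads$read_id)
      sim_r
    })
    reads <- purrr::map_dfr(per_gene, "reads")
    read_sets[[s]] <- reads
  }
  if ("simulate" %in% stages) {
    writeLines(c(paste0(">", names(sim$ref)), unname(sim$ref)),
               file.path(out, "reference.fa"))
    write_targets(targets, file.path(out, "targets.tsv"))
    readr::write_tsv(sim$annotation, file.path(out, "annotation.tsv"),
                     progress = FALSE)
    readr::write_tsv(lin$samples, file.path(out, "lineage_truth.tsv"),
                     progress = FALSE)
    readr::write_tsv(lin$events, file.path(out, "lineage_events_truth.tsv"),
                     progress = FALSE)
    for (s in sample_ids) {
      write_fastq(read_sets[[s]], file.path(out, paste0(s, ".fastq")))
    }
    res$simulate <- list(targets = targets, lineage = lin)
  }

  # -- quantify ----------------------------------------------------------
  tables <- list()
  for (s in sample_ids) {
    for (ti in seq_len(nrow(targets))) {
      site <- targets[ti, ]
      sel <- startsWith(read_sets[[s]]$read_id,
                        paste0(s, "_", site$gene_id, "_"))
      calls <- call_alleles(read_sets[[s]][sel, ], site, sim$ref)
      tab <- build_allele_table(calls, sample_id = s,
                                min_coverage = cfg$min_coverage)
      tables[[length(tables) + 1L]] <-
        apply_true_mutation_threshold(tab, tau = cfg$tau)
    }
  }
  combined <- purrr::map_dfr(tables, as_tibble)
  if ("quantify" %in% stages) {
    readr::write_tsv(combined, file.path(out, "allele_tables.tsv"),
                     progress = FALSE)
    res$quantify <- tables
  }

  # -- compare -----------------------------------------------------------
  profile <- profile_matrix(combined, sample_order = sample_ids)
  events <- oscillation_events(profile, parent = "parent",
                               children = setdiff(sample_ids, "parent"),
                               tau = cfg$tau)
  if ("compare" %in% stages) {
    readr::write_tsv(as_tibble(profile), file.path(out, "profile_long.tsv"),
                     progress = FALSE)
    readr::write_tsv(profile_wide(profile, scale = "sqrt"),
                     file.path(out, "profile_sqrt_wide.tsv"), progress = FALSE)
    readr::write_tsv(events, file.path(out, "oscillation_events.tsv"),
                     progress = FALSE)
    res$compare <- list(profile = profile, events = events)
  }

  # -- eccdna ------------------------------------------------------------
  withr::local_seed(cfg$seed + 3L)
  chrom <- names(sim$ref)[1]
  glen <- nchar(sim$ref[[1]])
  n_circ <- cfg$n_circles
  n_target_circ <- min(2L, n_circ, nrow(targets))
  circ <- list()
  for (i in seq_len(n_target_circ)) {
    site <- targets[i, ]
    size <- sample(400:800, 1)
    off <- sample(100:(size - 100), 1)
    circ[[i]] <- tibble(chrom = chrom, start = site$cut_pos - off,
                        end = site$cut_pos - off + size,
                        copy_number = 3L, mh_len = sample(0:3, 1),
                        allele_at_target = "Del1|0")
  }
  for (i in seq_len(n_circ - n_target_circ)) {
    size <- sample(300:900, 1)
    start <- sample(0:(glen - size), 1)
    circ[[n_target_circ + i]] <- tibble(chrom = chrom, start = start,
                                        end = start + size, copy_number = 1L,
                                        mh_len = 0L,
                                        allele_at_target = NA_character_)
  }
  ecc <- simulate_eccdna_library(dplyr::bind_rows(circ), sim$ref,
                                 targets = targets, seed = cfg$seed + 4L)
  circles <- detect_junctions(ecc$reads, ecc$ref,
                              min_support = cfg$min_support)
  circles <- annotate_circle(circles, sim$annotation)
  hits <- assign_target_alleles(circles, ecc$reads, targets, ecc$ref)
  if ("eccdna" %in% stages) {
    write_fastq(ecc$reads, file.path(out, "eccdna.fastq"))
    readr::write_tsv(ecc$truth, file.path(out, "eccdna_truth.tsv"),
                     progress = FALSE)
    circles_to_bed(circles, file.path(out, "circles.bed"))
    if (nrow(circles) > 0) {
      readr::write_tsv(circle_length_stats(circles),
                       file.path(out, "circle_stats.tsv"), progress = FALSE)
    }
    readr::write_tsv(hits, file.path(out, "circle_target_alleles.tsv"),
                     progress = FALSE)
    res$eccdna <- list(circles = circles, hits = hits)
  }

  # -- report ------------------------------------------------------------
  if ("report" %in% stages) {
    summary_tbl <- purrr::map_dfr(tables, glance)
    readr::write_tsv(summary_tbl, file.path(out, "report_allele_summary.tsv"),
                     progress = FALSE)
    readr::write_tsv(glance(circles), file.path(out, "report_circles.tsv"),
                     progress = FALSE)
    res$report <- summary_tbl
  }
  res
}
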