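# Per-target allele tables, frequencies, thresholds, and library-normalized
# read ratios.
#
# Discarded reads are excluded from both numerator and denominator of every
# frequency. The gene-level mutation frequency is the total edited read
# count divided by the total retained read count (equivalently,
# 100 - WT frequency). An allelic mutation with a frequency of no less than
# `tau` percent (default 5) is flagged as a true mutation, the filter used
# to suppress sequencing-error alleles.

#' Build a per-target allele table from read calls
#'
#' Aggregates retained allele calls by label and computes allelic
#' frequencies in percent of retained reads. Sites with fewer retained
#' reads than `min_coverage` are reported as a no-call record (one all-NA
#' row) rather than as 0% frequencies.
#'
#' @param calls Allele-call tibble from [call_alleles()]/[classify_edits()].
#' @param sample_id,gene_id Identifiers stamped onto the table; `gene_id`
#'   defaults to the calls' `gene_id` column when present.
#' @param min_coverage Minimum retained reads for the site to be quantified
#'   (default 100).
#' @return An `allele_table`: tibble with columns `sample_id`, `gene_id`,
#'   `label`, `read_count`, `frequency` (percent), plus attributes
#'   `total_reads`, `n_discarded`, and `gene_mutation_frequency`.
#' @export
build_allele_table <- function(calls, sample_id, gene_id = NULL,
                               min_coverage = 100L) {
  gene_id <- gene_id %||% unique(calls$gene_id)
  stopifnot(length(gene_id) == 1)
  retained <- calls[!is.na(calls$category) & calls$category != "DISCARD", ]
  n_disc <- nrow(calls) - nrow(retained)
  if (nrow(retained) < min_coverage) {
    out <- tibble(sample_id = sample_id, gene_id = gene_id,
                  label = NA_character_, read_count = NA_integer_,
                  frequency = NA_real_, is_true_mutation = NA)
    return(new_allele_table(out, total_reads = nrow(retained),
                            n_discarded = n_disc, no_call = TRUE))
  }
  agg <- retained |>
    count(label = .data$label, name = "read_count") |>
    arrange(dplyr::desc(.data$read_count), .data$label) |>
    mutate(frequency = .data$read_count / sum(.data$read_count) * 100,
           sample_id = sample_id, gene_id = gene_id) |>
    select("sample_id", "gene_id", "label", "read_count", "frequency")
  new_allele_table(agg, total_reads = nrow(retained), n_discarded = n_disc,
                   no_call = FALSE)
}

new_allele_table <- function(tbl, total_reads, n_discarded, no_call) {
  wt <- tbl$frequency[tbl$label == "WT"]
  mf <- if (no_call) NA_real_ else 100 - (if (length(wt)) wt else 0)
  structure(tbl,
            class = c("allele_table", class(tbl)),
            total_reads = total_reads,
            n_discarded = n_discarded,
            no_call = no_call,
            gene_mutation_frequency = mf)
}

#' Gene-level mutation frequency of an allele table
#'
#' Total edited read count over total retained read count, in percent
#' (equivalently `100 - frequency(WT)`).
#'
#' @param table An `allele_table`.
#' @return Scalar percent (NA for a no-call record).
#' @export
gene_mutation_frequency <- function(table) {
  attr(table, "gene_mutation_frequency")
}

#' Flag true mutations under the frequency threshold
#'
#' A non-WT allele with frequency at no less than `tau` percent (inclusive)
#' is a true mutation; WT is never flagged. The threshold is applied per
#' sample and per site, never across pooled samples.
#'
#' @param table An `allele_table` (or compatible tibble with `label`,
#'   `frequency`).
#' @param tau Threshold in percent (default 5).
#' @return The table with an `is_true_mutation` logical column.
#' @export
apply_true_mutation_threshold <- function(table, tau = 5) {
  table$is_true_mutation <- !is.na(table$frequency) &
    table$label != "WT" & table$frequency >= tau
  if (any(is.na(table$label))) {
    table$is_true_mutation[is.na(table$label)] <- NA
  }
  table
}

#' Square-root transform a frequency matrix
#'
#' Elementwise square root of a targets-by-samples matrix of frequencies on
#' the `[0, 1]` scale, the transform used for lineage heatmaps.
#'
#' @param frequency_matrix Numeric matrix (or vector) with entries in
#'   `[0, 1]`.
#' @return Same-shape object of square roots.
#' @export
sqrt_transform <- function(frequency_matrix) {
  x <- frequency_matrix
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort("frequencies must lie in [0, 1]")
  }
  sqrt(x)
}

#' Per-gene percentages of a library's combined target reads
#'
#' Library-size normalization: each gene's read count as a percentage of
#' the combined reads over all targets in the library. Percentages sum to
#' 100.
#'
#' @param read_counts Tibble with columns `gene_id`, `read_count` (or a
#'   named numeric vector).
#' @param library_id Identifier stamped on the result.
#' @return Tibble with `library_id`, `gene_id`, `read_count`, `pct_of_library`.
#' @export
libsize_percentages <- function(read_counts, library_id) {
  if (!is.data.frame(read_counts)) {
    read_counts <- tibble(gene_id = names(read_counts),
                          read_count = unname(read_counts))
  }
  if (nrow(read_counts) == 0 || sum(read_counts$read_count) <= 0) {
    abort("library has no reads")
  }
  read_counts |>
    mutate(library_id = library_id,
           pct_of_library = .data$read_count / sum(.data$read_count) * 100) |>
    select("library_id", "gene_id", "read_count", "pct_of_library")
}

#' Relative read ratio of eccDNA to gDNA per target
#'
#' Divides each target's library-fraction percentage in the eccDNA library
#' by its percentage in the gDNA library. The ratio is undefined (NA, with
#' `ratio_defined = FALSE`) where the gDNA percentage is zero or invalid
#' under the `< 0.1%` rule; an eccDNA percentage of zero gives a ratio of
#' 0. Invalid flags for both libraries are carried alongside.
#'
#' @param gdna_pcts,eccdna_pcts Tibbles from [libsize_percentages()].
#' @param invalid_pct Invalid-site threshold in percent (default 0.1,
#'   strict less-than).
#' @return Tibble with `gene_id`, `pct_of_library_gDNA`,
#'   `pct_of_library_eccDNA`, `invalid_gDNA`, `invalid_eccDNA`,
#'   `relative_ratio`, `ratio_defined`.
#' @export
relative_read_ratio <- function(gdna_pcts, eccdna_pcts, invalid_pct = 0.1) {
  g <- gdna_pcts |>
    select("gene_id", pct_of_library_gDNA = "pct_of_library",
           reads_gDNA = "read_count")
  e <- eccdna_pcts |>
    select("gene_id", pct_of_library_eccDNA = "pct_of_library",
           reads_eccDNA = "read_count")
  out <- dplyr::full_join(g, e, by = "gene_id")
  out$pct_of_library_gDNA[is.na(out$pct_of_library_gDNA)] <- 0
  out$pct_of_library_eccDNA[is.na(out$pct_of_library_eccDNA)] <- 0
  out$invalid_gDNA <- out$pct_of_library_gDNA < invalid_pct
  out$invalid_eccDNA <- out$pct_of_library_eccDNA < invalid_pct
  out$ratio_defined <- !out$invalid_gDNA & out$pct_of_library_gDNA > 0
  out$relative_ratio <- ifelse(
    out$ratio_defined,
    out$pct_of_library_eccDNA / out$pct_of_library_gDNA,
    NA_real_
  )
  out[, c("gene_id", "pct_of_library_gDNA", "pct_of_library_eccDNA",
          "invalid_gDNA", "invalid_eccDNA", "relative_ratio", "ratio_defined")]
}

#' Flag invalid (trace-read) sites in a library
#'
#' A target is invalid when its reads amount to strictly less than
#' `invalid_pct` percent (default 0.1) of the library's total target reads.
#'
#' @inheritParams libsize_percentages
#' @param invalid_pct Threshold in percent, strict less-than.
#' @return Tibble with `gene_id`, `read_count`, `invalid`.
#' @export
flag_invalid_sites <- function(read_counts, invalid_pct = 0.1) {
  if (!is.data.frame(read_counts)) {
    read_counts <- tibble(gene_id = names(read_counts),
                          read_count = unname(read_counts))
  }
  total <- sum(read_counts$read_count)
  if (total <= 0) abort("library total must be > 0")
  read_counts |>
    mutate(invalid = .data$read_count / total * 100 < invalid_pct) |>
    select("gene_id", "read_count", "invalid")
}

#' @export
print.allele_table <- function(x, ...) {
  if (attr(x, "no_call")) {
    cat(sprintf("<allele_table> %s / %s: no call (%d retained reads)\n",
                x$sample_id[1], x$gene_id[1], attr(x, "total_reads")))
  } else {
    cat(sprintf(
      "<allele_table> %s / %s: %d retained reads (%d discarded), mutation frequency %.2f%%\n",
      x$sample_id[1], x$gene_id[1], attr(x, "total_reads"),
      attr(x, "n_discarded"), gene_mutation_frequency(x)))
  }
  print(as_tibble(x), ...)
  invisible(x)
}

#' @rdname tidy.allele_table
#' @method glance allele_table
#' @export
glance.allele_table <- function(x, ...) {
  tibble(sample_id = x$sample_id[1], gene_id = x$gene_id[1],
         total_reads = attr(x, "total_reads"),
         n_discarded = attr(x, "n_discarded"),
         no_call = attr(x, "no_call"),
         gene_mutation_frequency = gene_mutation_frequency(x),
         n_true_mutations = if ("is_true_mutation" %in% names(x)) {
           sum(x$is_true_mutation, na.rm = TRUE)
         } else {
           NA_integer_
         })
}

#' Tidiers for allele tables
#'
#' `tidy()` returns the per-allele rows as a plain tibble; `glance()`
#' returns a one-row summary (total reads, discards, gene mutation
#' frequency, number of true mutations if flagged).
#'
#' @param x An `allele_table`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy allele_table
#' @export
tidy.allele_table <- function(x, ...) {
  as_tibble(x)
}
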