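# Lineage profiles: allele-frequency matrices across related samples
# (parental clone, subclones, time points, grafts), allele gain/loss events
# between samples, and allelic richness per target.

#' Build a lineage profile matrix from allele tables
#'
#' Combines per-sample allele tables into a long (gene, label, sample)
#' frequency matrix: the union of labels per gene, absent labels filled
#' with 0%, sample order preserved as given.
#'
#' @param tables A list of `allele_table` objects, or one tibble with
#'   columns `sample_id`, `gene_id`, `label`, `frequency` (percent).
#' @param sample_order Optional explicit sample ordering; defaults to order
#'   of first appearance.
#' @param relations Optional named character vector of relation tags
#'   (`parent`/`subclone`/`timepoint`/`graft`) per sample.
#' @return A `lineage_profile`: long tibble `gene_id`, `label`,
#'   `sample_id`, `frequency`, with sample order and relations stored as
#'   attributes.
#' @export
profile_matrix <- function(tables, sample_order = NULL, relations = NULL) {
  if (is.list(tables) && !is.data.frame(tables)) {
    ids <- purrr::map_chr(tables, function(t) t$sample_id[1])
    per_sample_genes <- purrr::map_chr(tables, function(t) t$gene_id[1])
    key <- paste(ids, per_sample_genes)
    if (anyDuplicated(key)) {
      abort("duplicated sample_id/gene_id combination among allele tables")
    }
    tbl <- purrr::map_dfr(tables, as_tibble)
  } else {
    tbl <- as_tibble(tables)
  }
  stopifnot(all(c("sample_id", "gene_id", "label", "frequency") %in% names(tbl)))
  tbl <- tbl[!is.na(tbl$label), ]
  if (anyDuplicated(tbl[, c("sample_id", "gene_id", "label")])) {
    abort("duplicated (sample, gene, label) rows in input")
  }
  samples <- sample_order %||% unique(tbl$sample_id)
  if (anyDuplicated(samples)) abort("duplicated sample_id")
  long <- tbl |>
    select("gene_id", "label", "sample_id", "frequency") |>
    tidyr::complete(
      tidyr::nesting(gene_id, label),
      sample_id = samples,
      fill = list(frequency = 0)
    ) |>
    mutate(sample_id = factor(.data$sample_id, levels = samples)) |>
    arrange(.data$gene_id, .data$label, .data$sample_id) |>
    mutate(sample_id = as.character(.data$sample_id))
  structure(long,
            class = c("lineage_profile", class(long)),
            samples = samples,
            relations = relations)
}

#' Samples of a lineage profile, in order
#' @param profile A `lineage_profile`.
#' @return Character vector of sample ids.
#' @export
profile_samples <- function(profile) attr(profile, "samples")

#' Wide matrix form of a lineage profile
#'
#' @param profile A `lineage_profile`.
#' @param scale `"percent"` (as stored) or `"sqrt"` for the square root of
#'   the 0-1 fraction (the heatmap scale).
#' @return Tibble with `gene_id`, `label`, and one column per sample.
#' @export
profile_wide <- function(profile, scale = c("percent", "sqrt")) {
  scale <- match.arg(scale)
  x <- as_tibble(profile)
  if (scale == "sqrt") x$frequency <- sqrt_transform(x$frequency / 100)
  tidyr::pivot_wider(x, names_from = "sample_id", values_from = "frequency")
}

#' Number of clones carrying each mutation type
#'
#' For every (gene, label), the count of samples in which the label's
#' frequency is at or above `tau` percent.
#'
#' @param profile A `lineage_profile`.
#' @param tau Presence threshold in percent (default 5).
#' @return Tibble `gene_id`, `label`, `n_clones`, `proportion_pct`
#'   (percentage of samples carrying the type).
#' @export
clone_count_per_type <- function(profile, tau = 5) {
  n_samples <- length(profile_samples(profile))
  as_tibble(profile) |>
    group_by(.data$gene_id, .data$label) |>
    summarise(n_clones = sum(.data$frequency >= tau), .groups = "drop") |>
    mutate(proportion_pct = .data$n_clones / n_samples * 100)
}

#' Allelic richness per target and sample
#'
#' Richness is the number of alleles (including WT) at or above `tau`
#' percent in a sample at a target. Richness above 2 in a single-cell clone
#' flags more allele types than a diploid locus can carry (a copy-number
#' signal).
#'
#' @inheritParams clone_count_per_type
#' @return Tibble `gene_id`, `sample_id`, `richness`, `flag_gt2`.
#' @export
allele_richness <- function(profile, tau = 5) {
  as_tibble(profile) |>
    group_by(.data$gene_id, .data$sample_id) |>
    summarise(richness = sum(.data$frequency >= tau), .groups = "drop") |>
    mutate(flag_gt2 = .data$richness > 2)
}

#' Allele gain/loss events between a parent and child samples
#'
#' For each (gene, label) and child: a loss event where the parent
#' frequency is at or above `tau` and the child's is below; a gain event
#' where the parent is below `tau` and the child at or above. WT
#' participates like any allele. An optional hysteresis band suppresses
#' events whose frequencies lie within `band` percentage points of `tau`
#' on both sides.
#'
#' @inheritParams clone_count_per_type
#' @param parent Parent sample id.
#' @param children Character vector of child sample ids.
#' @param band Hysteresis half-band in percentage points (default 0).
#' @return Tibble `sample_id` (child), `gene_id`, `label`, `event`
#'   (`gain`/`loss`), `parent_frequency`, `child_frequency`.
#' @export
oscillation_events <- function(profile, parent, children, tau = 5, band = 0) {
  samples <- profile_samples(profile)
  missing <- setdiff(c(parent, children), samples)
  if (length(missing) > 0) {
    abort(sprintf("sample(s) not in profile: %s", paste(missing, collapse = ", ")))
  }
  x <- as_tibble(profile)
  p <- x[x$sample_id == parent, c("gene_id", "label", "frequency")]
  names(p)[3] <- "parent_frequency"
  purrr::map_dfr(children, function(ch) {
    c_tbl <- x[x$sample_id == ch, c("gene_id", "label", "frequency")]
    names(c_tbl)[3] <- "child_frequency"
    m <- dplyr::inner_join(p, c_tbl, by = c("gene_id", "label"))
    loss <- m$parent_frequency >= tau + band & m$child_frequency < tau - band
    gain <- m$parent_frequency < tau - band & m$child_frequency >= tau + band
    ev <- m[loss | gain, ]
    if (nrow(ev) == 0) return(NULL)
    ev$event <- ifelse(ev$parent_frequency >= tau, "loss", "gain")
    ev$sample_id <- ch
    ev[, c("sample_id", "gene_id", "label", "event",
           "parent_frequency", "child_frequency")]
  })
}

#' Consecutive gain/loss events along a time course
#'
#' Treats the samples as an ordered chain (e.g. day 0, day 15, day 30, ...)
#' and reports [oscillation_events()] for each consecutive parent-child
#' step.
#'
#' @inheritParams oscillation_events
#' @param chain Ordered character vector of sample ids; defaults to the
#'   profile's sample order.
#' @return Event tibble with an extra `parent_id` column.
#' @export
timecourse_events <- function(profile, chain = NULL, tau = 5, band = 0) {
  chain <- chain %||% profile_samples(profile)
  if (length(chain) < 2) {
    abort("a time course needs at least two samples")
  }
  purrr::map_dfr(seq_len(length(chain) - 1L), function(i) {
    ev <- oscillation_events(profile, chain[i], chain[i + 1L],
                             tau = tau, band = band)
    if (nrow(ev) == 0) return(NULL)
    ev$parent_id <- chain[i]
    ev
  })
}

#' @rdname tidy.lineage_profile
#' @method glance lineage_profile
#' @export
glance.lineage_profile <- function(x, ...) {
  tibble(n_samples = length(profile_samples(x)),
         n_genes = length(unique(x$gene_id)),
         n_labels = nrow(distinct(as_tibble(x)[, c("gene_id", "label")])))
}

#' Tidiers for lineage profiles
#'
#' `tidy()` returns the long frequency matrix; `glance()` a one-row size
#' summary.
#'
#' @param x A `lineage_profile`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lineage_profile
#' @export
tidy.lineage_profile <- function(x, ...) as_tibble(x)
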