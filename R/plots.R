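# ggplot2 presentation helpers. All plotting is presentation-only; every
# quantity shown is computed by the quantification functions.

#' Bar plot of an allele table
#'
#' Allelic frequencies (percent of retained reads) per label, with true
#' mutations highlighted when flagged.
#'
#' @param table An `allele_table`.
#' @param tau Optional threshold line, percent.
#' @return A ggplot object.
#' @export
plot_allele_frequencies <- function(table, tau = 5) {
  x <- as_tibble(table)
  x <- x[!is.na(x$label), ]
  x$label <- factor(x$label, levels = x$label[order(-x$frequency)])
  fill <- if ("is_true_mutation" %in% names(x)) {
    factor(dplyr::case_when(x$label == "WT" ~ "WT",
                            x$is_true_mutation ~ "true mutation",
                            TRUE ~ "below threshold"),
           levels = c("WT", "true mutation", "below threshold"))
  } else {
    factor(ifelse(x$label == "WT", "WT", "mutation"))
  }
  ggplot2::ggplot(x, ggplot2::aes(x = .data$label, y = .data$frequency,
                                  fill = fill)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = tau, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = "frequency (%)", fill = NULL,
                  title = sprintf("%s / %s", x$sample_id[1], x$gene_id[1])) +
    ggplot2::theme_minimal()
}

#' @method autoplot allele_table
#' @export
autoplot.allele_table <- function(object, ...) {
  plot_allele_frequencies(object, ...)
}

#' Square-root frequency heatmap of a lineage profile
#'
#' Tiles of the square root of the 0-1 mutation frequency per (gene,
#' label) row and sample column, white (0) to dark green (1).
#'
#' @param profile A `lineage_profile`.
#' @return A ggplot object.
#' @export
plot_profile_heatmap <- function(profile) {
  x <- as_tibble(profile)
  x$row <- paste(x$gene_id, x$label)
  x$sample_id <- factor(x$sample_id, levels = profile_samples(profile))
  x$sqrt_freq <- sqrt_transform(x$frequency / 100)
  ggplot2::ggplot(x, ggplot2::aes(x = .data$sample_id, y = .data$row,
                                  fill = .data$sqrt_freq)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen",
                                 limits = c(0, 1),
                                 name = expression(sqrt(frequency))) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot lineage_profile
#' @export
autoplot.lineage_profile <- function(object, ...) {
  plot_profile_heatmap(object, ...)
}

#' Histogram of circle sizes
#'
#' @param circles A `circle_set` (or tibble with a `size` column).
#' @param bin_width Bin width, bp.
#' @return A ggplot object.
#' @export
plot_circle_sizes <- function(circles, bin_width = 250L) {
  x <- as_tibble(circles)
  ggplot2::ggplot(x, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "eccDNA size (bp)", y = "circles") +
    ggplot2::theme_minimal()
}

#' @method autoplot circle_set
#' @export
autoplot.circle_set <- function(object, ...) {
  plot_circle_sizes(object, ...)
}

#' Junction-distance scatter plot
#'
#' log10 distances from the Cas9 cut to the proximal and distal junction
#' coordinates, one point per circle.
#'
#' @param distances Tibble from [junction_distance_to_cut()].
#' @return A ggplot object.
#' @export
plot_junction_distances <- function(distances) {
  ggplot2::ggplot(distances,
                  ggplot2::aes(x = .data$log10_proximal,
                               y = .data$log10_distal)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "log10 proximal distance (bp)",
                  y = "log10 distal distance (bp)") +
    ggplot2::theme_minimal()
}

#' Bar plot of eccDNA/gDNA relative read ratios
#'
#' @param ratios Tibble from [relative_read_ratio()].
#' @return A ggplot object.
#' @export
plot_relative_ratios <- function(ratios) {
  x <- ratios[ratios$ratio_defined, ]
  ggplot2::ggplot(x, ggplot2::aes(x = stats::reorder(.data$gene_id,
                                                     -.data$relative_ratio),
                                  y = .data$relative_ratio)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "eccDNA% / gDNA%") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
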