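#' Plot bin heterozygosity scores along chromosomes
#'
#' Displays the pooled heterozygosity score of each bin at its midpoint,
#' coloured by zygosity class (if classified), faceted by chromosome —
#' zygosity switches (crossovers) are visible as jumps between the
#' heterozygous band near 0.5 and the homozygous band near 0.
#'
#' @param object A `bc1_bins` tibble from [bin_snps()] (optionally after
#'   [classify_bins()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bc1_bins
#' @export
autoplot.bc1_bins <- function(object, ...) {
  df <- mutate(object, midpoint = (first_snp_pos + last_snp_pos) / 2e6)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = midpoint, y = h)) +
    ggplot2::geom_hline(yintercept = c(0.05, 0.45), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::facet_grid(sample_id ~ chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "pooled heterozygosity h") +
    ggplot2::ylim(0, 0.55)
  if ("zygosity" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = zygosity), size = 0.8)
  } else {
    p + ggplot2::geom_point(size = 0.8)
  }
}

#' Plot the crossover distribution along normalized chromosome arms
#'
#' @param object A `co_summary` from [summarize_crossovers()].
#' @param bins Number of histogram bins over the arm (0 = centromere,
#'   1 = telomere).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot co_summary
#' @export
autoplot.co_summary <- function(object, bins = 10, ...) {
  ggplot2::ggplot(object$arm_positions, ggplot2::aes(x = arm_pos)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, closed = "left",
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "proportional arm position (0 = centromere, 1 = telomere)",
                  y = "crossovers")
}

#' Plot detected maxima over a spot image
#'
#' @param object A `maxima_set` from [find_maxima()].
#' @param image The image the maxima were detected in (matrix).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot maxima_set
#' @export
autoplot.maxima_set <- function(object, image, ...) {
  img_df <- tibble(
    row = rep(seq_len(nrow(image)), ncol(image)),
    col = rep(seq_len(ncol(image)), each = nrow(image)),
    value = as.numeric(image))
  ggplot2::ggplot(img_df, ggplot2::aes(x = col, y = row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(data = as_tibble(object),
                        colour = "red", shape = 3, size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity")
}

#' Plot a crossover event spectrum
#'
#' Bar chart of the fraction of tetrads with 0, 1, 2 and 3+ crossover
#' events across the scored intervals, optionally comparing genotypes.
#'
#' @param spectra A tibble from [tetrad_event_spectrum()], or several such
#'   tibbles row-bound with an added `genotype` column.
#' @return A ggplot object.
#' @export
plot_event_spectrum <- function(spectra) {
  if (!"genotype" %in% names(spectra)) spectra$genotype <- "all"
  df <- spectra %>%
    group_by(genotype) %>%
    mutate(fraction = n / sum(n)) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = events, y = fraction,
                                   fill = genotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "crossover events per tetrad",
                  y = "fraction of tetrads")
}
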