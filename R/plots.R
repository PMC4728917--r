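#' Plot an unfolded SFS against its neutral expectation
#'
#' Observed bin proportions as bars with the neutral expectation overlaid
#' as points and a line, one panel per SNP category.
#'
#' @param object a `rarehap_sfs` tibble from [sfs_table()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rarehap_sfs <- function(object, ...) {
  mid <- (object$bin_low + object$bin_high) / 2
  df <- mutate(as_tibble(object), mid = mid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed_prop),
                      fill = "grey55", width = 0.08) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected_prop),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected_prop),
                        colour = "firebrick", size = 1) +
    ggplot2::facet_wrap(~category) +
    ggplot2::labs(x = "derived-allele frequency",
                  y = "proportion of SNPs",
                  title = "Unfolded SFS vs neutral expectation") +
    ggplot2::theme_minimal()
}

#' Plot the relative-rate decay over frequency bins
#'
#' @param object a `rarehap_ratefreq` tibble from [rate_by_frequency()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rarehap_ratefreq <- function(object, ...) {
  df <- filter(as_tibble(object), !is.na(.data$ratio))
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                                   y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "focal-allele frequency",
                  y = "relative rate (derived / ancient)",
                  title = "Relative-rate decay with allele frequency") +
    ggplot2::theme_minimal()
}

#' Plot a quadratic fit of binned SNP counts
#'
#' @param object a `rarehap_quadfit` from [quadratic_fit()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rarehap_quadfit <- function(object, ...) {
  grid <- tibble(x = seq(min(object$data$x), 1, length.out = 200))
  cf <- object$coefficients
  grid$y <- cf[1] + cf[2] * grid$x + cf[3] * grid$x^2
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "frequency bin midpoint", y = "SNP count",
                  title = sprintf("Quadratic fit (r = %.2f, y(1) = %.1f)",
                                  object$r, object$y_at_1)) +
    ggplot2::theme_minimal()
}

#' Plot per-accession rare-allele occurrence against the binomial
#' expectation
#'
#' @param object a `rarehap_occurrence` from [accession_occurrence()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rarehap_occurrence <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected),
                       colour = "firebrick") +
    ggplot2::labs(x = "rare-allele memberships per accession",
                  y = "number of accessions",
                  title = "Occurrence of rare alleles across accessions") +
    ggplot2::theme_minimal()
}
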