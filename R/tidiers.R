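#' Tidy a quadratic fit
#'
#' @param x a `rarehap_quadfit` object.
#' @param ... unused.
#' @return tibble with `term` (`c0`, `c1`, `c2`) and `estimate`.
#' @exportS3Method generics::tidy
tidy.rarehap_quadfit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' Glance at a quadratic fit
#'
#' @param x a `rarehap_quadfit` object.
#' @param ... unused.
#' @return one-row tibble with `r` and `y_at_1`.
#' @exportS3Method generics::glance
glance.rarehap_quadfit <- function(x, ...) {
  tibble(r = x$r, y_at_1 = x$y_at_1)
}

#' Tidy a random occurrence model
#'
#' @param x a `rarehap_rom` object.
#' @param ... unused.
#' @return the per-`i` observed/expected table.
#' @exportS3Method generics::tidy
tidy.rarehap_rom <- function(x, ...) x$table

#' Glance at a random occurrence model
#'
#' @param x a `rarehap_rom` object.
#' @param ... unused.
#' @return one-row tibble with `F1`, `chi2`, `df`, `p_value`.
#' @exportS3Method generics::glance
glance.rarehap_rom <- function(x, ...) {
  tibble(F1 = x$F1, chi2 = x$chi2, df = x$df, p_value = x$p_value)
}

#' Tidy a per-accession occurrence result
#'
#' @param x a `rarehap_occurrence` object.
#' @param ... unused.
#' @return the per-accession tibble.
#' @exportS3Method generics::tidy
tidy.rarehap_occurrence <- function(x, ...) x$per_accession

#' Glance at a per-accession occurrence result
#'
#' @param x a `rarehap_occurrence` object.
#' @param ... unused.
#' @return one-row tibble with `p_hat`, `n_outliers`, `chi2_p`.
#' @exportS3Method generics::glance
glance.rarehap_occurrence <- function(x, ...) {
  tibble(p_hat = x$p_hat,
         n_outliers = sum(x$per_accession$outlier),
         chi2_p = x$chi2_p)
}
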