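#' Exact Shapley attributions for a linear model
#'
#' For a linear model `f(x) = b0 + sum_j beta_j x_j` evaluated against a
#' background of feature means, the Shapley value of feature `j` at a point
#' `x` has the closed form `phi_j = beta_j (x_j - mean_j)`.  The attributions
#' satisfy the efficiency axiom: `sum_j phi_j = f(x) - f(means)`.
#'
#' @param coefficients named or plain numeric vector of slopes `beta_j`.
#' @param intercept model intercept (does not affect attributions).
#' @param background_means numeric vector of feature means, same length as
#'   `coefficients`.
#' @param x_row numeric vector (single observation) or matrix/data frame of
#'   observations.
#' @return a numeric vector of attributions, or a matrix (rows = observations)
#'   when `x_row` has multiple rows.
#' @export
linear_shap <- function(coefficients, intercept, background_means, x_row) {
  p <- length(coefficients)
  assert_that(length(background_means) == p,
              "`background_means` length must match `coefficients`")
  if (is.data.frame(x_row)) x_row <- as.matrix(x_row)
  if (is.matrix(x_row)) {
    assert_that(ncol(x_row) == p, "`x_row` has the wrong number of columns")
    phi <- sweep(x_row, 2, background_means, "-")
    return(sweep(phi, 2, as.numeric(coefficients), "*"))
  }
  assert_that(length(x_row) == p, "`x_row` has the wrong length")
  as.numeric(coefficients) * (x_row - background_means)
}
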