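#' Hartigan dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical CDF and any unimodal CDF. It is zero for a constant sample,
#' at most 1/4, and at least `1/(2n)` for a sample of `n` distinct values;
#' large values indicate multimodality. The statistic is computed exactly
#' by an O(n^2)-worst-case hull algorithm (see the package vignette for the
#' construction); the test suite verifies it against an independent
#' linear-programming oracle.
#'
#' @param x Numeric vector (NA not allowed).
#' @return The dip statistic, a single number in `[0, 0.25]`.
#' @examples
#' dip_statistic(c(rnorm(50, 0), rnorm(50, 6)))  # large
#' dip_statistic(rnorm(100))                     # small
#' @export
dip_statistic <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1, all(is.finite(x)))
  .dip_stat_cpp(as.numeric(x))
}

#' Test a trait sample for multimodality (dip test)
#'
#' Computes the dip statistic and a bootstrap p value under the uniform
#' null: `n_boot` samples of the same size are drawn from Uniform(0, 1)
#' (the least-favourable unimodal case), and `p` is the fraction of null
#' dips at least as large as the observed one. A constant sample has dip 0
#' and `p = 1` by construction.
#'
#' @param values Numeric vector of trait measurements, `n >= 10`.
#' @param n_boot Number of bootstrap null draws (default 2000).
#' @param seed Optional integer seed for the bootstrap.
#' @return A one-row tibble: `dip`, `p_value`, `n`, `n_boot`.
#' @examples
#' test_multimodality(c(rnorm(30, 0.020, 0.002), rnorm(30, 0.068, 0.002)),
#'                    n_boot = 500, seed = 1)
#' @export
test_multimodality <- function(values, n_boot = 2000, seed = NULL) {
  stopifnot(is.numeric(values), all(is.finite(values)), n_boot >= 1)
  n <- length(values)
  if (n < 10) stop("need at least 10 observations for the dip test", call. = FALSE)
  d <- dip_statistic(values)
  if (d == 0) {
    return(tibble::tibble(dip = 0, p_value = 1, n = n, n_boot = as.integer(n_boot)))
  }
  if (!is.null(seed)) set.seed(seed)
  null_dips <- .dip_null_cpp(n, as.integer(n_boot))
  tibble::tibble(dip = d, p_value = mean(null_dips >= d), n = n,
                 n_boot = as.integer(n_boot))
}
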