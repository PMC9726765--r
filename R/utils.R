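`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compensated (Kahan) summation
#'
#' Sums a numeric vector with Kahan's compensated algorithm. Used for the
#' Sullivan sums over ages so that expectancy identities (e.g. all weights
#' equal to one reproducing life expectancy) hold to tight absolute
#' tolerance regardless of table length.
#'
#' @param x numeric vector.
#' @return The sum as a length-one double.
#' @keywords internal
kahan_sum <- function(x) {
  s <- 0
  c <- 0
  for (v in x) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}

#' Coefficient of variation in percent
#'
#' V = 100 * SD / mean. The rounded integer form is the conventional way
#' dispersion of summary measures of population health is reported across
#' countries.
#'
#' @param mean arithmetic mean.
#' @param sd standard deviation (n - 1 denominator).
#' @return Unrounded coefficient of variation in percent.
#' @examples
#' variation_coefficient(17.7, 6.6)  # ~37.3
#' @export
variation_coefficient <- function(mean, sd) {
  if (any(mean == 0)) stop("variation coefficient undefined for zero mean")
  100 * sd / mean
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
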