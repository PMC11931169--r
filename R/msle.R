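#' Mean squared logarithmic error
#'
#' The reconstruction score
#' \deqn{S(\hat x, x) = \frac{1}{N}\sum_{i=1}^{N}
#'   \left(\log(|\hat x[i]| + 1) - \log(|x[i]| + 1)\right)^2}
#' with natural logarithms. The absolute value and the added one keep the
#' logarithm defined for signed microvolt samples; the log transform makes
#' the score robust to amplitude fluctuations, which is why it is preferred
#' over a plain mean squared error for extracellular waveforms.
#'
#' @param x,xhat numeric vectors of equal length (the order of arguments
#'   does not matter; the score is symmetric and sign-insensitive).
#' @return non-negative scalar.
#' @examples
#' msle(c(0), c(exp(1) - 1))  # exactly 1
#' msle(c(3, -3), c(-3, 3))   # 0: only magnitudes enter
#' @export
msle <- function(x, xhat) {
  if (length(x) != length(xhat))
    stop("'x' and 'xhat' must have the same length")
  if (length(x) < 1) stop("empty input")
  if (!all(is.finite(x)) || !all(is.finite(xhat)))
    stop("inputs must be finite")
  mean((log1p(abs(xhat)) - log1p(abs(x)))^2)
}

## row-wise MSLE between a matrix of inputs and their reconstructions
msle_rows <- function(x, xhat) {
  rowMeans((log1p(abs(xhat)) - log1p(abs(x)))^2)
}
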