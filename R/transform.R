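#' Convert beta-values to M-values
#'
#' The M-value is the logit2 transform `M = log2(beta / (1 - beta))`.
#' M-values are approximately homoscedastic and are the scale on which all
#' statistical tests in this package operate; beta-values are kept for
#' effect sizes and presentation.
#'
#' @param beta Numeric vector of methylation fractions, strictly in (0, 1).
#' @return Numeric vector of M-values.
#' @seealso [m_to_beta()] for the inverse.
#' @examples
#' beta_to_m(0.5) # 0
#' beta_to_m(0.8) # 2
#' @export
beta_to_m <- function(beta) {
  if (!is.numeric(beta)) stop("`beta` must be numeric")
  bad <- !is.na(beta) & (beta <= 0 | beta >= 1)
  if (any(bad)) {
    stop(sprintf("beta-values must lie strictly in (0, 1); offending value %g",
                 beta[which(bad)[1L]]))
  }
  log2(beta / (1 - beta))
}

#' Convert M-values to beta-values
#'
#' Inverse logit2: `beta = 2^M / (2^M + 1)`. Exact inverse of
#' [beta_to_m()] to floating-point precision.
#'
#' @param m Numeric vector of finite M-values.
#' @return Numeric vector of beta-values in (0, 1).
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) stop("`m` must be numeric")
  if (any(!is.finite(m) & !is.na(m))) stop("M-values must be finite")
  # 1/(1+2^-m) is stable for large |m| in both directions
  1 / (1 + 2^(-m))
}
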