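#' Selection coefficient between two amino-acid fitnesses
#'
#' The selection coefficient of a mutant with Darwinian fitness `f_b`
#' arising on a wild-type background of fitness `f_a` is
#' `s = f_b / f_a - 1`.
#'
#' @param f_a,f_b Strictly positive Darwinian fitnesses (wild type,
#'   mutant).  Vectorised.
#' @return Numeric vector of selection coefficients.
#' @examples
#' selection_coefficient(1, 1.00002)   # 2e-5
#' @export
selection_coefficient <- function(f_a, f_b) {
  if (any(f_a <= 0) || any(f_b <= 0))
    stop("fitness values must be strictly positive", call. = FALSE)
  f_b / f_a - 1
}

#' Wright-Fisher fixation probability
#'
#' Probability that a single new mutant with selection coefficient `s`
#' ultimately fixes in a diploid Wright-Fisher population of effective
#' size `N_p`, from the diffusion approximation.  The
#' `"non_reversible"` form evaluates
#' \deqn{P_{fix} = \frac{1 - e^{-2s}}{1 - e^{-4 N_p s}}}
#' directly (no log-linearisation of the numerator), which makes the
#' resulting substitution process non-time-reversible.  The
#' `"reversible"` form is the standard population-scaled approximation
#' \deqn{P_{fix} = \frac{2s}{1 - e^{-4 N_p s}}.}
#' Both are computed through `expm1()` so that `1 - e^{-x}` retains full
#' relative precision for the very small arguments (`x ~ 1e-5`) this
#' model operates at.  For `|s|` below `neutral_eps` the neutral limit
#' `1 / (2 N_p)` is returned exactly.
#'
#' @param s Selection coefficient(s).
#' @param N_p Effective diploid population size (>= 1).
#' @param form `"non_reversible"` (default) or `"reversible"`.
#' @param s_max Largest `|s|` accepted; larger values raise an error
#'   naming the offending coefficient.  Default `5e-4` comfortably covers
#'   fitness profiles drawn within 1 +/- 5e-5.
#' @param neutral_eps Threshold below which `|s|` is treated as exactly
#'   neutral (the expression is 0/0 at s = 0).
#' @return Fixation probabilities in (0, 1].
#' @examples
#' fixation_probability(0, 1e5)        # 5e-6 = 1/(2 N_p)
#' fixation_probability(1e-5, 1e5)     # ~2.0373e-5
#' @export
fixation_probability <- function(s, N_p,
                                 form = c("non_reversible", "reversible"),
                                 s_max = 5e-4, neutral_eps = 1e-12) {
  form <- match.arg(form)
  if (N_p < 1) stop("N_p must be >= 1", call. = FALSE)
  bad <- which(abs(s) > s_max)
  if (length(bad))
    stop(sprintf(
      "selection coefficient s = %.6g outside supported range |s| <= %g",
      s[bad[1]], s_max), call. = FALSE)
  out <- numeric(length(s))
  neu <- abs(s) < neutral_eps
  out[neu] <- 1 / (2 * N_p)
  if (any(!neu)) {
    sn <- s[!neu]
    denom <- expm1(-4 * N_p * sn)          # -(1 - e^{-4 N_p s})
    num <- if (form == "non_reversible") expm1(-2 * sn) else -2 * sn
    out[!neu] <- num / denom
  }
  out
}
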