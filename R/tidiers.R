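#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a mutation-selection fit
#'
#' One row per estimated parameter: fitnesses by amino acid and model,
#' mutation parameters, and (when present) the 61 root codon
#' frequencies.
#'
#' @param x A `mutsel_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `block`, `model`, `estimate`.
#' @export
tidy.mutsel_fit <- function(x, ...) {
  if (is.null(x$estimates)) return(tibble::tibble(
    term = character(0), block = character(0), model = integer(0),
    estimate = numeric(0)))
  est <- x$estimates
  rows <- list(
    tibble::tibble(term = "kappa", block = "mutation", model = NA_integer_,
                   estimate = est$kappa),
    tibble::tibble(term = paste0("theta_", c("A", "C", "G", "T")),
                   block = "mutation", model = NA_integer_,
                   estimate = est$theta))
  for (m in seq_along(est$profiles))
    rows <- c(rows, list(tibble::tibble(
      term = paste0("f_", amino_acids()),
      block = "fitness", model = m,
      estimate = as.numeric(est$profiles[[m]]))))
  if (!is.null(est$root_frequencies))
    rows <- c(rows, list(tibble::tibble(
      term = paste0("rho_", codon_space()$codons),
      block = "root", model = NA_integer_,
      estimate = est$root_frequencies)))
  dplyr::bind_rows(rows)
}

#' One-row summary of a mutation-selection fit
#'
#' @param x A `mutsel_fit`.
#' @param ... Unused.
#' @return Tibble with `logLik`, `k_params`, `convergence`,
#'   `iterations`.
#' @export
glance.mutsel_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, k_params = x$k_params,
                 convergence = x$convergence, iterations = x$iterations)
}

#' Tidy a shift search (its AICc trace)
#'
#' @param x A `shift_search`.
#' @param ... Unused.
#' @return The trace tibble: one row per tested model.
#' @export
tidy.shift_search <- function(x, ...) x$trace

#' One-row summary of a shift search
#'
#' @param x A `shift_search`.
#' @param ... Unused.
#' @return Tibble with outcome, number of shifts, final and initial
#'   AICc, final log-likelihood.
#' @export
glance.shift_search <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, n_shifts = length(x$shifts),
                 shifts = paste(x$shifts, collapse = ","),
                 aicc = x$aicc, initial_aicc = x$initial_aicc,
                 logLik = x$fit$loglik)
}
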