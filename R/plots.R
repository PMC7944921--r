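#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   labs theme_minimal facet_wrap geom_hline
#' @export
ggplot2::autoplot

#' Plot outcome proportions of a simulation block
#'
#' @param object A `block_summary`.
#' @param ... Unused.
#' @return A ggplot bar chart of outcome proportions.
#' @export
autoplot.block_summary <- function(object, ...) {
  ggplot(object$proportions, aes(x = .data$outcome,
                                 y = .data$proportion)) +
    geom_col(fill = "grey30") +
    labs(x = NULL, y = "proportion of replicates",
         title = "Inference outcomes") +
    theme_minimal()
}

#' Plot the AICc trajectory of a greedy shift search
#'
#' Shows the AICc of every tested model by search step, highlighting
#' accepted models.
#'
#' @param object A `shift_search`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shift_search <- function(object, ...) {
  tr <- object$trace[is.finite(object$trace$aicc), ]
  ggplot(tr, aes(x = .data$step, y = .data$aicc,
                 colour = .data$accepted)) +
    geom_point(alpha = 0.7) +
    labs(x = "search step", y = "AICc",
         title = "Greedy shift-search AICc trace") +
    theme_minimal()
}

#' Bar chart of fitnesses relative to the median amino acid
#'
#' Displays each model's estimated amino-acid fitnesses relative to the
#' median amino-acid fitness of that model, the conventional way of
#' comparing profiles before and after inferred shifts.
#'
#' @param fit A `mutsel_fit` (or any list of profiles via
#'   `fit$estimates$profiles`).
#' @return A ggplot object, one facet per model.
#' @export
plot_fitness_profiles <- function(fit) {
  profs <- fit$estimates$profiles
  rows <- lapply(seq_along(profs), function(m) {
    f <- as.numeric(profs[[m]])
    tibble::tibble(model = paste("model", m), aa = amino_acids(),
                   rel = f - median(f))
  })
  dat <- dplyr::bind_rows(rows)
  ggplot(dat, aes(x = .data$aa, y = .data$rel)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    facet_wrap(~model, ncol = 1) +
    labs(x = "amino acid", y = "fitness relative to model median") +
    theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
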