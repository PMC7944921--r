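#' Corrected Akaike Information Criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1) / (n - k - 1)` with `n` the number of
#' alignment columns (codon sites), the sample size the likelihood
#' actually sees.
#'
#' @param logL Maximised log-likelihood.
#' @param k_params Number of free parameters.
#' @param n Sample size (codon columns); must exceed `k_params + 1`.
#' @return The AICc value.
#' @examples
#' aicc(-1000, 24, 300)   # 2048 + 1200/275
#' @export
aicc <- function(logL, k_params, n) {
  if (n <= k_params + 1)
    stop(sprintf(
      "AICc undefined: need n > k + 1 (k = %d requires at least n = %d codon columns)",
      k_params, k_params + 2), call. = FALSE)
  -2 * logL + 2 * k_params + 2 * k_params * (k_params + 1) / (n - k_params - 1)
}

#' Settings for the greedy shift search
#'
#' @param fixation_form Fixation-probability form for all models.
#' @param root_mode `"equilibrium"` (root codon frequencies equal the
#'   root model's stationary distribution) or `"free"` (60 extra free
#'   parameters, profiled by EM).
#' @param free_kappa,free_theta Estimate the mutation parameters.
#' @param N_p Effective population size.
#' @param s_max Selection-coefficient ceiling.
#' @param refit_scope After a branch is accepted, `"full"` re-optimises
#'   every free parameter of the augmented model jointly; `"frequencies"`
#'   re-optimises only the frequency-type parameters (kappa, theta, root
#'   frequencies), keeping fitness profiles at their current values.
#' @param full Optimiser settings ([fit_settings()]) for the initial fit.
#' @param refit Optimiser settings for the joint re-optimisation after a
#'   branch is selected; warm-started from the incumbent estimates, so a
#'   smaller initial trust region is the default.
#' @param candidate Optimiser settings for the per-branch provisional
#'   fits (19 parameters, everything else frozen); these only need to
#'   rank branches, so looser tolerances are the default.
#' @param penalty_multiplier Multiplies the AICc penalty term (testing
#'   hook; 1 = standard AICc).
#' @return A list of class `search_settings`.
#' @export
search_settings <- function(fixation_form = "non_reversible",
                            root_mode = c("equilibrium", "free"),
                            free_kappa = TRUE, free_theta = TRUE,
                            N_p = 1e5, s_max = 5e-4,
                            refit_scope = c("full", "frequencies"),
                            full = fit_settings(maxfun = 2500,
                                                rhoend = 3e-3),
                            refit = fit_settings(maxfun = 2000,
                                                 rhobeg = 0.4,
                                                 rhoend = 4e-3,
                                                 polish_sweeps = 2),
                            candidate = fit_settings(maxfun = 350,
                                                     rhoend = 0.06),
                            penalty_multiplier = 1) {
  structure(list(fixation_form = fixation_form,
                 root_mode = match.arg(root_mode),
                 free_kappa = free_kappa, free_theta = free_theta,
                 N_p = N_p, s_max = s_max,
                 refit_scope = match.arg(refit_scope),
                 full = full, refit = refit, candidate = candidate,
                 penalty_multiplier = penalty_multiplier),
            class = "search_settings")
}

pen_aicc <- function(logL, k, n, mult) {
  -2 * logL + mult * (2 * k + 2 * k * (k + 1) / (n - k - 1))
}

#' Greedy AICc-guided search for selective shifts
#'
#' Infers the number and branch positions of sequence-wide shifts in the
#' amino-acid fitness profile on a fixed rooted phylogeny.  The
#' shift-free model is fitted first; then, at each round, every eligible
#' branch receives a provisional shift whose 19 new fitnesses are
#' estimated with all other aspects of the model frozen, the branch with
#' the lowest provisional AICc is selected, all free parameters of the
#' augmented model are re-optimised, and the shift is accepted if and
#' only if the re-optimised AICc improves on the incumbent.  The search
#' stops at the first rejection or when `max_shifts` is reached.
#' Branches already carrying a shift are not candidates, and a shift is
#' never proposed on the second basal branch when the other basal branch
#' already carries one (the process present at the root must survive on
#' at least one side).  Per-branch optimisation failures are recorded
#' and excluded from selection; if every candidate fails the outcome is
#' `"optimisation_failure"`.
#'
#' @param alignment A [codon_alignment()].
#' @param tree Rooted binary `phylo` matching the alignment's taxa.
#' @param max_shifts Maximum number of change points (>= 0).
#' @param settings A [search_settings()].
#' @return An object of class `shift_search`: `shifts` (branch ids =
#'   child nodes, in acceptance order), `config` and `fit` for the final
#'   accepted model, `aicc`, `outcome` (`"no_shift"`, `"shifts_found"`
#'   or `"optimisation_failure"`), and `trace`, a tibble with one row
#'   per tested model (step, stage, branch, logL, k_params, AICc,
#'   accepted, failed).
#' @export
greedy_shift_search <- function(alignment, tree, max_shifts = 2,
                                settings = search_settings()) {
  stopifnot(max_shifts >= 0)
  n <- ncol(alignment)
  mut <- mutation_params(kappa = 2, theta = rep(0.25, 4), N_p = settings$N_p)
  root0 <- if (settings$root_mode == "free") rep(1 / 61, 61) else "equilibrium"
  config <- shift_configuration(fitness_profile(), list(), root0)
  engine <- likelihood_engine(tree, alignment, config, mut,
                              settings$fixation_form, settings$s_max)
  free_root <- settings$root_mode == "free"
  trace <- list()
  add_row <- function(step, stage, branch, logL, k, acc, failed) {
    trace[[length(trace) + 1L]] <<- tibble::tibble(
      step = step, stage = stage, branch = branch, logL = logL,
      k_params = k,
      aicc = if (is.finite(logL))
        pen_aicc(logL, k, n, settings$penalty_multiplier) else NA_real_,
      accepted = acc, failed = failed)
  }

  incumbent <- fit(engine, free_kappa = settings$free_kappa,
                   free_theta = settings$free_theta, free_root = free_root,
                   settings = settings$full)
  if (incumbent$failed) {
    add_row(0L, "initial", NA_integer_, -Inf, incumbent$k_params, FALSE, TRUE)
    return(new_shift_search(integer(0), config, incumbent, NA_real_,
                            NA_real_, "optimisation_failure",
                            dplyr::bind_rows(trace), n, settings))
  }
  k_inc <- incumbent$k_params
  aicc_inc <- pen_aicc(incumbent$loglik, k_inc, n,
                       settings$penalty_multiplier)
  aicc_init <- aicc_inc
  add_row(0L, "initial", NA_integer_, incumbent$loglik, k_inc, TRUE, FALSE)

  shifts_accepted <- integer(0)
  step <- 0L
  while (length(shifts_accepted) < max_shifts) {
    step <- step + 1L
    # refresh engine at incumbent configuration / estimates
    engine <- likelihood_engine(tree, alignment, config, mut,
                                settings$fixation_form, settings$s_max)
    est <- incumbent$estimates
    rho_inc <- if (free_root) est$root_frequencies else NULL
    ev <- ms_eval(engine, est$kappa, est$theta,
                  lapply(est$profiles, as.numeric),
                  root = rho_inc, detail = TRUE)

    cands <- candidate_branches(engine)
    k_aug <- k_inc + 19L
    best <- NULL
    for (ce in cands) {
      pv <- fit_candidate_shift(engine, ev, ce, settings$candidate,
                                est$kappa, est$theta)
      bid <- engine$edge[ce, 2]
      add_row(step, "provisional", bid, pv$loglik, k_aug, FALSE, pv$failed)
      if (pv$failed) next
      a <- pen_aicc(pv$loglik, k_aug, n, settings$penalty_multiplier)
      if (is.null(best) || a < best$aicc - 1e-12 ||
          (abs(a - best$aicc) <= 1e-12 && bid < best$branch)) {
        best <- list(edge = ce, branch = bid, aicc = a, profile = pv$profile)
      }
    }
    if (is.null(best)) {
      return(new_shift_search(shifts_accepted, config, incumbent,
                              aicc_inc, aicc_init, "optimisation_failure",
                              dplyr::bind_rows(trace), n, settings))
    }

    aug_config <- shift_configuration(
      config$base_profile,
      c(config$shifts, list(list(branch = best$branch,
                                 profile = best$profile))),
      config$root_frequencies)
    aug_engine <- likelihood_engine(tree, alignment, aug_config, mut,
                                    settings$fixation_form, settings$s_max)
    M_aug <- length(shifts_accepted) + 2L
    starts <- list(kappa = est$kappa, theta = est$theta,
                   profiles = c(lapply(est$profiles, as.numeric),
                                list(as.numeric(best$profile))),
                   root = rho_inc)
    free_prof <- if (settings$refit_scope == "full") seq_len(M_aug)
                 else integer(0)
    refit <- fit(aug_engine, free_profiles = free_prof,
                 free_kappa = settings$free_kappa,
                 free_theta = settings$free_theta, free_root = free_root,
                 starts = starts, settings = settings$refit)
    # the counting rule always includes every profile of the augmented model
    k_new <- count_k_params(seq_len(M_aug), settings$free_kappa,
                            settings$free_theta, free_root)
    if (refit$failed) {
      add_row(step, "refit", best$branch, -Inf, k_new, FALSE, TRUE)
      return(new_shift_search(shifts_accepted, config, incumbent,
                              aicc_inc, aicc_init, "optimisation_failure",
                              dplyr::bind_rows(trace), n, settings))
    }
    aicc_new <- pen_aicc(refit$loglik, k_new, n,
                         settings$penalty_multiplier)
    accept <- aicc_new < aicc_inc
    add_row(step, "refit", best$branch, refit$loglik, k_new, accept, FALSE)
    if (!accept) break
    shifts_accepted <- c(shifts_accepted, best$branch)
    config <- aug_config
    if (settings$refit_scope == "frequencies") {
      # keep profiles from provisional stage; merge frequency refit
      refit$estimates$profiles <- starts$profiles
    }
    refit$k_params <- k_new
    incumbent <- refit
    k_inc <- k_new
    aicc_inc <- aicc_new
  }

  # deterministic refinement of the accepted model's reported estimates
  # (identifiable coordinates only; can only improve the likelihood)
  if (max_shifts > 0 && !incumbent$failed &&
      !is.null(incumbent$estimates)) {
    engine <- likelihood_engine(tree, alignment, config, mut,
                                settings$fixation_form, settings$s_max)
    est <- incumbent$estimates
    pol <- fit(engine, free_kappa = settings$free_kappa,
               free_theta = settings$free_theta, free_root = free_root,
               starts = list(kappa = est$kappa, theta = est$theta,
                             profiles = lapply(est$profiles, as.numeric),
                             root = est$root_frequencies),
               settings = settings$refit, local = TRUE)
    if (!pol$failed && pol$loglik >= incumbent$loglik) {
      incumbent$estimates <- pol$estimates
      incumbent$loglik <- pol$loglik
      aicc_inc <- pen_aicc(pol$loglik, k_inc, n,
                           settings$penalty_multiplier)
      add_row(step, "polish", NA_integer_, pol$loglik, k_inc, TRUE, FALSE)
    }
  }

  outcome <- if (length(shifts_accepted)) "shifts_found" else "no_shift"
  new_shift_search(shifts_accepted, config, incumbent, aicc_inc,
                   aicc_init, outcome, dplyr::bind_rows(trace), n,
                   settings)
}

candidate_branches <- function(engine) {
  edge <- engine$edge
  shift_br <- vapply(engine$config$shifts,
                     function(s) as.integer(s$branch), integer(1))
  basal <- edge[edge[, 1] == engine$root, 2]
  excl <- shift_br
  if (any(basal %in% shift_br))
    excl <- c(excl, basal)            # other basal branch also barred
  which(!(edge[, 2] %in% excl))
}

new_shift_search <- function(shifts, config, fit, aicc, aicc_init,
                             outcome, trace, n, settings) {
  structure(list(shifts = shifts, config = config, fit = fit,
                 aicc = aicc, initial_aicc = aicc_init,
                 outcome = outcome, trace = trace, n = n,
                 settings = settings),
            class = "shift_search")
}

#' @export
print.shift_search <- function(x, ...) {
  cat("Greedy AICc shift search\n")
  cat("  outcome:", x$outcome, "\n")
  cat("  accepted shift branches:",
      if (length(x$shifts)) paste(x$shifts, collapse = ", ") else "(none)",
      "\n")
  cat(sprintf("  AICc: %.3f (initial %.3f)\n", x$aicc, x$initial_aicc))
  invisible(x)
}

#' Classify a search result against simulation truth
#'
#' Maps an inferred shift set and the known true shift branches to the
#' outcome categories used when scoring simulation studies.  With a
#' non-empty truth: `"correct_only"`, `"correct_plus_false"`,
#' `"incorrect_only"`, `"optimisation_failure"` or `"none_returned"`;
#' with an empty truth: `"true_negative"` or `"false_positive"` (or
#' `"optimisation_failure"`).
#'
#' @param result A `shift_search` object.
#' @param true_shifts Integer vector of true shift branch ids (child
#'   nodes); may be empty.
#' @return A single outcome string.
#' @export
classify_outcome <- function(result, true_shifts = integer(0)) {
  if (result$outcome == "optimisation_failure")
    return("optimisation_failure")
  inferred <- result$shifts
  if (!length(true_shifts))
    return(if (length(inferred)) "false_positive" else "true_negative")
  if (!length(inferred)) return("none_returned")
  hit <- all(true_shifts %in% inferred)
  extra <- length(setdiff(inferred, true_shifts)) > 0
  if (hit && !extra) "correct_only"
  else if (hit) "correct_plus_false"
  else "incorrect_only"
}
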