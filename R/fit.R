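#' Optimiser and likelihood settings for model fitting
#'
#' @param maxfun Maximum objective evaluations (bounded derivative-free
#'   optimiser, [minqa::bobyqa()]).
#' @param rhobeg,rhoend Initial/final trust-region radii on the internal
#'   parameter scale (fitnesses are optimised as `(f - 1) * 1e5`, kappa
#'   on the log scale, theta as additive log-ratios, so all coordinates
#'   are O(1)).
#' @param band Fitness search box half-width `|f - 1| <= band`.
#' @param em_tol,em_maxit Convergence tolerance / cap for the inner EM
#'   loop that profiles free root frequencies.
#' @param npt Number of bobyqa interpolation points (`NULL` = the
#'   recommended `2 * npar + 1`; smaller values trade model quality for
#'   fewer evaluations).
#' @param polish_delta Probe spacing (internal parameter scale) for the
#'   deterministic coordinate-quadratic refinement (`local = TRUE` fits).
#' @param polish_curv_min Minimum estimated curvature below which a
#'   coordinate is considered unidentifiable and left untouched by the
#'   refinement.
#' @param polish_sweeps Maximum refinement sweeps (stops earlier at a
#'   fixed point).
#' @return A list of class `fit_settings`.
#' @export
fit_settings <- function(maxfun = 4000, rhobeg = 1, rhoend = 1e-3,
                         band = 1e-4, em_tol = 1e-9, em_maxit = 2000,
                         npt = NULL, polish_delta = 0.1,
                         polish_curv_min = 0.05, polish_sweeps = 12) {
  structure(list(maxfun = maxfun, rhobeg = rhobeg, rhoend = rhoend,
                 band = band, em_tol = em_tol, em_maxit = em_maxit,
                 npt = npt, polish_delta = polish_delta,
                 polish_curv_min = polish_curv_min,
                 polish_sweeps = polish_sweeps),
            class = "fit_settings")
}

# Deterministic cyclic coordinate-quadratic refinement.  For each
# coordinate a local quadratic is fitted through three points spaced
# `delta` apart; coordinates whose curvature falls below `curv_min`
# (statistically unidentifiable directions) are left untouched, so two
# refinements started from the same point treat them identically.
ms_polish <- function(fn, x, lower, upper, delta = 0.1, sweeps = 12,
                      curv_min = 0.05, gain_min = 1e-7) {
  f0 <- fn(x)
  for (sw in seq_len(sweeps)) {
    x_before <- x
    for (i in seq_along(x)) {
      d <- min(delta, (upper[i] - lower[i]) / 4)
      xp <- x; xp[i] <- min(x[i] + d, upper[i])
      xm <- x; xm[i] <- max(x[i] - d, lower[i])
      fp <- fn(xp); fm <- fn(xm)
      a <- (fp + fm - 2 * f0) / (d * d)        # 2nd derivative estimate
      b <- (fp - fm) / (2 * d)
      if (!is.finite(a) || a < curv_min) next  # unidentifiable: freeze
      step <- max(min(-b / a, 5 * d), -5 * d)
      xn <- x; xn[i] <- min(max(x[i] + step, lower[i]), upper[i])
      fnew <- fn(xn)
      # require a clear improvement so borderline moves resolve
      # identically across numerically indistinguishable surfaces
      if (fnew < f0 - gain_min) { x <- xn; f0 <- fnew }
      else if (fp < f0 - gain_min) { x <- xp; f0 <- fp }
      else if (fm < f0 - gain_min) { x <- xm; f0 <- fm }
    }
    if (max(abs(x - x_before)) < 1e-8) break   # fixed point reached
  }
  list(par = x, value = f0)
}

bobyqa_control <- function(settings, npar) {
  ctl <- list(rhobeg = settings$rhobeg, rhoend = settings$rhoend,
              maxfun = settings$maxfun, iprint = 0)
  if (!is.null(settings$npt))
    ctl$npt <- max(npar + 2, min(settings$npt, (npar + 1) * (npar + 2) / 2))
  ctl
}

FIT_FSCALE <- 1e5  # internal fitness coordinate: g = (f - 1) * FIT_FSCALE

# number of free parameters under a mask (AICc counting rule)
count_k_params <- function(free_profiles, free_kappa, free_theta,
                           free_root) {
  19L * length(free_profiles) + as.integer(free_kappa) +
    3L * as.integer(free_theta) + 60L * as.integer(free_root)
}

#' Maximum-likelihood fit of a branch-heterogeneous model
#'
#' Maximises the pruning log-likelihood of `engine` over the selected
#' parameters by bounded derivative-free optimisation
#' ([minqa::bobyqa()]).  Fitness profiles are searched inside the band
#' `|f - 1| <= band` on a rescaled coordinate, `kappa` on the log scale
#' and `theta` through an additive log-ratio transform; free root
#' frequencies (when the configuration is in free-root mode and
#' `free_root = TRUE`) are profiled out exactly at every objective
#' evaluation by an inner EM loop, so they never enter the outer search
#' yet are counted among the free parameters.  Deterministic given
#' identical starts and settings.
#'
#' @param engine A [likelihood_engine()].
#' @param free_profiles Integer indices of the fitness profiles (1 =
#'   base, `i + 1` = shift `i`) whose 19 free fitnesses are optimised.
#' @param free_kappa,free_theta Optimise the mutation parameters?
#' @param free_root Optimise root frequencies (requires free-root
#'   configuration)?
#' @param starts Optional named list overriding start values
#'   (`kappa`, `theta`, `profiles` = list over all models, `root`).
#'   Defaults: profiles at their configured values (neutral for fresh
#'   configurations), `kappa = 2`, `theta` at observed nucleotide
#'   frequencies, root EM started at observed codon frequencies.
#' @param settings A [fit_settings()].
#' @param local If `TRUE`, replace the global bounded search by a
#'   deterministic cyclic coordinate-quadratic refinement of the start
#'   values, which leaves statistically unidentifiable (flat)
#'   coordinates exactly in place.  Intended for polishing and for
#'   numerical comparisons between model variants, where derivative-free
#'   search noise in flat directions would otherwise dominate the
#'   comparison.
#' @return An object of class `mutsel_fit` with elements `estimates`
#'   (kappa, theta, profiles, root_frequencies), `loglik`, `k_params`,
#'   `convergence`, `iterations`, `trace` (best log-likelihood after
#'   each evaluation), and `failed` (TRUE when no finite likelihood was
#'   found).
#' @export
fit <- function(engine, free_profiles = seq_along(config_profiles(engine$config)),
                free_kappa = TRUE, free_theta = TRUE,
                free_root = is.numeric(engine$config$root_frequencies),
                starts = NULL, settings = fit_settings(),
                local = FALSE) {
  cfg <- engine$config
  root_is_free <- is.numeric(cfg$root_frequencies)
  if (free_root && !root_is_free)
    stop("free_root = TRUE requires a configuration in free-root mode",
         call. = FALSE)
  profiles0 <- lapply(config_profiles(cfg), as.numeric)
  M <- length(profiles0)
  stopifnot(all(free_profiles %in% seq_len(M)))

  band <- settings$band
  kappa0 <- if (!is.null(starts$kappa)) starts$kappa
            else if (free_kappa) 2 else engine$mutation$kappa
  theta0 <- if (!is.null(starts$theta)) starts$theta
            else if (free_theta) engine$theta_obs else engine$mutation$theta
  if (!is.null(starts$profiles)) profiles0 <- lapply(starts$profiles, as.numeric)
  root0 <- if (!is.null(starts$root)) starts$root
           else if (root_is_free && free_root) engine$codon_freq_obs
           else if (root_is_free) cfg$root_frequencies else NULL

  # parameter vector layout
  lower <- upper <- par0 <- numeric(0)
  blocks <- list()
  for (m in free_profiles) {
    par0 <- c(par0, (profiles0[[m]][1:19] - 1) * FIT_FSCALE)
    lower <- c(lower, rep(-band * FIT_FSCALE, 19))
    upper <- c(upper, rep(band * FIT_FSCALE, 19))
    blocks <- c(blocks, list(list(kind = "profile", m = m)))
  }
  if (free_kappa) {
    par0 <- c(par0, log(kappa0))
    lower <- c(lower, log(0.05)); upper <- c(upper, log(50))
    blocks <- c(blocks, list(list(kind = "kappa")))
  }
  if (free_theta) {
    par0 <- c(par0, log(theta0[1:3] / theta0[4]))
    lower <- c(lower, rep(-8, 3)); upper <- c(upper, rep(8, 3))
    blocks <- c(blocks, list(list(kind = "theta")))
  }

  state <- new.env(parent = emptyenv())
  state$best <- -Inf
  state$trace <- numeric(0)
  state$rho <- root0
  state$evals <- 0L

  unpack <- function(x) {
    kap <- kappa0; th <- theta0; prof <- profiles0
    off <- 0L
    for (b in blocks) {
      if (b$kind == "profile") {
        prof[[b$m]][1:19] <- 1 + x[off + 1:19] / FIT_FSCALE
        off <- off + 19L
      } else if (b$kind == "kappa") {
        kap <- exp(x[off + 1L]); off <- off + 1L
      } else {
        z <- exp(c(x[off + 1:3], 0)); th <- z / sum(z); off <- off + 3L
      }
    }
    list(kappa = kap, theta = th, profiles = prof)
  }

  profiled <- root_is_free && free_root
  objective <- function(x) {
    p <- unpack(x)
    val <- tryCatch({
      ev <- ms_eval(engine, p$kappa, p$theta, p$profiles,
                    root = if (profiled) NULL else root0)
      if (profiled) {
        em <- ms_root_em(ev$L_root, ev$logsc_root, engine$weights,
                         state$rho, tol = settings$em_tol,
                         maxit = settings$em_maxit)
        state$last_rho <- em$rho
        em$loglik
      } else ev$loglik
    }, error = function(e) -Inf)
    state$evals <- state$evals + 1L
    if (is.finite(val) && val > state$best) {
      state$best <- val
      if (profiled) state$rho <- state$last_rho
      state$best_x <- x
    }
    state$trace <- c(state$trace, state$best)
    if (!is.finite(val)) return(1e12)
    -val
  }

  convergence <- TRUE
  if (length(par0)) {
    if (local) {
      opt <- tryCatch(
        ms_polish(objective, par0, lower, upper,
                  delta = settings$polish_delta,
                  curv_min = settings$polish_curv_min,
                  sweeps = settings$polish_sweeps),
        error = function(e) NULL)
      convergence <- !is.null(opt)
    } else {
      opt <- tryCatch(
        suppressWarnings(      # advisory maxfun note; budget is deliberate
          minqa::bobyqa(par0, objective, lower = lower, upper = upper,
                        control = bobyqa_control(settings, length(par0)))),
        error = function(e) NULL)
      convergence <- !is.null(opt) && opt$ierr == 0
    }
    if (!is.finite(state$best)) {
      # no finite likelihood found anywhere
      return(structure(list(
        estimates = NULL, loglik = -Inf,
        k_params = count_k_params(free_profiles, free_kappa, free_theta,
                                  profiled),
        convergence = FALSE, iterations = state$evals,
        trace = state$trace, failed = TRUE), class = "mutsel_fit"))
    }
    best <- unpack(state$best_x)
  } else {
    val <- -objective(numeric(0))
    best <- list(kappa = kappa0, theta = theta0, profiles = profiles0)
    state$best <- val
    state$evals <- 0L
  }

  rho_hat <- if (profiled) state$rho
             else if (root_is_free) root0 else NULL
  structure(list(
    estimates = list(kappa = best$kappa, theta = best$theta,
                     profiles = lapply(best$profiles, fitness_profile,
                                       band = band * (1 + 1e-9)),
                     root_frequencies = rho_hat),
    loglik = state$best,
    k_params = count_k_params(free_profiles, free_kappa, free_theta,
                              profiled),
    convergence = convergence,
    iterations = state$evals,
    trace = state$trace,
    failed = FALSE
  ), class = "mutsel_fit")
}

#' Co-estimate free root frequencies with the other parameters
#'
#' Convenience wrapper around [fit()] with `free_root = TRUE`; the
#' engine's configuration must be in free-root mode.  Supports the
#' non-equilibrium inference variant in which 60 free root codon
#' frequencies are estimated jointly with fitnesses and mutation
#' parameters.
#'
#' @inheritParams fit
#' @return A `mutsel_fit`; see [fit()].
#' @export
fit_root_frequencies <- function(engine, settings = fit_settings(), ...) {
  fit(engine, free_root = TRUE, settings = settings, ...)
}

#' Compare fitness estimates under the two fixation-probability forms
#'
#' Fits the equilibrium-root model under the non-reversible (diffusion)
#' fixation probability, then refines the shared optimum under each of
#' the two forms by the deterministic identifiable-coordinate
#' refinement ([fit()] with `local = TRUE`) and reports the largest
#' absolute difference between the resulting fitness estimates.  On one
#' finite alignment many fitness parameters carry little or no
#' statistical information (amino acids that rarely or never occur);
#' independently optimised estimates differ in those directions by
#' optimiser noise, not by anything the fixation form does.  The shared
#' warm start and the curvature threshold confine the comparison to
#' directions the data actually identify, which is the quantity of
#' scientific interest: whether the diffusion and linearised fixation
#' probabilities are numerically distinguishable from data.
#'
#' @param tree Rooted binary `phylo`.
#' @param alignment A [codon_alignment()].
#' @param mutation Treewide [mutation_params()].
#' @param settings Optimiser settings for the initial global fit.
#' @param curv_min Identifiability (curvature) threshold for the
#'   refinement stage.
#' @return A list: `fit_non_reversible`, `fit_reversible` (both
#'   `mutsel_fit`), `max_abs_difference` (over the 20 fitnesses),
#'   `loglik_difference`.
#' @export
compare_fixation_forms <- function(tree, alignment,
                                   mutation = mutation_params(),
                                   settings = fit_settings(),
                                   curv_min = 0.5) {
  cfg0 <- shift_configuration(fitness_profile(), list(), "equilibrium")
  engN <- likelihood_engine(tree, alignment, cfg0, mutation,
                            "non_reversible")
  engR <- likelihood_engine(tree, alignment, cfg0, mutation,
                            "reversible")
  fN0 <- fit(engN, settings = settings)
  warm <- list(kappa = fN0$estimates$kappa, theta = fN0$estimates$theta,
               profiles = list(as.numeric(fN0$estimates$profiles[[1]])))
  loc <- fit_settings(band = settings$band, polish_curv_min = curv_min)
  fN <- fit(engN, starts = warm, settings = loc, local = TRUE)
  fR <- fit(engR, starts = warm, settings = loc, local = TRUE)
  d <- max(abs(as.numeric(fN$estimates$profiles[[1]]) -
               as.numeric(fR$estimates$profiles[[1]])))
  list(fit_non_reversible = fN, fit_reversible = fR,
       max_abs_difference = d,
       loglik_difference = fN$loglik - fR$loglik)
}

#' @export
print.mutsel_fit <- function(x, ...) {
  cat("Mutation-selection fit\n")
  cat(sprintf("  log-likelihood: %.4f  (free parameters: %d)\n",
              x$loglik, x$k_params))
  if (!is.null(x$estimates))
    cat(sprintf("  kappa = %.4f; theta = %s\n", x$estimates$kappa,
                paste(sprintf("%.4f", x$estimates$theta), collapse = " ")))
  cat(sprintf("  converged: %s after %d evaluations\n",
              x$convergence, x$iterations))
  invisible(x)
}

# ---- provisional candidate-shift fit -------------------------------------

# Outside weights for edge `cand`: D (61 x npat) and its log-scale such
# that site likelihood = colSums(D * (P_cand %*% L_clade)) on the log
# scale logsc_D + logsc_clade.  Uses per-edge M and per-node partials of
# an incumbent detail evaluation (all frozen during the candidate fit).
ms_outside <- function(eng, ev, cand) {
  edge <- eng$edge
  npat <- eng$npat
  path <- integer(0)                       # edges from root down to cand
  e <- cand
  repeat {
    path <- c(e, path)
    par <- edge[e, 1]
    if (par == eng$root) break
    e <- which(edge[, 2] == par)
  }
  O <- matrix(ev$rho, 61, npat)
  logsc <- rep(0, npat)
  for (e in path) {
    v <- edge[e, 1]
    sibs <- setdiff(eng$children_of[[as.character(v)]], e)
    D <- O
    for (sb in sibs) {
      D <- D * ev$M[[sb]]
      chi <- edge[sb, 2]
      if (chi > eng$n_tip) logsc <- logsc + ev$lsc[[chi]]
    }
    if (e == cand) return(list(D = D, logsc = logsc))
    O <- crossprod(ev$P[[e]], D)           # t(P) %*% D
    cs <- .colSums(O, 61, npat)
    O <- O / rep(cs, each = 61)
    logsc <- logsc + log(cs)
  }
}

# edges of the subtree rooted at the child of `cand`, plus cand itself
clade_edges <- function(eng, cand) {
  edge <- eng$edge
  out <- cand
  stack <- edge[cand, 2]
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    kids <- eng$children_of[[as.character(v)]]
    if (!is.null(kids)) {
      out <- c(out, kids)
      stack <- c(stack, edge[kids, 2])
    }
  }
  sort(out)
}

# Provisional fit of a candidate shift on branch `cand`: optimises the
# 19 fitnesses of the prospective new profile with every other aspect of
# the incumbent model frozen (its transition matrices, root frequencies
# and scaling are reused).  Returns the provisional profile and
# log-likelihood of the augmented model.
fit_candidate_shift <- function(eng, ev, cand, settings = fit_settings(),
                                kappa, theta) {
  aug <- shift_configuration(
    eng$config$base_profile,
    c(eng$config$shifts, list(list(branch = eng$edge[cand, 2],
                                   profile = fitness_profile()))),
    eng$config$root_frequencies)
  new_m <- n_shifts(aug) + 1L
  new_assign <- assign_models(eng$tree, aug)
  cl <- clade_edges(eng, cand)
  changed <- cl[new_assign[cl] == new_m]
  out <- ms_outside(eng, ev, cand)

  # clade-internal nodes, children before parents
  sub_nodes <- intersect(eng$post_nodes,
                         unique(eng$edge[setdiff(cl, cand), 1]))
  sub_nodes <- sub_nodes[order(match(sub_nodes, eng$post_nodes))]
  npat <- eng$npat

  obj_state <- new.env(parent = emptyenv())
  obj_state$best <- -Inf
  objective <- function(g) {
    f <- c(1 + g / FIT_FSCALE, 1)
    val <- tryCatch({
      Qn <- ms_q_scaled(eng, kappa, theta, f)
      dec <- ms_decomp(Qn)
      P <- ev$P
      for (e in changed) P[[e]] <- ms_pmat(dec, eng$edge_len[e])
      # prune the clade only
      part <- vector("list", max(eng$edge))
      lsc <- vector("list", max(eng$edge))
      for (v in sub_nodes) {
        kids <- eng$children_of[[as.character(v)]]
        L <- NULL; sc <- rep(0, npat)
        for (e in kids) {
          chi <- eng$edge[e, 2]
          Me <- ms_edge_M(eng, P, part, e)
          if (chi > eng$n_tip) sc <- sc + lsc[[chi]]
          L <- if (is.null(L)) Me else L * Me
        }
        cs <- .colSums(L, 61, npat)
        if (min(cs) < 1e-120) {
          L <- L / rep(cs, each = 61)
          sc <- sc + log(cs)
        }
        part[[v]] <- L
        lsc[[v]] <- sc
      }
      chi <- eng$edge[cand, 2]
      Mb <- ms_edge_M(eng, P, part, cand)
      sc <- if (chi > eng$n_tip) lsc[[chi]] else rep(0, npat)
      lik <- .colSums(out$D * Mb, 61, npat)
      sum(eng$weights * (log(lik) + out$logsc + sc))
    }, error = function(e) -Inf)
    if (is.finite(val) && val > obj_state$best) {
      obj_state$best <- val
      obj_state$best_g <- g
    }
    if (!is.finite(val)) return(1e12)
    -val
  }

  band <- settings$band
  opt <- tryCatch(
    suppressWarnings(
      minqa::bobyqa(rep(0, 19), objective,
                    lower = rep(-band * FIT_FSCALE, 19),
                    upper = rep(band * FIT_FSCALE, 19),
                    control = bobyqa_control(settings, 19L))),
    error = function(e) NULL)
  if (!is.finite(obj_state$best))
    return(list(failed = TRUE, loglik = -Inf, profile = NULL))
  list(failed = FALSE, loglik = obj_state$best,
       profile = fitness_profile(1 + obj_state$best_g / FIT_FSCALE,
                                 band = band * (1 + 1e-9)),
       convergence = !is.null(opt) && opt$ierr == 0)
}
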