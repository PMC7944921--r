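#' Branch-heterogeneous pruning likelihood engine
#'
#' Binds a rooted binary tree, an in-frame codon alignment and a
#' [shift_configuration()] into an object on which the log-likelihood
#' can be evaluated and parameters fitted.  Alignment columns are
#' compressed to unique site patterns; partial likelihoods are rescaled
#' per pattern at every internal node to avoid underflow; every branch
#' is propagated with the transition matrix of its *own* model as
#' resolved by [assign_models()].
#'
#' @param tree Rooted binary `phylo` with branch lengths in
#'   neutral-substitution units.
#' @param alignment A [codon_alignment()]; its taxa must contain every
#'   tip label of `tree`.
#' @param config A [shift_configuration()].
#' @param mutation Treewide [mutation_params()].
#' @param fixation_form `"non_reversible"` or `"reversible"`.
#' @param s_max Supported selection-coefficient ceiling.
#' @return An object of class `likelihood_engine`.
#' @export
likelihood_engine <- function(tree, alignment, config,
                              mutation = mutation_params(),
                              fixation_form = c("non_reversible",
                                                "reversible"),
                              s_max = 5e-4) {
  fixation_form <- match.arg(fixation_form)
  tree <- validate_phylogeny(tree)
  if (!all(tree$tip.label %in% rownames(alignment)))
    stop("alignment is missing taxa present in the tree", call. = FALSE)
  aln <- alignment[tree$tip.label, , drop = FALSE]

  # site-pattern compression
  key <- apply(aln, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.numeric(table(key)[key[first]])
  tippat <- aln[, first, drop = FALSE]

  space <- codon_space()
  nb <- space$neighbors
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  children_of <- split(seq_len(nrow(edge)), edge[, 1])
  # internal nodes, children strictly before parents (deepest first)
  depths <- node_edge_depths(tree)
  internal <- unique(edge[, 1])
  post_nodes <- internal[order(depths[internal], decreasing = TRUE)]

  # observed frequencies (fitting start values)
  codons_obs <- table(factor(tippat[!is.na(tippat)], levels = 1:61))
  codon_freq_obs <- as.numeric(codons_obs + 0.5)
  codon_freq_obs <- codon_freq_obs / sum(codon_freq_obs)
  base_count <- numeric(4)
  cmat <- do.call(rbind, strsplit(space$codons, ""))
  for (p in 1:3) {
    tb <- table(factor(cmat[tippat[!is.na(tippat)], p],
                       levels = c("A", "C", "G", "T")))
    base_count <- base_count + as.numeric(tb)
  }
  theta_obs <- (base_count + 0.5) / sum(base_count + 2)

  structure(list(
    tree = tree, alignment = aln, config = config, mutation = mutation,
    fixation_form = fixation_form, s_max = s_max,
    space = space, nb = nb,
    n_tip = n_tip, edge = edge, edge_len = tree$edge.length,
    children_of = children_of, post_nodes = post_nodes,
    root = n_tip + 1L,
    tippat = tippat, weights = w, npat = ncol(tippat),
    tipidx = {
      ti <- tippat; ti[is.na(ti)] <- 1L; ti
    },
    tipna = lapply(seq_len(n_tip), function(k) {
      nas <- which(is.na(tippat[k, ]))
      if (length(nas)) nas else NULL
    }),
    n_sites = ncol(alignment),
    assign = assign_models(tree, config),
    pos_base = matrix(match(do.call(rbind, strsplit(space$codons, "")),
                            c("A", "C", "G", "T")), 61, 3),
    theta_obs = theta_obs, codon_freq_obs = codon_freq_obs
  ), class = "likelihood_engine")
}

# ---- fast internal model algebra (no class validation in hot loops) ----

# scaled generator for one fitness profile given mutation parameters
ms_q_scaled <- function(eng, kappa, theta, f) {
  nb <- eng$nb
  mp <- eng$mutation
  s <- f[eng$space$aa[nb$j]] / f[eng$space$aa[nb$i]] - 1
  pfix <- fixation_probability(s, mp$N_p, eng$fixation_form,
                               s_max = eng$s_max)
  mut <- theta[nb$target]                 # HKY inflow (mu = 1)
  mut[nb$ti] <- mut[nb$ti] * kappa
  rate <- 2 * mp$N_p * mut * pfix
  # neutral expected rate under the neutral counterpart's stationary dist
  pi0 <- ms_pi0(eng, theta)
  r0 <- sum(pi0[nb$i] * mut)
  Q <- matrix(0, 61, 61)
  Q[cbind(nb$i, nb$j)] <- rate / r0
  diag(Q) <- -rowSums(Q)
  Q
}

ms_pi0 <- function(eng, theta) {
  pb <- eng$pos_base
  if (is.null(pb)) {
    cmat <- do.call(rbind, strsplit(eng$space$codons, ""))
    pb <- matrix(match(cmat, c("A", "C", "G", "T")), 61, 3)
  }
  w <- theta[pb[, 1]] * theta[pb[, 2]] * theta[pb[, 3]]
  w / sum(w)
}

# eigendecomposition with quality check; fall back to Pade per branch
ms_decomp <- function(Q) {
  e <- tryCatch(eigen(Q), error = function(err) NULL)
  if (!is.null(e)) {
    Vinv <- tryCatch(solve(e$vectors), error = function(err) NULL)
    if (!is.null(Vinv)) {
      err <- max(Mod(e$vectors %*% (e$values * Vinv) - Q))
      if (is.finite(err) && err < 1e-8 * max(1, max(abs(Q))))
        return(list(ok = TRUE, V = e$vectors, d = e$values, Vinv = Vinv,
                    Q = Q))
    }
  }
  list(ok = FALSE, Q = Q)
}

ms_pmat <- function(dec, t) {
  if (t == 0) return(diag(61))
  if (dec$ok) {
    P <- Re(dec$V %*% (exp(dec$d * t) * dec$Vinv))
    P[P < 0] <- 0
    return(P)
  }
  transition_probabilities(dec$Q, t)
}

# full pruning pass.  profiles: list of 20-vectors, one per model index.
# root: NULL = equilibrium of model 1, else a 61-vector.
# detail: also return per-node partials/log-scales and per-edge M for the
# outside (weights) pass used by provisional shift fits.
ms_eval <- function(eng, kappa, theta, profiles, root = NULL,
                    detail = FALSE) {
  Qs <- lapply(profiles, function(f)
    ms_q_scaled(eng, kappa, theta, as.numeric(f)))
  decs <- lapply(Qs, ms_decomp)
  E <- nrow(eng$edge)
  P <- vector("list", E)
  for (e in seq_len(E))
    P[[e]] <- ms_pmat(decs[[eng$assign[e]]], eng$edge_len[e])
  rho <- if (is.null(root)) stationary_distribution(Qs[[1]]) else root
  out <- ms_prune(eng, P, rho, detail = detail)
  out$P <- P
  out$Qs <- Qs
  out$decs <- decs
  out$rho <- rho
  out
}

# edge contribution M_e = P_e %*% L_child (tips resolved by column gather)
ms_edge_M <- function(eng, P, part, e) {
  chi <- eng$edge[e, 2]
  if (chi <= eng$n_tip) {
    Me <- P[[e]][, eng$tipidx[chi, ], drop = FALSE]
    nas <- eng$tipna[[chi]]
    if (!is.null(nas)) Me[, nas] <- 1
    Me
  } else {
    P[[e]] %*% part[[chi]]
  }
}

# pruning given per-edge transition matrices; partials are rescaled per
# pattern only when their column sums drift below `rescale_floor`, so
# shallow trees avoid the rescaling cost entirely
ms_prune <- function(eng, P, rho, detail = FALSE) {
  npat <- eng$npat
  maxn <- max(eng$edge)
  part <- vector("list", maxn)
  lsc <- vector("list", maxn)
  zero <- numeric(npat)
  M <- if (detail) vector("list", nrow(eng$edge)) else NULL
  for (v in eng$post_nodes) {
    kids <- eng$children_of[[as.character(v)]]
    L <- NULL
    sc <- zero
    for (e in kids) {
      chi <- eng$edge[e, 2]
      Me <- ms_edge_M(eng, P, part, e)
      if (chi > eng$n_tip) sc <- sc + lsc[[chi]]
      if (detail) M[[e]] <- Me
      L <- if (is.null(L)) Me else L * Me
    }
    cs <- .colSums(L, 61, npat)
    if (min(cs) < 1e-120) {          # rescale before underflow can bite
      L <- L / rep(cs, each = 61)
      sc <- sc + log(cs)
    }
    part[[v]] <- L
    lsc[[v]] <- sc
  }
  L_root <- part[[eng$root]]
  logsc <- lsc[[eng$root]]
  site_lik <- .colSums(rho * L_root, 61, npat)
  ll <- sum(eng$weights * (log(site_lik) + logsc))
  res <- list(loglik = ll, L_root = L_root, logsc_root = logsc,
              site_lik = site_lik)
  if (detail) {
    res$part <- part
    res$lsc <- lsc
    res$M <- M
  }
  res
}

# EM profiling of free root frequencies: maximises
# sum_s w_s log sum_a rho_a L(a,s) over the simplex.  Concave in rho, so
# EM converges to the global optimum from any interior start.
ms_root_em <- function(L_root, logsc, w, rho0, tol = 1e-9, maxit = 2000) {
  rho <- rho0
  ll_old <- -Inf
  W <- sum(w)
  for (it in seq_len(maxit)) {
    lik <- .colSums(rho * L_root, nrow(L_root), ncol(L_root))
    ll <- sum(w * (log(lik) + logsc))
    resp <- (rho * L_root) %*% (w / lik)       # 61-vector of expected counts
    rho <- as.numeric(resp) / W
    if (ll - ll_old < tol && it > 3) break
    ll_old <- ll
  }
  lik <- .colSums(rho * L_root, nrow(L_root), ncol(L_root))
  list(rho = rho, loglik = sum(w * (log(lik) + logsc)), iterations = it)
}

#' Log-likelihood of an engine at its stored parameters
#'
#' Felsenstein pruning over site patterns, with each branch propagated
#' by its own model's transition matrix and the root handled according
#' to the configuration (equilibrium frequencies of the root model, or
#' the stored free 61-vector).
#'
#' @param engine A [likelihood_engine()].
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(engine) {
  profiles <- lapply(config_profiles(engine$config), as.numeric)
  root <- engine$config$root_frequencies
  if (is.character(root)) root <- NULL
  ms_eval(engine, engine$mutation$kappa, engine$mutation$theta,
          profiles, root = root)$loglik
}
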