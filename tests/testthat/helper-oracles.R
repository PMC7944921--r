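# High-precision reference values for the diffusion fixation
# probability (1 - e^{-2s}) / (1 - e^{-4 N s}) at N = 1e5, evaluated
# with 50-digit interval arithmetic and frozen here to 22 significant
# digits.
PFIX_ORACLE <- data.frame(
  s = c(1e-9, -1e-9, 1e-6, -1e-6, 1e-5, -1e-5, 2e-5, -2e-5,
        5e-5, -5e-5, 1e-4, -1e-4, 2e-4, -2e-4),
  p = c(5.001000061665666425556e-06, 4.999000071665666558888e-06,
        6.066483496953953598513e-06, 4.066493629931747147502e-06,
        2.037294347716161122676e-05, 3.731509387724303184556e-07,
        4.001262275024362855911e-05, 1.342327649738997584215e-08,
        9.999500037276755732741e-05, 2.061256687803588365216e-13,
        1.999800013332666701828e-04, 8.497558238081792097909e-22,
        3.999200106656000853276e-04, 7.220849625028671679944e-39)
)

# Reversible (linearised-numerator) form at the same N, same precision.
PFIX_REV_ORACLE <- data.frame(
  s = c(1e-5, -1e-5, 5e-6, -5e-6),
  p = c(2.037314720727548095878e-05, 3.731472072754809587781e-07,
        1.156517642749665651818e-05, 1.565176427496656518181e-06)
)

# Direct summation over all internal-node state assignments: the
# likelihood oracle for trees with <= 3 leaves (<= 2 internal nodes).
# Independent of the pruning code: only transition matrices, the edge
# table and root frequencies are shared inputs.
enumerate_loglik <- function(tree, aln, P_by_edge, rho) {
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  internal <- sort(unique(edge[, 1]))
  stopifnot(length(internal) <= 2)
  root <- n_tip + 1L
  ll <- 0
  for (s in seq_len(ncol(aln))) {
    states <- rep(list(1:61), length(internal))
    total <- 0
    grid <- do.call(expand.grid, states)
    for (g in seq_len(nrow(grid))) {
      assign_state <- integer(max(edge))
      assign_state[internal] <- as.integer(grid[g, ])
      for (k in seq_len(n_tip)) assign_state[k] <- aln[tree$tip.label[k], s]
      term <- rho[assign_state[root]]
      for (e in seq_len(nrow(edge))) {
        chi <- assign_state[edge[e, 2]]
        if (is.na(chi)) next                     # missing tip: sum over all
        term <- term * P_by_edge[[e]][assign_state[edge[e, 1]], chi]
      }
      total <- total + term
    }
    ll <- ll + log(total)
  }
  unname(ll)
}

# Expected Colless index of a Yule (uniform-split) topology on n tips,
# by direct recursion over the split-size distribution.
yule_colless_expectation <- function(n) {
  memo <- numeric(n)
  memo[1] <- 0
  if (n >= 2) memo[2] <- 0
  for (m in 3:n) {
    tot <- 0
    for (i in 1:(m - 1))
      tot <- tot + abs(m - 2 * i) + memo[i] + memo[m - i]
    memo[m] <- tot / (m - 1)
  }
  memo[n]
}

# chi-squared goodness of fit with low-expectation cells lumped
lumped_chisq_p <- function(obs, prob, min_exp = 5) {
  n <- sum(obs)
  exp_counts <- prob * n
  keep <- exp_counts >= min_exp
  o <- c(obs[keep], sum(obs[!keep]))
  p <- c(prob[keep], sum(prob[!keep]))
  if (sum(!keep) == 0) { o <- obs; p <- prob }
  suppressWarnings(stats::chisq.test(o, p = p / sum(p)))$p.value
}

quiet_fit <- function(...) suppressWarnings(fit(...))

# small shared fixtures
fixture_tree3 <- function() read_newick("((A:0.3,B:0.5):0.2,C:0.4);")

fixture_model <- function(kappa = 1.5, theta = c(0.3, 0.2, 0.3, 0.2),
                          seed = 5, half_width = 5e-5) {
  set.seed(seed)
  mutsel_model(mutation_params(kappa = kappa, theta = theta),
               draw_fitness_profile(half_width))
}
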