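#' Mutation-layer parameters (HKY on nucleotides)
#'
#' Parameters of the treewide mutation process: new mutations enter the
#' population at rate `2 * N_p * mu` per codon position, distributed
#' over single-nucleotide changes according to an HKY model with
#' transition/transversion ratio `kappa` and target-nucleotide
#' frequencies `theta` (A, C, G, T).
#'
#' @param kappa Transition/transversion ratio (> 0).
#' @param theta Nucleotide frequencies A, C, G, T; must sum to 1.
#' @param mu Per-individual mutation rate (> 0).  Cancels out of the
#'   scaled generator, kept for completeness.
#' @param N_p Effective diploid population size, fixed across the tree.
#' @return An object of class `mutation_params`.
#' @export
mutation_params <- function(kappa = 2, theta = rep(0.25, 4), mu = 1,
                            N_p = 1e5) {
  stopifnot(length(kappa) == 1, kappa > 0, length(theta) == 4,
            all(theta > 0), length(mu) == 1, mu > 0, N_p >= 1)
  if (abs(sum(theta) - 1) > 1e-8)
    stop("theta must sum to 1", call. = FALSE)
  structure(list(kappa = kappa, theta = as.numeric(theta) / sum(theta),
                 mu = mu, N_p = N_p),
            class = "mutation_params")
}

#' Amino-acid fitness profile
#'
#' A vector of 20 Darwinian fitnesses indexed by [amino_acids()].  The
#' twentieth (tyrosine, last in alphabetical order) is the anchor, fixed
#' to exactly 1; the remaining 19 are free parameters.  Fitnesses are
#' constrained to a narrow band around 1: the diffusion fixation
#' probability is evaluated without log-linearisation and only small
#' selection coefficients are supported.
#'
#' @param f Numeric vector: either all 20 fitnesses (with `f[20] == 1`)
#'   or the 19 free fitnesses (the anchor is appended).
#' @param band Maximum allowed `|f - 1|` (default 1e-4).
#' @return Numeric vector of length 20, class `fitness_profile`.
#' @export
fitness_profile <- function(f = rep(1, 19), band = 1e-4) {
  f <- as.numeric(f)
  if (length(f) == 19L) f <- c(f, 1)
  if (length(f) != 20L)
    stop("a fitness profile has 19 free entries plus the anchor",
         call. = FALSE)
  if (f[20] != 1)
    stop("the anchored (20th) fitness must equal 1 exactly", call. = FALSE)
  if (any(f <= 0))
    stop("fitness values must be strictly positive", call. = FALSE)
  if (any(abs(f - 1) > band + 1e-15))
    stop(sprintf("|f - 1| exceeds the supported band %g", band),
         call. = FALSE)
  structure(f, class = "fitness_profile", band = band)
}

#' Mutation-selection codon model
#'
#' Couples a mutation layer with one sequence-wide amino-acid fitness
#' profile.  Substitution rates between single-nucleotide codon
#' neighbours are `q_ab = 2 N_p mu * HKY(a -> b) * P_fix(s_ab)` where
#' `s_ab = f_b / f_a - 1` compares the encoded amino acids;
#' non-neighbour rates are zero.
#'
#' @param mutation A [mutation_params()] object.
#' @param fitness A [fitness_profile()].
#' @param fixation_form `"non_reversible"` (diffusion numerator, the
#'   default) or `"reversible"` (standard linearised numerator).
#' @param s_max Supported selection-coefficient ceiling, passed to
#'   [fixation_probability()].
#' @return An object of class `mutsel_model`.
#' @export
mutsel_model <- function(mutation = mutation_params(),
                         fitness = fitness_profile(),
                         fixation_form = c("non_reversible", "reversible"),
                         s_max = 5e-4) {
  fixation_form <- match.arg(fixation_form)
  if (!inherits(mutation, "mutation_params"))
    mutation <- do.call(mutation_params, as.list(mutation))
  if (!inherits(fitness, "fitness_profile")) fitness <- fitness_profile(fitness)
  structure(list(mutation = mutation, fitness = fitness,
                 fixation_form = fixation_form, s_max = s_max),
            class = "mutsel_model")
}

neutral_model <- function(model) {
  mutsel_model(model$mutation, fitness_profile(rep(1, 19)),
               model$fixation_form, s_max = model$s_max)
}

#' Build the 61x61 mutation-selection generator
#'
#' Off-diagonal entries exist only for codon pairs differing at exactly
#' one nucleotide; each equals the mutation inflow
#' `2 N_p mu theta(target) kappa^[transition]` times the fixation
#' probability of the implied amino-acid change (synonymous changes are
#' neutral, `P_fix = 1/(2 N_p)`).  Diagonals make rows sum to zero.
#'
#' @param model A [mutsel_model()].
#' @param space A [codon_space()] (defaults to the cached one).
#' @return 61x61 rate matrix with codon row/column names (unscaled; see
#'   [scale_generator()]).
#' @export
build_generator <- function(model, space = codon_space()) {
  mp <- model$mutation
  f <- as.numeric(model$fitness)
  nb <- space$neighbors
  s <- selection_coefficient(f[space$aa[nb$i]], f[space$aa[nb$j]])
  pfix <- fixation_probability(s, mp$N_p, model$fixation_form,
                               s_max = model$s_max)
  rate <- 2 * mp$N_p * mp$mu * mp$theta[nb$target] *
    ifelse(nb$ti, mp$kappa, 1) * pfix
  Q <- matrix(0, 61, 61, dimnames = list(space$codons, space$codons))
  Q[cbind(nb$i, nb$j)] <- rate
  diag(Q) <- -rowSums(Q)
  Q
}

# Stationary distribution of the neutral (all fitnesses = 1) codon
# chain: HKY positions evolve independently and the chain restricted to
# sense codons stays reversible, so pi is the product of theta over the
# three positions, renormalised over the 61 sense codons.
neutral_stationary <- function(mutation, space = codon_space()) {
  bases <- c("A", "C", "G", "T")
  cmat <- do.call(rbind, strsplit(space$codons, ""))
  w <- mutation$theta[match(cmat[, 1], bases)] *
    mutation$theta[match(cmat[, 2], bases)] *
    mutation$theta[match(cmat[, 3], bases)]
  w / sum(w)
}

#' Scale a generator to neutral-substitution time units
#'
#' Divides the generator by the expected substitution rate of its
#' neutral counterpart (same mutation parameters, all fitnesses 1) at
#' that counterpart's stationary distribution, so that one unit of
#' branch length corresponds to one expected substitution per site under
#' neutrality.  The individual mutation rate `mu` cancels.
#'
#' @param Q Generator from [build_generator()].
#' @param model The [mutsel_model()] that produced `Q`.
#' @param space A [codon_space()].
#' @return The rescaled generator.
#' @export
scale_generator <- function(Q, model, space = codon_space()) {
  r0 <- neutral_rate(model, space)
  if (r0 <= 0) stop("degenerate mutation parameters: zero neutral rate",
                    call. = FALSE)
  Q / r0
}

neutral_rate <- function(model, space = codon_space()) {
  Q0 <- build_generator(neutral_model(model), space)
  pi0 <- neutral_stationary(model$mutation, space)
  sum(pi0 * -diag(Q0))
}

#' Scaled generator for a model (convenience)
#'
#' @inheritParams build_generator
#' @return [build_generator()] output passed through [scale_generator()].
#' @export
generator <- function(model, space = codon_space()) {
  scale_generator(build_generator(model, space), model, space)
}

#' Stationary distribution of a codon generator
#'
#' Solves the left null-vector problem `pi Q = 0`, `sum(pi) = 1` for a
#' general (asymmetric) generator by direct linear solve with one step
#' of iterative refinement; no reversibility shortcut is used.
#'
#' @param Q A proper generator (rows sum to 0) of an irreducible chain.
#' @param tol Maximum residual `max |pi Q|` accepted before erroring.
#' @return Numeric vector of 61 stationary probabilities.
#' @export
stationary_distribution <- function(Q, tol = 1e-9) {
  n <- nrow(Q)
  A <- t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  pi_hat <- tryCatch(solve(A, b), error = function(e)
    stop("generator is numerically singular: ", conditionMessage(e),
         call. = FALSE))
  # one refinement step
  r <- b - A %*% pi_hat
  pi_hat <- pi_hat + solve(A, r)
  pi_hat <- pmax(as.numeric(pi_hat), 0)
  pi_hat <- pi_hat / sum(pi_hat)
  res <- max(abs(pi_hat %*% Q))
  if (!is.finite(res) || res > tol)
    stop(sprintf(
      "stationary solve failed: residual max|pi Q| = %.3g (chain reducible or ill-conditioned)",
      res), call. = FALSE)
  names(pi_hat) <- rownames(Q)
  pi_hat
}

#' Detailed-balance residual of a generator
#'
#' Largest absolute violation of `pi_a q_ab = pi_b q_ba` over all codon
#' pairs; zero (to numerical precision) for time-reversible processes.
#'
#' @param Q Generator matrix.
#' @param pi Stationary distribution; computed from `Q` if missing.
#' @return Scalar, `max |pi_a q_ab - pi_b q_ba|`.
#' @export
detailed_balance_residual <- function(Q, pi = stationary_distribution(Q)) {
  F <- pi * Q            # F[a,b] = pi_a q_ab
  max(abs(F - t(F)))
}

#' Transition probabilities over a branch
#'
#' Computes `exp(Q t)` by scaling-and-squaring Padé approximation
#' (`Matrix::expm`), valid for asymmetric and non-diagonalisable
#' generators.  Entries in `[-1e-14, 0)` are clamped to 0.
#'
#' @param Q Scaled generator.
#' @param t Branch length (>= 0) in neutral-substitution units.
#' @return 61x61 stochastic matrix.
#' @export
transition_probabilities <- function(Q, t) {
  if (length(t) != 1 || !is.finite(t) || t < 0)
    stop("branch length t must be a single finite value >= 0", call. = FALSE)
  if (t == 0) {
    P <- diag(nrow(Q))
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
  P[P < 0 & P > -1e-14] <- 0
  dimnames(P) <- dimnames(Q)
  P
}
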