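make_engine <- function(tree, aln, cfg, kappa = 1.5,
                        theta = c(0.3, 0.2, 0.3, 0.2), form = "non_reversible") {
  likelihood_engine(tree, aln, cfg, mutation_params(kappa = kappa,
                                                    theta = theta), form)
}

test_that("pruning equals dense enumeration on small instances", {
  set.seed(12)
  tr <- fixture_tree3()
  mut <- mutation_params(kappa = 1.5, theta = c(0.3, 0.2, 0.3, 0.2))
  for (rep in 1:4) {
    prof <- draw_fitness_profile()
    cfg <- shift_configuration(prof, list(), "equilibrium")
    aln <- simulate_alignment(tr, cfg, 5, mut)
    eng <- make_engine(tr, aln, cfg)
    Q <- generator(mutsel_model(mut, prof))
    rho <- stationary_distribution(Q)
    P <- lapply(tr$edge.length, function(t) transition_probabilities(Q, t))
    expect_equal(log_likelihood(eng), enumerate_loglik(tr, aln, P, rho),
                 tolerance = 1e-10)
  }
})

test_that("pruning handles branch-heterogeneous models exactly", {
  set.seed(13)
  tr <- fixture_tree3()
  mut <- mutation_params(kappa = 1, theta = rep(0.25, 4))
  base <- draw_fitness_profile()
  shift <- draw_fitness_profile()
  sb <- ape::getMRCA(tr, c("A", "B"))
  cfg <- shift_configuration(base, list(list(branch = sb, profile = shift)),
                             "equilibrium")
  aln <- simulate_alignment(tr, cfg, 5, mut)
  eng <- likelihood_engine(tr, aln, cfg, mut)
  Qb <- generator(mutsel_model(mut, base))
  Qs <- generator(mutsel_model(mut, shift))
  am <- assign_models(tr, cfg)
  P <- lapply(seq_len(nrow(tr$edge)), function(e)
    transition_probabilities(if (am[e] == 2) Qs else Qb, tr$edge.length[e]))
  rho <- stationary_distribution(Qb)
  expect_equal(log_likelihood(eng), enumerate_loglik(tr, aln, P, rho),
               tolerance = 1e-10)
})

test_that("free-root mode and missing data enter the root sum correctly", {
  set.seed(14)
  tr <- read_newick("(A:0.4,B:0.6);")
  mut <- mutation_params(kappa = 2, theta = c(0.4, 0.1, 0.3, 0.2))
  prof <- draw_fitness_profile()
  rho <- draw_root_frequencies()
  cfg <- shift_configuration(prof, list(), rho)
  aln <- simulate_alignment(tr, cfg, 6, mut)
  aln[2, 3] <- NA                                # B missing at site 3
  aln <- codon_alignment(aln)
  eng <- likelihood_engine(tr, aln, cfg, mut)
  Q <- generator(mutsel_model(mut, prof))
  P <- lapply(tr$edge.length, function(t) transition_probabilities(Q, t))
  expect_equal(log_likelihood(eng), enumerate_loglik(tr, aln, P, rho),
               tolerance = 1e-10)
  # a zero-length branch to a known codon reduces to log rho[c]
  tr0 <- read_newick("(A:0,B:0.5);")
  aln0 <- codon_alignment(matrix(c(17L, NA), nrow = 2, ncol = 1),
                          taxa = c("A", "B"))
  eng0 <- likelihood_engine(tr0, aln0, cfg, mut)
  expect_equal(log_likelihood(eng0), log(rho[17]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("duplicating every column doubles the log-likelihood", {
  set.seed(15)
  tr <- fixture_tree3()
  cfg <- shift_configuration(draw_fitness_profile(), list(), "equilibrium")
  mut <- mutation_params(kappa = 1)
  aln <- simulate_alignment(tr, cfg, 20, mut)
  aln2 <- codon_alignment(cbind(aln, aln), taxa = rownames(aln))
  e1 <- likelihood_engine(tr, aln, cfg, mut)
  e2 <- likelihood_engine(tr, aln2, cfg, mut)
  expect_equal(2 * log_likelihood(e1), log_likelihood(e2),
               tolerance = 1e-10)
})

test_that("the likelihood is invariant to relabelling the codon states", {
  set.seed(16)
  tr <- read_newick("(A:0.3,B:0.7);")
  mut <- mutation_params(kappa = 1.3, theta = c(0.2, 0.3, 0.25, 0.25))
  prof <- draw_fitness_profile()
  cfg <- shift_configuration(prof, list(), "equilibrium")
  aln <- simulate_alignment(tr, cfg, 5, mut)
  eng <- likelihood_engine(tr, aln, cfg, mut)
  Q <- generator(mutsel_model(mut, prof))
  rho <- stationary_distribution(Q)
  perm <- sample(61)
  Qp <- Q[perm, perm]
  Pp <- lapply(tr$edge.length, function(t) transition_probabilities(Qp, t))
  alnp <- codon_alignment(matrix(match(as.integer(aln), perm),
                                 nrow = 2, dimnames = dimnames(aln)),
                          taxa = rownames(aln))
  expect_equal(log_likelihood(eng),
               enumerate_loglik(tr, alnp, Pp, rho[perm]),
               tolerance = 1e-10)
})

test_that("engines demand alignments covering every tree tip", {
  tr <- fixture_tree3()
  aln <- read_codon_fasta(">A\nATGAAA\n>B\nATGAAG\n")
  expect_error(likelihood_engine(tr, aln, shift_configuration()),
               "missing taxa")
})
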