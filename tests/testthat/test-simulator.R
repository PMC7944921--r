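test_that("simulated trees are rooted, binary, ultrametric pure-birth", {
  set.seed(40)
  tr <- simulate_tree(10, 0.5, 0)
  expect_equal(nrow(tr$edge), 18)             # 2n - 2
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.binary(tr))
  # determinism under a seed
  t1 <- simulate_tree(8, 1, 0.5, seed = 99)
  t2 <- simulate_tree(8, 1, 0.5, seed = 99)
  expect_identical(write_newick(t1), write_newick(t2))
  # branch lengths scale inversely with the birth rate
  set.seed(41)
  a_slow <- mean(replicate(200, max(ape::node.depth.edgelength(
    simulate_tree(6, 0.5, 0)))))
  a_fast <- mean(replicate(200, max(ape::node.depth.edgelength(
    simulate_tree(6, 5, 0)))))
  expect_gt(a_slow, 5 * a_fast)
})

test_that("balance zero reproduces the Yule Colless expectation", {
  set.seed(42)
  n <- 8
  idx <- replicate(3000, mutselshift:::colless_index(
    simulate_tree(n, 1, 0)))
  expected <- yule_colless_expectation(n)
  se <- sd(idx) / sqrt(length(idx))
  expect_lt(abs(mean(idx) - expected), 4 * se)
})

test_that("the balance parameter orders tree imbalance monotonically", {
  set.seed(43)
  n <- 16
  coll <- function(b) replicate(300, mutselshift:::colless_index(
    simulate_tree(n, 1, b)))
  bal <- coll(1.9); bdp <- coll(0); imb <- coll(-0.7)
  expect_lt(mean(bal), mean(bdp))
  expect_lt(mean(bdp), mean(imb))
})

test_that("fitness draws respect the uniform bounds and the anchor", {
  set.seed(44)
  draws <- replicate(400, as.numeric(draw_fitness_profile(5e-5)))
  expect_true(all(draws[1:19, ] >= 1 - 5e-5 & draws[1:19, ] <= 1 + 5e-5))
  expect_true(all(draws[20, ] == 1))
  free <- as.numeric(draws[1:19, ])
  se <- sd(free) / sqrt(length(free))
  expect_lt(abs(mean(free) - 1), 4 * se)
})

test_that("shift placement follows the two-stage uniform depth scheme", {
  tr3 <- read_newick("((A:1,B:1):1,C:2);")
  # depths: level 1 = {internal(5), C(3)}, level 2 = {A(1), B(2)}
  # two-stage scheme here gives each of the four branches probability 1/4
  set.seed(45)
  draws <- replicate(8000, place_shift(tr3))
  freq <- table(factor(draws, levels = c(1, 2, 3, 5))) / length(draws)
  expect_true(all(abs(freq - 0.25) < 0.02))
  # 5-leaf caterpillar: analytic marginals from the scheme
  tr5 <- read_newick("((((A:1,B:1):1,C:2):1,D:3):1,E:4);")
  depth <- mutselshift:::node_edge_depths(tr5)
  levels_present <- sort(unique(depth[depth > 0]))
  marg <- sapply(seq_len(max(tr5$edge)), function(v) {
    if (is.na(depth[v]) || depth[v] == 0) return(0)
    (1 / length(levels_present)) / sum(depth == depth[v], na.rm = TRUE)
  })
  set.seed(46)
  draws5 <- replicate(8000, place_shift(tr5))
  freq5 <- as.numeric(table(factor(draws5, levels = seq_along(marg)))) /
    length(draws5)
  expect_true(all(abs(freq5 - marg) < 0.025))
})

test_that("Dirichlet root frequencies are symmetric on the 61-simplex", {
  set.seed(47)
  draws <- replicate(2000, draw_root_frequencies(1))
  expect_equal(colSums(draws), rep(1, 2000), tolerance = 1e-9)
  means <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(means - 1 / 61) < 4 * se))
  # large concentration collapses towards uniform
  conc <- draw_root_frequencies(1e5, seed = 2)
  expect_lt(max(abs(conc - 1 / 61)), 1e-3)
})

test_that("a zero-length tree copies the root draw to every tip", {
  set.seed(48)
  tr <- read_newick("((A:0,B:0):0,C:0);")
  cfg <- shift_configuration(draw_fitness_profile(), list(),
                             "equilibrium")
  aln <- simulate_alignment(tr, cfg, 40, mutation_params(kappa = 1))
  expect_true(all(aln["A", ] == aln["B", ]))
  expect_true(all(aln["A", ] == aln["C", ]))
})

test_that("long-branch tip frequencies reach the stationary distribution", {
  set.seed(49)
  # weak selection so the chain actually mixes from a uniform start
  prof <- draw_fitness_profile(2e-6)
  mut <- mutation_params(kappa = 1)
  cfg <- shift_configuration(prof, list(), rep(1 / 61, 61))
  pi <- stationary_distribution(generator(mutsel_model(mut, prof)))
  # star-ish tree with long branches, uniform (non-stationary) root
  tr <- read_newick("((A:30,B:30):30,C:60);")
  aln <- simulate_alignment(tr, cfg, 500, mut, method = "ctmc")
  obs <- table(factor(as.integer(aln[c("A", "C"), ]), levels = 1:61))
  expect_gt(lumped_chisq_p(as.numeric(obs), as.numeric(pi)), 0.01)
})

test_that("CTMC-jump and matrix-sampling modes agree in distribution", {
  set.seed(50)
  prof <- draw_fitness_profile()
  mut <- mutation_params(kappa = 1)
  cfg <- shift_configuration(prof, list(), "equilibrium")
  tr <- read_newick("(A:1.5,B:1.5);")
  a1 <- simulate_alignment(tr, cfg, 700, mut, method = "ctmc")
  a2 <- simulate_alignment(tr, cfg, 700, mut, method = "matrix")
  t1 <- table(factor(as.integer(a1), levels = 1:61))
  t2 <- table(factor(as.integer(a2), levels = 1:61))
  pooled <- (as.numeric(t1) + as.numeric(t2)) / sum(t1 + t2)
  keep <- pooled * sum(t1) >= 5
  o <- rbind(c(as.numeric(t1)[keep], sum(t1[!keep])),
             c(as.numeric(t2)[keep], sum(t2[!keep])))
  p <- suppressWarnings(stats::chisq.test(o))$p.value
  expect_gt(p, 0.005)
})

test_that("with no shift and equilibrium root the process is stationary", {
  set.seed(51)
  prof <- draw_fitness_profile()
  mut <- mutation_params(kappa = 1)
  cfg <- shift_configuration(prof, list(), "equilibrium")
  pi <- stationary_distribution(generator(mutsel_model(mut, prof)))
  tr <- read_newick("(A:0.8,B:0.8);")
  aln <- simulate_alignment(tr, cfg, 800, mut)
  obs <- table(factor(as.integer(aln), levels = 1:61))
  expect_gt(lumped_chisq_p(as.numeric(obs), as.numeric(pi)), 0.01)
})

test_that("run_block archives replicates reproducibly", {
  spec <- simulation_spec("ASHIFT", taxa = 5, codons = 20, n_shifts = 1,
                          replicates = 3, seed = 7)
  d1 <- file.path(tempdir(), "blk1"); d2 <- file.path(tempdir(), "blk2")
  m1 <- run_block(spec, d1); m2 <- run_block(spec, d2)
  expect_equal(nrow(m1), 3)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # truth JSON reconstructs the simulated configuration
  cfg <- config_from_json(file.path(d1, "rep_001_truth.json"))
  rep1 <- simulate_replicate(spec, 1)
  expect_equal(as.numeric(cfg$base_profile),
               as.numeric(rep1$config$base_profile))
  expect_equal(cfg$shifts[[1]]$branch, rep1$shift_branch)
  # alignment and tree files round-trip
  aln <- read_codon_fasta(file.path(d1, "rep_001.fasta"))
  expect_equal(unclass(aln), unclass(rep1$alignment))
  tr <- read_newick(file = file.path(d1, "rep_001.nwk"))
  expect_equal(tr$edge, rep1$tree$edge)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("simulation specs encode the two study designs", {
  sp <- simulation_spec("RFREQ", taxa = 20, codons = 300,
                        balance = "BAL", birth_rate = 2, replicates = 10,
                        seed = 3)
  expect_equal(sp$n_shifts, 0L)          # RFREQ never places shifts
  expect_equal(sp$balance, 1.9)
  expect_error(simulation_spec("ASHIFT", n_shifts = 2), "n_shifts")
})
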