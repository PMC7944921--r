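small_sim <- function(seed = 20, codons = 80, taxa = 5) {
  set.seed(seed)
  tr <- simulate_tree(taxa, 0.7, 0)
  prof <- draw_fitness_profile()
  cfg <- shift_configuration(prof, list(), "equilibrium")
  mut <- mutation_params(kappa = 1)
  aln <- simulate_alignment(tr, cfg, codons, mut)
  list(tree = tr, prof = prof, cfg = cfg, mut = mut, aln = aln)
}

test_that("a fully masked fit returns the input point with 0 evaluations", {
  d <- small_sim()
  eng <- likelihood_engine(d$tree, d$aln, d$cfg, d$mut)
  f <- fit(eng, free_profiles = integer(0), free_kappa = FALSE,
           free_theta = FALSE)
  expect_equal(f$loglik, log_likelihood(eng), tolerance = 1e-12)
  expect_equal(f$iterations, 0L)
  expect_equal(f$k_params, 0L)
  expect_equal(f$estimates$kappa, d$mut$kappa)
  expect_equal(as.numeric(f$estimates$profiles[[1]]),
               as.numeric(d$prof))
})

test_that("the recorded best log-likelihood never decreases", {
  d <- small_sim()
  eng <- likelihood_engine(d$tree, d$aln,
                           shift_configuration(fitness_profile()), d$mut)
  f <- quiet_fit(eng, free_kappa = FALSE, free_theta = FALSE,
                 settings = fit_settings(maxfun = 300, rhoend = 0.02))
  expect_true(all(diff(f$trace) >= 0))
  # the fitted point can only improve on the neutral start
  expect_gte(f$loglik, log_likelihood(eng))
})

test_that("fitting recovers a likelihood at least as good as the truth", {
  d <- small_sim(seed = 21, codons = 150)
  eng <- likelihood_engine(d$tree, d$aln,
                           shift_configuration(fitness_profile()), d$mut)
  f <- quiet_fit(eng, free_kappa = FALSE, free_theta = FALSE,
                 settings = fit_settings(maxfun = 1200, rhoend = 5e-3))
  eng_truth <- likelihood_engine(d$tree, d$aln, d$cfg, d$mut)
  expect_gte(f$loglik, log_likelihood(eng_truth) - 1e-6)
  expect_equal(f$k_params, 19L)
  # estimates stay inside the supported band
  expect_true(all(abs(as.numeric(f$estimates$profiles[[1]]) - 1) <= 1e-4 + 1e-12))
})

test_that("free-root fits nest the equilibrium-root model", {
  d <- small_sim(seed = 22, codons = 60)
  st <- fit_settings(maxfun = 500, rhoend = 0.02)
  eng_eq <- likelihood_engine(d$tree, d$aln,
                              shift_configuration(fitness_profile()), d$mut)
  f_eq <- quiet_fit(eng_eq, free_kappa = FALSE, free_theta = FALSE,
                    settings = st)
  eng_fr <- likelihood_engine(d$tree, d$aln,
                              shift_configuration(fitness_profile(),
                                                  list(), rep(1 / 61, 61)),
                              d$mut)
  f_fr <- quiet_fit(eng_fr, free_kappa = FALSE, free_theta = FALSE,
                    settings = st)
  expect_gte(f_fr$loglik, f_eq$loglik - 1e-6)
  expect_equal(f_fr$k_params, 79L)     # 19 fitnesses + 60 root frequencies
  expect_equal(sum(f_fr$estimates$root_frequencies), 1, tolerance = 1e-9)
})

test_that("root-frequency EM profiling matches direct maximisation", {
  set.seed(23)
  L <- matrix(rexp(61 * 8), 61, 8)
  w <- c(3, 1, 2, 1, 1, 4, 1, 2)
  em <- mutselshift:::ms_root_em(L, rep(0, 8), w, rep(1 / 61, 61),
                                 tol = 1e-12, maxit = 5000)
  # EM result is a stationary point: no single-coordinate exchange helps
  obj <- function(rho) sum(w * log(colSums(rho * L)))
  base_val <- obj(em$rho)
  for (k in c(1, 17, 42)) {
    probe <- em$rho
    probe[k] <- probe[k] + 1e-4
    probe <- probe / sum(probe)
    expect_lte(obj(probe), base_val + 1e-8)
  }
  expect_equal(em$loglik, base_val, tolerance = 1e-10)
})

test_that("provisional candidate fits equal the full engine exactly", {
  set.seed(24)
  tr <- simulate_tree(8, 0.7, 0)
  base <- draw_fitness_profile()
  cfg <- shift_configuration(base, list(), "equilibrium")
  mut <- mutation_params(kappa = 1)
  aln <- simulate_alignment(tr, cfg, 60, mut)
  eng <- likelihood_engine(tr, aln, cfg, mut)
  ev <- mutselshift:::ms_eval(eng, 1.2, c(0.26, 0.24, 0.25, 0.25),
                              list(as.numeric(base)), detail = TRUE)
  for (ce in c(2, 7, nrow(tr$edge)))  {
    pv <- suppressWarnings(mutselshift:::fit_candidate_shift(
      eng, ev, ce, fit_settings(maxfun = 120, rhoend = 0.1),
      1.2, c(0.26, 0.24, 0.25, 0.25)))
    aug <- shift_configuration(base,
                               list(list(branch = tr$edge[ce, 2],
                                         profile = pv$profile)),
                               "equilibrium")
    enga <- likelihood_engine(tr, aln, aug, mut)
    full <- mutselshift:::ms_eval(enga, 1.2, c(0.26, 0.24, 0.25, 0.25),
                                  list(as.numeric(base),
                                       as.numeric(pv$profile)),
                                  root = ev$rho)$loglik
    expect_equal(pv$loglik, full, tolerance = 1e-8)
  }
})

test_that("tidy and glance summarise fits in tabular form", {
  d <- small_sim(seed = 25, codons = 30)
  eng <- likelihood_engine(d$tree, d$aln, d$cfg, d$mut)
  f <- fit(eng, free_profiles = integer(0), free_kappa = FALSE,
           free_theta = FALSE)
  td <- generics::tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$block == "fitness"), 20)
  expect_true(all(c("kappa", "f_A", "f_Y") %in% td$term))
  gl <- generics::glance(f)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$logLik, f$loglik)
})
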