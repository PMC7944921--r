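test_that("fitness correlation uses the 19 free entries only", {
  set.seed(60)
  truth <- draw_fitness_profile()
  expect_equal(fitness_correlation(truth, truth), 1)
  reflected <- fitness_profile(2 - as.numeric(truth)[1:19])
  expect_equal(fitness_correlation(truth, reflected), -1)
  # anchored entry is ignored: r is computed from the free entries
  est <- as.numeric(truth)
  expect_equal(fitness_correlation(truth, est[1:19]), 1)
  # textbook formula on a printed toy pair (first 5 entries replicated)
  a <- c(1.2, 0.8, 1.5, 0.9, 1.1); b <- c(1.0, 0.7, 1.6, 1.1, 0.9)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  pad <- function(x) c(rep(x, 3), x[1:4])          # 19 entries
  expect_equal(fitness_correlation(fitness_profile(1 + (pad(a) - 1) * 1e-5),
                                   fitness_profile(1 + (pad(b) - 1) * 1e-5)),
               cor(pad(a), pad(b)), tolerance = 1e-7)
  expect_equal(r_hand, cor(a, b), tolerance = 1e-12)
  # zero variance is undefined
  expect_true(is.na(fitness_correlation(fitness_profile(), truth)))
})

test_that("fitness correlation is invariant to common affine maps", {
  set.seed(61)
  x <- runif(19, 1 - 5e-5, 1 + 5e-5)
  y <- runif(19, 1 - 5e-5, 1 + 5e-5)
  r0 <- fitness_correlation(x, y)
  expect_equal(fitness_correlation(1 + 3 * (x - 1), 1 + 3 * (y - 1)), r0,
               tolerance = 1e-10)
})

test_that("root-frequency correlation drops the constrained coordinate", {
  set.seed(62)
  truth <- draw_root_frequencies()
  expect_equal(root_frequency_correlation(truth, truth), 1)
  # permuted estimates are uncorrelated on average
  rs <- replicate(300, root_frequency_correlation(truth, sample(truth)))
  expect_lt(abs(mean(rs)), 4 * sd(rs) / sqrt(length(rs)))
  # uniform estimate has zero variance: undefined
  expect_true(is.na(root_frequency_correlation(truth, rep(1 / 61, 61))))
})

test_that("error fold change is the RMSE ratio over free fitnesses", {
  set.seed(63)
  truth <- draw_fitness_profile()
  est1 <- fitness_profile(as.numeric(truth)[1:19] + 1e-6)
  est2 <- fitness_profile(as.numeric(truth)[1:19] + 2e-6)
  expect_equal(error_fold_change(truth, est1, est2), 2, tolerance = 1e-9)
  expect_equal(error_fold_change(truth, est1, est1), 1)
  # toy 3-vector worked example against the formula by hand
  tf <- c(1, 2, 3); with_r <- c(1.1, 2.1, 3.1); without_r <- c(0.7, 2.2, 3.4)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  pad19 <- function(x) c(rep(x, 6), x[1])
  expect_equal(error_fold_change(pad19(tf), pad19(with_r), pad19(without_r)),
               rmse(pad19(without_r), pad19(tf)) /
                 rmse(pad19(with_r), pad19(tf)), tolerance = 1e-12)
  expect_warning(out <- error_fold_change(truth, truth, est1), "infinite")
  expect_identical(out, Inf)
})

fake_result <- function(shifts, profiles, outcome =
                          if (length(shifts)) "shifts_found" else "no_shift") {
  structure(list(shifts = shifts, outcome = outcome,
                 fit = list(estimates = list(profiles = profiles))),
            class = "shift_search")
}

test_that("block summaries tabulate outcomes, depths and correlations", {
  set.seed(64)
  tr <- simulate_tree(6, 1, 0)
  base <- draw_fitness_profile()
  shift_prof <- draw_fitness_profile()
  sb <- place_shift(tr)
  rep_shift <- list(tree = tr, shift_branch = sb,
                    config = shift_configuration(
                      base, list(list(branch = sb, profile = shift_prof))))
  rep_null <- list(tree = tr, shift_branch = NA_integer_,
                   config = shift_configuration(base))
  reps <- list(rep_shift, rep_shift, rep_null)
  results <- list(
    fake_result(sb, list(base, shift_prof)),            # correct_only
    fake_result(integer(0), list(base)),                # none_returned
    fake_result(integer(0), list(base)))                # true_negative
  bs <- summarise_block(reps, results)
  expect_s3_class(bs$replicates, "tbl_df")
  expect_equal(nrow(bs$replicates), 3)
  expect_equal(bs$replicates$outcome,
               c("correct_only", "none_returned", "true_negative"))
  expect_equal(sum(bs$proportions$proportion), 1, tolerance = 1e-12)
  expect_equal(bs$replicates$shift_depth[1], node_time_depth(tr, sb))
  expect_equal(bs$replicates$r_root[1], 1)
  expect_equal(bs$replicates$r_shift[1], 1)
  expect_true(is.na(bs$replicates$r_shift[2]))
  cr <- bs$correlations
  expect_equal(cr$n[cr$parameter == "root_fitness"], 3L)
  expect_equal(cr$median[cr$parameter == "root_fitness"], 1)
  expect_equal(cr$n[cr$parameter == "shift_fitness"], 1L)
  # missing results are flagged and excluded from proportions
  bs2 <- summarise_block(reps, list(results[[1]], NULL, results[[3]]))
  expect_true(bs2$replicates$missing[2])
  expect_equal(sum(bs2$proportions$proportion), 1, tolerance = 1e-12)
  # pure function of the archive: identical re-run
  expect_identical(summarise_block(reps, results)$replicates,
                   bs$replicates)
  # TSV output
  dir <- file.path(tempdir(), "bs")
  paths <- write_block_summary(bs, dir)
  expect_true(all(file.exists(paths)))
  unlink(dir, recursive = TRUE)
})

test_that("plot builders return ggplot objects", {
  set.seed(65)
  prof <- list(draw_fitness_profile(), draw_fitness_profile())
  p <- plot_fitness_profiles(list(estimates = list(profiles = prof)))
  expect_s3_class(p, "ggplot")
})
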