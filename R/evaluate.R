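#' Pearson correlation between true and estimated fitness profiles
#'
#' Computed over the 19 free entries (the anchored twentieth fitness is
#' excluded), on the relative-fitness scale as parameterised.
#'
#' @param true,est Fitness profiles (vectors of length 19 or 20).
#' @return Pearson r, or `NA` if either vector has zero variance.
#' @export
fitness_correlation <- function(true, est) {
  true <- as.numeric(true)[1:19]
  est <- as.numeric(est)[1:19]
  if (sd(true) == 0 || sd(est) == 0) return(NA_real_)
  cor(true, est)
}

#' Pearson correlation between true and estimated root frequencies
#'
#' Computed over a 60-element free subset (the last codon frequency,
#' constrained by the simplex, is dropped).
#'
#' @param true,est Numeric 61-vectors on the simplex.
#' @return Pearson r, or `NA` if either subset has zero variance.
#' @export
root_frequency_correlation <- function(true, est) {
  true <- as.numeric(true)[1:60]
  est <- as.numeric(est)[1:60]
  if (sd(true) == 0 || sd(est) == 0) return(NA_real_)
  cor(true, est)
}

#' Fold change in fitness-estimation error from ignoring root frequencies
#'
#' Ratio of the root-mean-square error (over the 19 free fitnesses) of
#' estimates that do *not* model separate root frequencies to the RMSE
#' of estimates from the same data that do.
#'
#' @param true_f True fitness profile.
#' @param est_with_root Estimate from the model with free root
#'   frequencies.
#' @param est_without_root Estimate from the equilibrium-root model.
#' @return The RMSE ratio (>= 0); `Inf` with a warning if the free-root
#'   estimate is exact.
#' @export
error_fold_change <- function(true_f, est_with_root, est_without_root) {
  rmse <- function(a, b) sqrt(mean((as.numeric(a)[1:19] -
                                    as.numeric(b)[1:19])^2))
  num <- rmse(est_without_root, true_f)
  den <- rmse(est_with_root, true_f)
  if (den == 0) {
    warning("zero RMSE for the free-root estimate; fold change is infinite")
    return(Inf)
  }
  num / den
}

#' Score a block of inference runs against simulation truth
#'
#' Joins each replicate's search (or fit) result to its simulated
#' truth: the outcome category, the time depth of the true shift (child
#' node of the shifted branch, via [node_time_depth()]), and the
#' fitness correlations for the root model and, when the correct branch
#' was found, the post-shift model.
#'
#' @param replicates List of [simulate_replicate()] results.
#' @param results List of matching `shift_search` objects (same order).
#' @return An object of class `block_summary`: `$replicates`, a tibble
#'   with one row per replicate; `$proportions`, outcome proportions
#'   over non-missing replicates; `$correlations`, quartile summaries of
#'   the correlation vectors.
#' @export
summarise_block <- function(replicates, results) {
  stopifnot(length(replicates) == length(results))
  rows <- vector("list", length(replicates))
  for (i in seq_along(replicates)) {
    rep <- replicates[[i]]
    res <- results[[i]]
    if (is.null(res)) {
      rows[[i]] <- tibble::tibble(replicate = i, missing = TRUE,
                                  outcome = NA_character_,
                                  shift_depth = NA_real_,
                                  r_root = NA_real_, r_shift = NA_real_)
      next
    }
    truth <- if (is.na(rep$shift_branch)) integer(0) else rep$shift_branch
    outcome <- classify_outcome(res, truth)
    depth <- if (length(truth)) node_time_depth(rep$tree, truth) else NA_real_
    est <- res$fit$estimates
    r_root <- if (!is.null(est) && length(est$profiles))
      fitness_correlation(rep$config$base_profile, est$profiles[[1]])
      else NA_real_
    r_shift <- NA_real_
    if (length(truth) && !is.null(est) && length(est$profiles) > 1 &&
        truth %in% res$shifts) {
      pos <- match(truth, res$shifts)
      r_shift <- fitness_correlation(rep$config$shifts[[1]]$profile,
                                     est$profiles[[pos + 1L]])
    }
    rows[[i]] <- tibble::tibble(replicate = i, missing = FALSE,
                                outcome = outcome, shift_depth = depth,
                                r_root = r_root, r_shift = r_shift)
  }
  per_rep <- dplyr::bind_rows(rows)
  lev <- c("correct_only", "correct_plus_false", "incorrect_only",
           "optimisation_failure", "none_returned", "true_negative",
           "false_positive")
  ok <- per_rep[!per_rep$missing, ]
  props <- tibble::tibble(outcome = lev,
                          proportion = as.numeric(
                            table(factor(ok$outcome, levels = lev)) /
                              max(1L, nrow(ok))))
  props <- props[props$proportion > 0 | props$outcome %in%
                   unique(ok$outcome), ]
  qsum <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(tibble::tibble(n = 0L, q1 = NA_real_,
                                          median = NA_real_, q3 = NA_real_))
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(n = length(x), q1 = q[1], median = q[2], q3 = q[3])
  }
  corrs <- dplyr::bind_rows(
    dplyr::mutate(qsum(ok$r_root), parameter = "root_fitness",
                  .before = 1),
    dplyr::mutate(qsum(ok$r_shift), parameter = "shift_fitness",
                  .before = 1))
  structure(list(replicates = per_rep, proportions = props,
                 correlations = corrs),
            class = "block_summary")
}

#' @export
print.block_summary <- function(x, ...) {
  cat("Block summary over", nrow(x$replicates), "replicates\n")
  print(x$proportions)
  print(x$correlations)
  invisible(x)
}

#' Write a block summary to TSV files
#'
#' @param summary A `block_summary`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_block_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("replicates.tsv", "proportions.tsv",
                            "correlations.tsv"))
  utils::write.table(summary$replicates, paths[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(summary$proportions, paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(summary$correlations, paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# Colless imbalance index of a rooted binary tree (used by the tree
# simulator's calibration checks).
colless_index <- function(tree) {
  edge <- tree$edge
  n_tip <- length(tree$tip.label)
  size <- rep(1L, max(edge))
  imb <- 0L
  kids_of <- split(edge[, 2], edge[, 1])
  depths <- node_edge_depths(tree)
  internal <- unique(edge[, 1])
  post <- internal[order(depths[internal], decreasing = TRUE)]
  for (v in post) {
    kids <- kids_of[[as.character(v)]]
    s <- size[kids]
    imb <- imb + abs(s[1] - s[2])
    size[v] <- sum(s)
  }
  imb
}
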