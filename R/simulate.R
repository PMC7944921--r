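#' Simulate a random rooted ultrametric tree with controlled balance
#'
#' Generates a pure-birth (Yule) tree whose topology follows the Aldous
#' beta-splitting model: a clade of `n` tips splits into left/right
#' sizes `(i, n - i)` with probability proportional to
#' `gamma(beta + i + 1) gamma(beta + n - i + 1) / (i! (n - i)!)`.
#' `balance = 0` reproduces the Yule topology distribution exactly;
#' positive values give stochastically more balanced trees, negative
#' values (> -1) more imbalanced ones.  Node times are drawn from the
#' constant-rate pure-birth process (waiting time with `k` lineages ~
#' Exponential(`k * birth_rate`), death rate 0), with the tips placed
#' one further exponential waiting time after the last speciation; the
#' age of the tree is therefore random.  Speciation times are attached
#' to the topology root-down, each successive event time going to a
#' uniformly chosen timeable internal node.
#'
#' @param taxa Number of tips (>= 3).
#' @param birth_rate Speciation rate (> 0) in neutral-substitution time
#'   units.
#' @param balance Beta-splitting balance parameter (> -1).
#' @param seed Optional integer seed.
#' @return A rooted binary ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(taxa, birth_rate, balance = 0, seed = NULL) {
  stopifnot(taxa >= 3, birth_rate > 0, balance > -1)
  if (!is.null(seed)) set.seed(seed)
  sizes <- beta_split_sizes(taxa, balance)      # per-node clade sizes
  # event times: with k lineages the wait is Exp(k * birth_rate)
  waits <- rexp(taxa - 1, rate = seq(2, taxa) * birth_rate)
  times <- cumsum(c(0, waits[-(taxa - 1)]))     # speciation times, root = 0
  tip_time <- sum(waits[-(taxa - 1)]) + waits[taxa - 1]
  nwk <- beta_split_newick(sizes, times, tip_time)
  tr <- ape::read.tree(text = nwk)
  validate_phylogeny(tr)
}

# Recursive beta-splitting: returns a nested list (tree of clade sizes).
beta_split_sizes <- function(n, beta) {
  if (n == 1L) return(list(size = 1L))
  i <- if (n == 2L) 1L else {
    ii <- 1:(n - 1)
    lw <- lgamma(beta + ii + 1) + lgamma(beta + n - ii + 1) -
      lgamma(ii + 1) - lgamma(n - ii + 1)
    sample(ii, 1L, prob = exp(lw - max(lw)))
  }
  list(size = n, left = beta_split_sizes(i, beta),
       right = beta_split_sizes(n - i, beta))
}

# Assign pure-birth event times to the topology and emit Newick.
# The root takes the first event; each subsequent time goes to a
# uniformly chosen internal node whose parent is already timed.
beta_split_newick <- function(top, times, tip_time) {
  nodes <- list(); edges <- list(); cnt <- 0L
  flatten <- function(x, parent) {
    cnt <<- cnt + 1L; id <- cnt
    nodes[[id]] <<- list(id = id, parent = parent, leaf = is.null(x$left))
    if (!is.null(x$left)) {
      l <- flatten(x$left, id); r <- flatten(x$right, id)
      nodes[[id]]$kids <<- c(l, r)
    }
    id
  }
  root <- flatten(top, NA)
  internal <- which(vapply(nodes, function(z) !z$leaf, logical(1)))
  tm <- rep(NA_real_, length(nodes))
  open <- root
  for (t in times) {
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    tm[pick] <- t
    open <- setdiff(open, pick)
    kids <- nodes[[pick]]$kids
    open <- c(open, kids[!vapply(nodes[kids], `[[`, logical(1), "leaf")])
  }
  tipc <- 0L
  emit <- function(id) {
    nd <- nodes[[id]]
    pt <- if (is.na(nd$parent)) NA else tm[nd$parent]
    if (nd$leaf) {
      tipc <<- tipc + 1L
      sprintf("t%d:%.12g", tipc, tip_time - pt)
    } else {
      len <- if (is.na(nd$parent)) 0 else tm[id] - pt
      sprintf("(%s,%s)%s", emit(nd$kids[1]), emit(nd$kids[2]),
              if (is.na(nd$parent)) "" else sprintf(":%.12g", len))
    }
  }
  paste0(emit(root), ";")
}

#' Draw a random amino-acid fitness profile
#'
#' The 19 free fitnesses are i.i.d. Uniform(1 - half_width,
#' 1 + half_width); the anchored twentieth fitness is exactly 1.
#'
#' @param half_width Half-width of the uniform draw (default 5e-5).
#' @param seed Optional integer seed.
#' @return A [fitness_profile()].
#' @export
draw_fitness_profile <- function(half_width = 5e-5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fitness_profile(runif(19, 1 - half_width, 1 + half_width))
}

#' Place a selective shift uniformly over node depths
#'
#' Two-stage draw: first a node depth (number of edges from the root) is
#' selected uniformly among the depths present in the tree, then one
#' node is selected uniformly among the nodes at that depth.  The
#' returned branch is the one above the selected node, so shifts are
#' spread over time depths rather than concentrated near the tips.
#'
#' @param tree A rooted binary `phylo`.
#' @param seed Optional integer seed.
#' @return Branch id (child node index) of the shifted branch.
#' @export
place_shift <- function(tree, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  depth <- node_edge_depths(tree)
  levels <- sort(unique(depth[depth > 0]))
  lev <- if (length(levels) == 1L) levels else sample(levels, 1L)
  at <- which(depth == lev)
  if (length(at) == 1L) at else sample(at, 1L)
}

# node depth in edges from the root, for all nodes (root = 0)
node_edge_depths <- function(tree) {
  edge <- tree$edge
  depth <- rep(NA_integer_, max(edge))
  depth[length(tree$tip.label) + 1L] <- 0L
  for (e in reorder_preorder(tree))
    depth[edge[e, 2]] <- depth[edge[e, 1]] + 1L
  depth
}

#' Draw root codon frequencies from a symmetric Dirichlet
#'
#' @param concentration Dirichlet concentration parameter (alpha = 1
#'   gives the uniform distribution on the 61-simplex).
#' @param seed Optional integer seed.
#' @return Numeric 61-vector summing to 1.
#' @export
draw_root_frequencies <- function(concentration = 1, seed = NULL) {
  stopifnot(concentration > 0)
  if (!is.null(seed)) set.seed(seed)
  g <- rgamma(61, shape = concentration)
  g / sum(g)
}

#' Simulate a codon alignment on a tree
#'
#' Evolves i.i.d. codon sites along the tree under the
#' branch-heterogeneous mutation-selection process described by
#' `config`.  The root codon of each site is drawn from the configured
#' root frequencies (the root model's stationary distribution in
#' equilibrium mode); each branch then evolves the site under its own
#' scaled generator, either by exact continuous-time Markov-chain
#' simulation (exponential waiting times and jump probabilities from the
#' generator rows; the default, exact for asymmetric generators) or by
#' sampling from the matrix exponential `exp(Q t)`.
#'
#' @param tree Rooted binary `phylo`.
#' @param config A [shift_configuration()].
#' @param codons Number of codon sites.
#' @param mutation Treewide [mutation_params()].
#' @param fixation_form Fixation form used for the generators.
#' @param method `"ctmc"` (exact jump simulation) or `"matrix"`
#'   (sampling from `exp(Q t)`).
#' @param seed Optional integer seed.
#' @param s_max Selection-coefficient ceiling.
#' @return A [codon_alignment()] over the tree's tips.
#' @export
simulate_alignment <- function(tree, config, codons,
                               mutation = mutation_params(kappa = 1),
                               fixation_form = "non_reversible",
                               method = c("ctmc", "matrix"),
                               seed = NULL, s_max = 5e-4) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  tree <- validate_phylogeny(tree)
  profiles <- config_profiles(config)
  models <- lapply(profiles, function(f)
    mutsel_model(mutation, f, fixation_form, s_max = s_max))
  Qs <- lapply(models, generator)
  assign <- assign_models(tree, config)
  rho <- config$root_frequencies
  if (is.character(rho)) rho <- stationary_distribution(Qs[[1]])

  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  state <- matrix(NA_integer_, max(edge), codons)
  state[n_tip + 1L, ] <- sample.int(61, codons, replace = TRUE, prob = rho)

  if (method == "ctmc") {
    jump <- lapply(Qs, function(Q) {
      J <- Q; diag(J) <- 0
      rs <- rowSums(J)
      list(P = J / rs, rate = rs)
    })
    for (e in reorder_preorder(tree)) {
      m <- assign[e]; len <- tree$edge.length[e]
      cur <- state[edge[e, 1], ]
      if (len > 0) {
        for (s in seq_len(codons)) {
          x <- cur[s]; t <- 0
          repeat {
            t <- t + rexp(1, jump[[m]]$rate[x])
            if (t > len) break
            x <- sample.int(61, 1L, prob = jump[[m]]$P[x, ])
          }
          cur[s] <- x
        }
      }
      state[edge[e, 2], ] <- cur
    }
  } else {
    for (e in reorder_preorder(tree)) {
      P <- transition_probabilities(Qs[[assign[e]]], tree$edge.length[e])
      cur <- state[edge[e, 1], ]
      out <- integer(codons)
      for (x in unique(cur)) {
        at <- which(cur == x)
        out[at] <- sample.int(61, length(at), replace = TRUE, prob = P[x, ])
      }
      state[edge[e, 2], ] <- out
    }
  }
  codon_alignment(state[seq_len(n_tip), , drop = FALSE],
                  taxa = tree$tip.label)
}

#' Specification of one simulation treatment block
#'
#' Captures one cell of the simulation design: the shift-detection
#' series (`"ASHIFT"`: equilibrium root frequencies, 0 or 1 selective
#' shifts, birth-death balance, birth rate 0.5) or the root-frequency
#' co-estimation series (`"RFREQ"`: free Dirichlet root frequencies, no
#' shifts, three balance conditions crossed with a birth-rate grid).
#'
#' @param series `"ASHIFT"` or `"RFREQ"`.
#' @param taxa Number of tips.
#' @param codons Alignment length in codons.
#' @param n_shifts 0 or 1 true selective shifts.
#' @param balance `"BAL"` (beta = 1.9), `"BDP"` (beta = 0) or `"IMB"`
#'   (beta = -0.7), or a numeric beta value.
#' @param birth_rate Speciation rate.
#' @param replicates Number of replicate simulations.
#' @param seed Master seed for the block; per-replicate streams are
#'   derived deterministically from it.
#' @param fitness_half_width Half-width of the uniform fitness draws.
#' @param root_concentration Dirichlet concentration for RFREQ root
#'   frequencies.
#' @param kappa,N_p Mutation parameters used in simulation.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(series = c("ASHIFT", "RFREQ"), taxa = 10,
                            codons = 300, n_shifts = 1,
                            balance = "BDP", birth_rate = 0.5,
                            replicates = 20, seed = 1,
                            fitness_half_width = 5e-5,
                            root_concentration = 1,
                            kappa = 1, N_p = 1e5) {
  series <- match.arg(series)
  stopifnot(n_shifts %in% 0:1, taxa >= 3, codons >= 1, replicates >= 1)
  if (is.character(balance))
    balance <- c(BAL = 1.9, BDP = 0, IMB = -0.7)[[balance]]
  if (series == "RFREQ") n_shifts <- 0L
  structure(list(series = series, taxa = taxa, codons = codons,
                 n_shifts = n_shifts, balance = balance,
                 birth_rate = birth_rate, replicates = replicates,
                 seed = as.integer(seed),
                 fitness_half_width = fitness_half_width,
                 root_concentration = root_concentration,
                 kappa = kappa, N_p = N_p),
            class = "simulation_spec")
}

replicate_seed <- function(spec, r) {
  as.integer((as.numeric(spec$seed) * 7919 + r * 104729) %% 2147483647)
}

#' Simulate one replicate of a treatment block
#'
#' Generates the tree, the true shift configuration and the codon
#' alignment for replicate `r` of `spec`, fully determined by the
#' block's master seed.  ASHIFT replicates use equilibrium root
#' frequencies and, when a shift is present, an independently drawn
#' post-shift profile on a branch placed by the two-stage uniform depth
#' scheme; RFREQ replicates draw root codon frequencies from a symmetric
#' Dirichlet, independent of the treewide fitness profile.
#'
#' @param spec A [simulation_spec()].
#' @param r Replicate index (1-based).
#' @return A list of class `simulated_replicate`: `tree`, `config`
#'   (truth), `alignment`, `shift_branch` (or `NA`), `seed`, `spec`.
#' @export
simulate_replicate <- function(spec, r) {
  set.seed(replicate_seed(spec, r))
  tree <- simulate_tree(spec$taxa, spec$birth_rate, spec$balance)
  mut <- mutation_params(kappa = spec$kappa, theta = rep(0.25, 4),
                         N_p = spec$N_p)
  base <- draw_fitness_profile(spec$fitness_half_width)
  shift_branch <- NA_integer_
  shifts <- list()
  if (spec$n_shifts == 1L) {
    shift_branch <- place_shift(tree)
    shifts <- list(list(branch = shift_branch,
                        profile = draw_fitness_profile(spec$fitness_half_width)))
  }
  root <- if (spec$series == "RFREQ")
    draw_root_frequencies(spec$root_concentration) else "equilibrium"
  config <- shift_configuration(base, shifts, root)
  aln <- simulate_alignment(tree, config, spec$codons, mut,
                            method = "ctmc")
  structure(list(tree = tree, config = config, alignment = aln,
                 shift_branch = shift_branch,
                 seed = replicate_seed(spec, r), spec = spec),
            class = "simulated_replicate")
}

#' Run a full treatment block and archive it to disk
#'
#' Simulates all replicates of `spec` and writes, per replicate, the
#' alignment (`rep_<r>.fasta`), the tree (`rep_<r>.nwk`) and the truth
#' (`rep_<r>_truth.json`), plus a `manifest.tsv` with one row per
#' replicate.  Byte-identical when re-run with the same spec and seed.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a tibble manifest (replicate, seed, shift branch,
#'   file paths).
#' @export
run_block <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", spec$replicates)
  for (r in seq_len(spec$replicates)) {
    rep <- simulate_replicate(spec, r)
    fa <- file.path(dir, sprintf("rep_%03d.fasta", r))
    nw <- file.path(dir, sprintf("rep_%03d.nwk", r))
    tj <- file.path(dir, sprintf("rep_%03d_truth.json", r))
    write_codon_fasta(rep$alignment, fa)
    write_newick(rep$tree, nw)
    config_to_json(rep$config, tj)
    rows[[r]] <- tibble::tibble(
      replicate = r, seed = rep$seed,
      shift_branch = rep$shift_branch,
      fasta = basename(fa), newick = basename(nw), truth = basename(tj))
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
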