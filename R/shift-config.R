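#' Shift configuration: branch-wise assignment of fitness profiles
#'
#' Describes a branch-heterogeneous model: a base fitness profile
#' inherited from the root, an ordered list of selective shifts (each a
#' branch plus the new profile that applies to that branch and all its
#' descendants until another shift intervenes), and the treatment of
#' codon frequencies at the root (`"equilibrium"` = stationary
#' frequencies of the root model, or an explicit free 61-vector).
#'
#' @param base_profile [fitness_profile()] in force at the root.
#' @param shifts List of `list(branch = <child-node id>, profile =
#'   <fitness_profile>)`, in order.
#' @param root_frequencies `"equilibrium"` or a numeric 61-vector
#'   summing to 1 (60 free parameters).
#' @return An object of class `shift_configuration`.
#' @export
shift_configuration <- function(base_profile = fitness_profile(),
                                shifts = list(),
                                root_frequencies = "equilibrium") {
  if (!inherits(base_profile, "fitness_profile"))
    base_profile <- fitness_profile(base_profile)
  for (s in shifts) {
    stopifnot(is.list(s), !is.null(s$branch), !is.null(s$profile))
    if (!inherits(s$profile, "fitness_profile"))
      stop("each shift needs a fitness_profile", call. = FALSE)
  }
  br <- vapply(shifts, function(s) as.integer(s$branch), integer(1))
  if (anyDuplicated(br))
    stop("at most one shift per branch", call. = FALSE)
  if (is.numeric(root_frequencies)) {
    if (length(root_frequencies) != 61L || any(root_frequencies < 0) ||
        abs(sum(root_frequencies) - 1) > 1e-8)
      stop("free root frequencies must be a 61-vector on the simplex",
           call. = FALSE)
    root_frequencies <- root_frequencies / sum(root_frequencies)
  } else if (!identical(root_frequencies, "equilibrium")) {
    stop('root_frequencies must be "equilibrium" or a 61-vector',
         call. = FALSE)
  }
  structure(list(base_profile = base_profile, shifts = shifts,
                 root_frequencies = root_frequencies),
            class = "shift_configuration")
}

#' Number of shifts in a configuration
#' @param config A [shift_configuration()].
#' @return Integer shift count `k`.
#' @export
n_shifts <- function(config) length(config$shifts)

config_profiles <- function(config) {
  c(list(config$base_profile), lapply(config$shifts, `[[`, "profile"))
}

#' Map branches to fitness profiles
#'
#' Resolves a [shift_configuration()] on a tree: every branch carries
#' the profile of the nearest shift on its path back to the root, or the
#' base profile if no shift intervenes.  Model index 1 is the base
#' profile; shift `i` introduces model `i + 1`.  A configuration placing
#' shifts on both basal branches is rejected: the process present at the
#' root must persist on at least one side.
#'
#' @param tree A rooted binary `phylo`.
#' @param config A [shift_configuration()].
#' @return Integer vector over `tree$edge` rows (model index per
#'   branch), with names giving the branch id (child node).
#' @export
assign_models <- function(tree, config) {
  edge <- tree$edge
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  shift_branch <- vapply(config$shifts, function(s) as.integer(s$branch),
                         integer(1))
  if (length(shift_branch)) {
    all_nodes <- c(seq_len(n_tip), root + seq_len(tree$Nnode) - 1L)
    if (!all(shift_branch %in% setdiff(edge[, 2], integer(0))))
      stop("shift branch id not found in tree", call. = FALSE)
    basal <- edge[edge[, 1] == root, 2]
    if (all(basal %in% shift_branch))
      stop("selective shifts on both basal branches are not permitted",
           call. = FALSE)
  }
  # preorder traversal: parent model known before child visited
  ord <- reorder_preorder(tree)
  model <- integer(nrow(edge))
  node_model <- integer(max(edge))
  node_model[root] <- 1L
  for (e in ord) {
    par <- edge[e, 1]; chi <- edge[e, 2]
    m <- node_model[par]
    hit <- match(chi, shift_branch)
    if (!is.na(hit)) m <- hit + 1L
    model[e] <- m
    node_model[chi] <- m
  }
  names(model) <- edge[, 2]
  model
}

# edge indices in preorder (root-ward edges first)
reorder_preorder <- function(tree) {
  edge <- tree$edge
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(edge)), edge[, 1])
  out <- integer(0)
  stack <- children[[as.character(root)]]
  while (length(stack)) {
    e <- stack[1]; stack <- stack[-1]
    out <- c(out, e)
    kids <- children[[as.character(edge[e, 2])]]
    if (!is.null(kids)) stack <- c(kids, stack)
  }
  out
}

#' Serialise a shift configuration to JSON
#'
#' @param config A [shift_configuration()].
#' @param file Optional path.
#' @return JSON string (invisibly when written).
#' @export
config_to_json <- function(config, file = NULL) {
  obj <- list(
    base_profile = as.numeric(config$base_profile),
    shifts = lapply(config$shifts, function(s)
      list(branch = as.integer(s$branch),
           profile = as.numeric(s$profile))),
    root_frequencies = if (is.character(config$root_frequencies))
      "equilibrium" else as.numeric(config$root_frequencies)
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a shift configuration from JSON
#'
#' @param input JSON text or file path.
#' @return A [shift_configuration()].
#' @export
config_from_json <- function(input) {
  obj <- jsonlite::fromJSON(input, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  shifts <- lapply(obj$shifts, function(s)
    list(branch = as.integer(s$branch),
         profile = fitness_profile(as.numeric(s$profile))))
  rf <- obj$root_frequencies
  if (!is.character(rf)) rf <- as.numeric(rf)
  shift_configuration(fitness_profile(as.numeric(obj$base_profile)),
                      shifts, rf)
}
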