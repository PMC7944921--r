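#' @importFrom stats runif rexp rgamma setNames cor median sd quantile
#' @importFrom utils head tail write.table read.table
NULL

# package-level cache (codon space, etc.)
.ms_cache <- new.env(parent = emptyenv())

#' Amino acids in the fixed package ordering
#'
#' Single-letter codes of the 20 canonical amino acids in alphabetical
#' order.  The last one (Y, tyrosine) is the anchored amino acid whose
#' Darwinian fitness is fixed to 1 in every [fitness_profile()].
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' The 61-codon state space of the universal genetic code
#'
#' Builds (once, then caches) the sense-codon state space used by every
#' rate matrix in the package: the 61 triplets of the universal genetic
#' code excluding the stop codons TAA, TAG and TGA, in alphabetical
#' (A < C < G < T) lexicographic order, together with the translation
#' table and the single-nucleotide neighbour relation.
#'
#' @return A list of class `codon_space` with components:
#'   \describe{
#'     \item{codons}{character(61), the sense codons in fixed order.}
#'     \item{aa}{integer(61), amino-acid index (1-20) of each codon,
#'       indexing into [amino_acids()].}
#'     \item{neighbors}{data frame of ordered neighbour pairs `(i, j)`
#'       (codon indices) differing at exactly one nucleotide position,
#'       with the position (1-3), the source and target base, the target
#'       base index into the ACGT frequency vector, a transition flag
#'       (A<->G, C<->T), and a synonymous flag.}
#'   }
#' @examples
#' sp <- codon_space()
#' length(sp$codons)  # 61
#' @export
codon_space <- function() {
  if (!is.null(.ms_cache$space)) return(.ms_cache$space)
  bases <- c("A", "C", "G", "T")
  trip <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  all64 <- sort(paste0(trip$b1, trip$b2, trip$b3))
  stops <- c("TAA", "TAG", "TGA")
  codons <- setdiff(all64, stops)
  stopifnot(length(codons) == 61L)

  gc_tab <- Biostrings::GENETIC_CODE
  aa_letters <- unname(gc_tab[codons])
  aa <- match(aa_letters, amino_acids())
  stopifnot(!anyNA(aa))

  cmat <- do.call(rbind, strsplit(codons, ""))
  n <- length(codons)
  rows <- vector("list", n)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  for (i in seq_len(n)) {
    diffs <- cmat != matrix(cmat[i, ], n, 3, byrow = TRUE)
    nd <- rowSums(diffs)
    js <- which(nd == 1L)
    if (!length(js)) next
    pos <- apply(diffs[js, , drop = FALSE], 1, which)
    from <- cmat[cbind(rep(i, length(js)), pos)]
    to <- cmat[cbind(js, pos)]
    rows[[i]] <- data.frame(
      i = i, j = js, pos = pos, from = from, to = to,
      target = match(to, bases),
      ti = purine[from] == purine[to],
      syn = aa[i] == aa[js],
      row.names = NULL
    )
  }
  nb <- do.call(rbind, rows)
  rownames(nb) <- NULL

  space <- structure(
    list(codons = codons, aa = aa, neighbors = nb),
    class = "codon_space"
  )
  .ms_cache$space <- space
  space
}

#' @export
print.codon_space <- function(x, ...) {
  cat("Codon state space: 61 sense codons, universal code,",
      "A<C<G<T lexicographic order\n")
  cat("Neighbour pairs (directed):", nrow(x$neighbors), "\n")
  invisible(x)
}
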