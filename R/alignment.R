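#' Codon alignment container
#'
#' Stores an in-frame codon alignment as an integer matrix of codon
#' indices (1-61, in [codon_space()] order; `NA` marks missing codons),
#' one row per taxon.
#'
#' @param x Integer matrix of codon indices, or a character vector of
#'   in-frame DNA sequences named by taxon.
#' @param taxa Taxon names (row names of `x` if missing).
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(x, taxa = rownames(x)) {
  space <- codon_space()
  if (is.character(x)) {
    seqs <- toupper(x)
    if (is.null(taxa)) taxa <- names(seqs)
    x <- do.call(rbind, lapply(seq_along(seqs), function(k)
      codon_indices(seqs[k], taxa[k], space, ambiguity = "error")))
  }
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (is.null(taxa)) stop("taxon names are required", call. = FALSE)
  if (anyDuplicated(taxa)) stop("duplicated taxon names", call. = FALSE)
  ok <- is.na(x) | (x >= 1L & x <= 61L)
  if (!all(ok)) stop("codon indices must lie in 1..61 or be NA",
                     call. = FALSE)
  rownames(x) <- taxa
  structure(x, class = c("codon_alignment", "matrix"))
}

codon_indices <- function(seq, taxon, space, ambiguity = c("error", "missing")) {
  ambiguity <- match.arg(ambiguity)
  if (nchar(seq) %% 3L != 0L)
    stop(sprintf("sequence for taxon '%s' has length %d, not a multiple of 3",
                 taxon, nchar(seq)), call. = FALSE)
  cods <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  idx <- match(cods, space$codons)
  bad <- which(is.na(idx))
  for (b in bad) {
    if (cods[b] %in% c("TAA", "TAG", "TGA"))
      stop(sprintf("in-frame stop codon %s in taxon '%s' at codon site %d",
                   cods[b], taxon, b), call. = FALSE)
    if (ambiguity == "error")
      stop(sprintf("ambiguous/invalid codon '%s' in taxon '%s' at codon site %d (use ambiguity = \"missing\" to treat as missing data)",
                   cods[b], taxon, b), call. = FALSE)
  }
  idx
}

#' Read a codon alignment from FASTA
#'
#' Parses an in-frame nucleotide FASTA alignment (file path or literal
#' FASTA text) into a [codon_alignment()].  Sequences must be equal
#' length and a multiple of 3; in-frame stop codons are rejected with
#' the offending taxon and site named.  Codons containing ambiguity
#' codes are rejected by default or, with `ambiguity = "missing"`,
#' treated as missing data.
#'
#' @param input Path to a FASTA file, or FASTA-formatted text.
#' @param ambiguity `"error"` (default) or `"missing"`.
#' @return A [codon_alignment()].
#' @export
read_codon_fasta <- function(input, ambiguity = c("error", "missing")) {
  ambiguity <- match.arg(ambiguity)
  path <- input
  if (length(input) > 1 || grepl(">", input, fixed = TRUE)) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(input, path)
  }
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged alignment: sequences differ in length", call. = FALSE)
  space <- codon_space()
  mat <- do.call(rbind, lapply(seq_along(seqs), function(k)
    codon_indices(seqs[k], names(seqs)[k], space, ambiguity)))
  codon_alignment(mat, taxa = names(seqs))
}

#' Write a codon alignment to FASTA
#'
#' @param aln A [codon_alignment()].  Missing codons are written as NNN.
#' @param file Optional path; if `NULL` the FASTA text is returned.
#' @param width Line-wrap width in nucleotides.
#' @return FASTA text (invisibly when written to a file).
#' @export
write_codon_fasta <- function(aln, file = NULL, width = 60) {
  space <- codon_space()
  lines <- character(0)
  for (k in seq_len(nrow(aln))) {
    cods <- ifelse(is.na(aln[k, ]), "NNN", space$codons[aln[k, ]])
    seq <- paste0(cods, collapse = "")
    starts <- seq(1, nchar(seq), width)
    lines <- c(lines, paste0(">", rownames(aln)[k]),
               substring(seq, starts, pmin(starts + width - 1, nchar(seq))))
  }
  if (is.null(file)) return(paste(lines, collapse = "\n"))
  writeLines(lines, file)
  invisible(paste(lines, collapse = "\n"))
}
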