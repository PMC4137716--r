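#' The codon state space and genetic code
#'
#' Builds the codon state space used throughout the package: the 64 codons
#' enumerated over nucleotide order T, C, A, G with the third codon position
#' varying fastest (so codon 1 is TTT and codon 64 is GGG), the 61 sense
#' codons obtained by dropping the three stop codons, and the translation
#' table.  This ordering is what makes the Kronecker product of three
#' per-position 4 x 4 matrices land directly in codon order.
#'
#' The returned object also carries precomputed pairwise structure over the
#' sense codons (number of differing positions, synonymy, transition status
#' of single-nucleotide changes) that the model-building code reuses.
#'
#' @param aa_table optional named character vector mapping all 64 codons to
#'   one-letter amino-acid symbols, with `"*"` for stops.  Defaults to the
#'   standard (universal) genetic code; alternative codes are accepted but
#'   only the standard code is exercised by the package's own analyses.
#' @return an object of class `genetic_code` with components
#'   `codons` (64 codons in canonical order), `sense` (61 sense codons,
#'   order preserved), `stop` (the stop codons), `aa` (amino acid per sense
#'   codon), `sense_index` (codon -> 1..61), and pairwise 61 x 61 matrices
#'   `ndiff`, `synonymous`, `is_transition`.
#' @examples
#' code <- standard_genetic_code()
#' length(code$sense)       # 61
#' code$aa[["TTT"]]         # "F"
#' @export
standard_genetic_code <- function(aa_table = NULL) {
  nucs <- c("T", "C", "A", "G")
  codons <- character(64L)
  k <- 1L
  for (n1 in nucs) for (n2 in nucs) for (n3 in nucs) {
    codons[k] <- paste0(n1, n2, n3)
    k <- k + 1L
  }
  if (is.null(aa_table)) {
    aa64 <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
    names(aa64) <- codons
  } else {
    if (!all(codons %in% names(aa_table)))
      stop("aa_table must name all 64 codons")
    aa64 <- aa_table[codons]
  }
  stop_codons <- names(aa64)[aa64 == "*"]
  sense <- codons[!codons %in% stop_codons]
  aa <- aa64[sense]

  n <- length(sense)
  pos <- do.call(rbind, strsplit(sense, ""))  # n x 3 nucleotide matrix
  ndiff <- matrix(0L, n, n, dimnames = list(sense, sense))
  for (p in 1:3) ndiff <- ndiff + outer(pos[, p], pos[, p], "!=")
  synonymous <- outer(aa, aa, "==")
  dimnames(synonymous) <- list(sense, sense)

  # transition indicator for single-difference pairs (purine<->purine or
  # pyrimidine<->pyrimidine change at the differing position)
  pur <- c("A", "G")
  is_ts <- matrix(FALSE, n, n, dimnames = list(sense, sense))
  for (p in 1:3) {
    d <- outer(pos[, p], pos[, p], "!=")
    same_class <- outer(pos[, p] %in% pur, pos[, p] %in% pur, "==")
    is_ts <- is_ts | (d & same_class & ndiff == 1L)
  }

  structure(
    list(codons = codons, sense = sense, stop = stop_codons,
         aa = aa, sense_index = stats::setNames(seq_len(n), sense),
         ndiff = ndiff, synonymous = synonymous, is_transition = is_ts),
    class = "genetic_code")
}

# cached default code; building it is cheap but it is used everywhere
.kcm_env <- new.env(parent = emptyenv())

get_code <- function(code = NULL) {
  if (!is.null(code)) return(code)
  if (is.null(.kcm_env$code)) .kcm_env$code <- standard_genetic_code()
  .kcm_env$code
}

check_codon <- function(x) {
  bad <- nchar(x) != 3L | grepl("[^TCAG]", x)
  if (any(bad))
    stop("malformed codon(s): ", paste(x[bad], collapse = ", "))
  invisible(x)
}

#' Number of differing positions between two codons
#'
#' @param c1,c2 codons as length-3 strings over T, C, A, G (vectorized).
#' @return integer count(s) in 0..3.
#' @examples
#' num_differences("TTT", "CCA")  # 3
#' @export
num_differences <- function(c1, c2) {
  check_codon(c1); check_codon(c2)
  m1 <- do.call(rbind, strsplit(c1, ""))
  m2 <- do.call(rbind, strsplit(c2, ""))
  as.integer(rowSums(m1 != m2))
}

#' Is a codon change synonymous?
#'
#' True when both sense codons encode the same amino acid.  Stop codons are
#' outside the model's state space and are rejected.
#'
#' @param c1,c2 sense codons (vectorized).
#' @param code a [standard_genetic_code()] object.
#' @export
is_synonymous <- function(c1, c2, code = NULL) {
  code <- get_code(code)
  bad <- !(c1 %in% code$sense) | !(c2 %in% code$sense)
  if (any(bad))
    stop("not a sense codon: ",
         paste(unique(c(c1, c2)[c(bad, bad)]), collapse = ", "))
  unname(code$aa[c1] == code$aa[c2])
}
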