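#' Codon alignment container
#'
#' Stores a codon-aligned set of protein-coding sequences as an integer
#' matrix of sense-codon states (taxa x codon sites, values 1..61 in the
#' canonical codon order, `NA` for gaps or ambiguous codons).
#'
#' @param x either a character matrix of codons (taxa x sites), a character
#'   vector of nucleotide sequences (lengths divisible by 3), or an integer
#'   state matrix.
#' @param taxa taxon labels (required when `x` carries no rownames/names).
#' @param code genetic code object.
#' @return an object of class `codon_alignment`: list with `states` (integer
#'   matrix), `taxa`, `n_sites`.
#' @export
codon_alignment <- function(x, taxa = NULL, code = NULL) {
  code <- get_code(code)
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(taxa)) taxa <- names(x)
    if (is.null(taxa)) stop("taxon labels required")
    x <- toupper(gsub("U", "T", toupper(x)))
    len <- unique(nchar(x))
    if (length(len) != 1L)
      stop("sequences differ in length (", paste(len, collapse = ", "), ")")
    if (len %% 3L != 0L)
      stop("sequence length ", len, " is not divisible by 3")
    x <- do.call(rbind, lapply(x, function(s)
      substring(s, seq(1, len, 3), seq(3, len, 3))))
    rownames(x) <- taxa
  }
  if (is.character(x)) {
    taxa <- if (!is.null(taxa)) taxa else rownames(x)
    if (is.null(taxa)) stop("taxon labels required")
    states <- matrix(NA_integer_, nrow(x), ncol(x))
    clean <- toupper(gsub("U", "T", x))
    known <- clean %in% code$sense
    states[known] <- code$sense_index[clean[known]]
    # stop codons are a frame/validation error, anything else is missing
    stop_hit <- which(matrix(clean %in% code$stop, nrow(clean)), arr.ind = TRUE)
    if (nrow(stop_hit))
      stop(sprintf("in-frame stop codon %s in sequence '%s' at codon site %d",
                   clean[stop_hit[1, , drop = FALSE]],
                   taxa[stop_hit[1, 1]], stop_hit[1, 2]))
  } else {
    states <- x
    taxa <- if (!is.null(taxa)) taxa else rownames(x)
    if (is.null(taxa)) stop("taxon labels required")
    storage.mode(states) <- "integer"
    if (any(states < 1L | states > length(code$sense), na.rm = TRUE))
      stop("codon state indices must be in 1..", length(code$sense))
  }
  if (anyDuplicated(taxa)) stop("duplicate taxon label: ", taxa[duplicated(taxa)][1])
  rownames(states) <- taxa
  structure(list(states = states, taxa = taxa, n_sites = ncol(states)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment:", length(x$taxa), "taxa x", x$n_sites, "codon sites\n")
  invisible(x)
}

#' Read a codon alignment from FASTA or PHYLIP
#'
#' Sequences are uppercased, U mapped to T, and validated: equal lengths
#' divisible by 3, unique taxon labels, no in-frame stop codons (reported
#' with 1-based codon site and sequence name).  Codons containing gaps or
#' ambiguity characters become missing data.
#'
#' @param path input file.
#' @param format `"fasta"` or `"phylip"` (sequential and interleaved PHYLIP
#'   are both understood); default guesses from the first character.
#' @param code genetic code object.
#' @return a [codon_alignment()].
#' @export
read_codon_alignment <- function(path, format = c("auto", "fasta", "phylip"),
                                 code = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  if (format == "fasta") {
    seqs <- unlist(seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                                      seqonly = FALSE))
  } else {
    mat <- tryCatch(ape::read.dna(path, format = "sequential", as.character = TRUE),
                    error = function(e)
                      ape::read.dna(path, format = "interleaved", as.character = TRUE))
    seqs <- apply(mat, 1, paste0, collapse = "")
  }
  codon_alignment(seqs, taxa = names(seqs), code = code)
}

#' Write a codon alignment as FASTA
#'
#' @param aln a [codon_alignment()].
#' @param path output file.
#' @param code genetic code object.
#' @export
write_codon_fasta <- function(aln, path, code = NULL) {
  code <- get_code(code)
  txt <- character(2L * length(aln$taxa))
  for (i in seq_along(aln$taxa)) {
    s <- aln$states[i, ]
    cods <- ifelse(is.na(s), "---", code$sense[s])
    txt[2L * i - 1L] <- paste0(">", aln$taxa[i])
    txt[2L * i] <- paste0(cods, collapse = "")
  }
  writeLines(txt, path)
  invisible(path)
}

#' Read and validate a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that checks branch lengths are
#' present and nonnegative, and (optionally) that leaf labels match an
#' alignment's taxa.
#'
#' @param path Newick file.
#' @param aln optional [codon_alignment()] to validate taxa against.
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(path, aln = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths: ", path)
  if (any(tree$edge.length < 0))
    stop("negative branch length in tree: ", path)
  if (!is.null(aln)) {
    orphans <- setdiff(tree$tip.label, aln$taxa)
    missing <- setdiff(aln$taxa, tree$tip.label)
    if (length(orphans) || length(missing))
      stop("tree/alignment taxon mismatch; in tree only: [",
           paste(orphans, collapse = ", "), "]; in alignment only: [",
           paste(missing, collapse = ", "), "]")
  }
  tree
}

#' Serialize a fit (or any result list) to JSON
#'
#' Numeric vectors are written in full precision together with the package
#' version, so a fit can be reloaded and its AICc re-derived exactly.
#'
#' @param x a result object (e.g. from [fit_codon_model()]).
#' @param path output path.
#' @export
write_results_json <- function(x, path) {
  x$package_version <- as.character(utils::packageVersion("kcm"))
  if (inherits(x, "kcm_fit")) {
    x$tree_newick <- ape::write.tree(x$tree)
    x$Q <- NULL          # rebuildable from spec + params + frequencies
    x$spec <- unclass(x$spec)
    x$freqs <- unclass(x$freqs)
  }
  x$tree <- NULL
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
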