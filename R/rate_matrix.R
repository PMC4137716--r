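#' Per-position nucleotide exchangeability matrix
#'
#' One symmetric 4 x 4 exchangeability matrix per codon position.  The
#' diagonal is fixed to 1 exactly: in the Kronecker product an unchanged
#' position then contributes a unit factor, so a single-nucleotide codon
#' change picks up exactly one rate, a double change the product of two, and
#' a triple change the product of three.  The global magnitude of the six
#' rates is therefore meaningful when multi-hit substitutions are allowed
#' (it sets the single : double : triple balance) even though the final
#' generator is rescaled to unit mean rate.
#'
#' @param rates six nonnegative rates for the unordered nucleotide pairs, in
#'   order TC, TA, TG, CA, CG, AG (a named vector is reordered by name).
#' @param position codon position in 1..3 (metadata only).
#' @return a 4 x 4 symmetric matrix with unit diagonal, rows/cols T, C, A, G,
#'   with attributes `rates` and `position`.
#' @examples
#' nuc_exchange_matrix(c(TC = 2, TA = 1, TG = 1, CA = 1, CG = 1, AG = 2))
#' @export
nuc_exchange_matrix <- function(rates, position = 1L) {
  pair_names <- c("TC", "TA", "TG", "CA", "CG", "AG")
  if (!is.null(names(rates))) {
    nm <- names(rates)
    nm[nm == "GA"] <- "AG"  # tolerate either spelling of the purine pair
    if (!setequal(nm, pair_names)) stop("rate names must be ", paste(pair_names, collapse = ", "))
    rates <- rates[match(pair_names, nm)]
  }
  if (length(rates) != 6L || any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be six finite nonnegative numbers")
  nucs <- c("T", "C", "A", "G")
  q <- diag(4)
  dimnames(q) <- list(nucs, nucs)
  q["T", "C"] <- q["C", "T"] <- rates[1]
  q["T", "A"] <- q["A", "T"] <- rates[2]
  q["T", "G"] <- q["G", "T"] <- rates[3]
  q["C", "A"] <- q["A", "C"] <- rates[4]
  q["C", "G"] <- q["G", "C"] <- rates[5]
  q["A", "G"] <- q["G", "A"] <- rates[6]
  attr(q, "rates") <- stats::setNames(as.numeric(rates), pair_names)
  attr(q, "position") <- as.integer(position)
  q
}

#' Kronecker kernel over sense codons
#'
#' Forms `q1 %x% q2 %x% q3` over the 64-codon space (canonical T, C, A, G
#' order, third position fastest) and deletes the stop-codon rows and
#' columns.  The entry for a codon pair differing at positions S is the
#' product over p in S of position p's nucleotide rate; the unit diagonals
#' supply identity factors at unchanged positions.
#'
#' @param q1,q2,q3 matrices from [nuc_exchange_matrix()].
#' @param code genetic code object.
#' @return symmetric 61 x 61 matrix with unit diagonal.
#' @export
kronecker_kernel <- function(q1, q2, q3, code = NULL) {
  code <- get_code(code)
  K <- (q1 %x% (q2 %x% q3))
  dimnames(K) <- list(code$codons, code$codons)
  K[code$sense, code$sense]
}

#' Codon equilibrium frequencies
#'
#' Container for the 61 sense-codon frequencies under one of three schemes:
#' `EQUAL` (all 1/61), `F3X4` (product of per-position nucleotide
#' frequencies, renormalized over sense codons) or `F61` (observed codon
#' proportions).
#'
#' @param pi 61 positive frequencies summing to 1 (named by sense codon or
#'   in canonical order).
#' @param mode one of `"EQUAL"`, `"F3X4"`, `"F61"`.
#' @param position_freqs optional 3 x 4 per-position nucleotide frequencies
#'   (rows = codon position, cols = T, C, A, G), kept when mode is F3X4.
#' @param code genetic code object.
#' @export
codon_frequencies <- function(pi = NULL, mode = c("EQUAL", "F3X4", "F61"),
                              position_freqs = NULL, code = NULL) {
  mode <- match.arg(mode)
  code <- get_code(code)
  n <- length(code$sense)
  if (mode == "EQUAL") {
    pi <- rep(1 / n, n)
  } else {
    if (is.null(pi)) stop("pi required for mode ", mode)
    if (!is.null(names(pi))) pi <- pi[code$sense]
    if (length(pi) != n || any(!is.finite(pi)) || any(pi <= 0))
      stop("pi must be ", n, " positive finite frequencies")
    pi <- pi / sum(pi)
  }
  names(pi) <- code$sense
  structure(list(pi = pi, mode = mode, position_freqs = position_freqs),
            class = "codon_frequencies")
}

#' Estimate codon frequencies from an alignment
#'
#' `EQUAL` ignores the data; `F3X4` counts nucleotide frequencies at each of
#' the three codon positions over all sequences and sets each codon's
#' frequency proportional to the product of its positional nucleotide
#' frequencies, renormalized over the 61 sense codons; `F61` uses observed
#' sense-codon proportions.  Zero counts receive a pseudocount so that no
#' stationary frequency is exactly zero (which would make the generator
#' singular).
#'
#' @param aln a [codon_alignment()].
#' @param mode frequency scheme.
#' @param code genetic code object.
#' @param pseudocount added to zero cells before normalization (default 0.5).
#' @return a [codon_frequencies()] object.
#' @export
estimate_frequencies <- function(aln, mode = c("F3X4", "F61", "EQUAL"),
                                 code = NULL, pseudocount = 0.5) {
  mode <- match.arg(mode)
  code <- get_code(code)
  if (mode == "EQUAL") return(codon_frequencies(mode = "EQUAL", code = code))
  idx <- aln$states[!is.na(aln$states)]
  if (!length(idx)) stop("alignment contains no observed codons")
  if (mode == "F61") {
    counts <- tabulate(idx, nbins = length(code$sense))
    counts[counts == 0] <- pseudocount
    return(codon_frequencies(counts / sum(counts), mode = "F61", code = code))
  }
  # F3X4: per-position nucleotide counts over the observed codons
  nucs <- c("T", "C", "A", "G")
  pos <- do.call(rbind, strsplit(code$sense[idx], ""))
  pf <- matrix(0, 3, 4, dimnames = list(NULL, nucs))
  for (p in 1:3) {
    cnt <- table(factor(pos[, p], levels = nucs))
    cnt[cnt == 0] <- pseudocount
    pf[p, ] <- cnt / sum(cnt)
  }
  sense_pos <- do.call(rbind, strsplit(code$sense, ""))
  pi <- unname(pf[1, sense_pos[, 1]] * pf[2, sense_pos[, 2]] * pf[3, sense_pos[, 3]])
  codon_frequencies(pi, mode = "F3X4", position_freqs = pf, code = code)
}

# assemble a generator from an exchangeability kernel (61x61 symmetric,
# diagonal ignored), frequencies, omega on nonsynonymous and alpha on
# multi-hit entries; fix the diagonal and scale to unit mean rate.
finalize_generator <- function(K, freqs, omega, alpha, code,
                               omega_on = NULL) {
  pi <- freqs$pi
  n <- length(pi)
  if (is.null(omega_on)) omega_on <- !code$synonymous
  Q <- K * rep(pi, each = n)           # K_ij * pi_j
  Q[omega_on] <- Q[omega_on] * omega
  multi <- code$ndiff > 1L
  if (alpha != 1) Q[multi] <- Q[multi] * alpha
  diag(Q) <- 0
  total <- sum(pi * rowSums(Q))
  if (total <= 0) stop("degenerate generator: no off-diagonal substitution mass")
  Q <- Q / total
  diag(Q) <- -rowSums(Q)
  structure(list(Q = Q, pi = pi, freqs = freqs, omega = omega,
                 alpha = alpha, scale_factor = total),
            class = "codon_rate_matrix")
}

#' Build a KCM codon generator
#'
#' Assembles the 61 x 61 generator from three per-position nucleotide
#' exchangeability matrices: the Kronecker kernel entry for codons i -> j is
#' multiplied by the target codon's equilibrium frequency, by `omega` when
#' the change is nonsynonymous, and by `alpha` (0 or 1) when it alters more
#' than one nucleotide.  The diagonal is then set to minus the row sums and
#' the matrix divided by the mean rate at equilibrium, so branch lengths are
#' expected substitutions per codon (a double or triple change counting as
#' one event).
#'
#' @param q1,q2,q3 per-position matrices from [nuc_exchange_matrix()].
#' @param freqs a [codon_frequencies()] object.
#' @param omega dN/dS multiplier (> 0).
#' @param alpha multi-hit switch, 0 (single-hit only) or 1.
#' @param code genetic code object.
#' @return a `codon_rate_matrix`: list with `Q`, `pi`, `freqs`, `omega`,
#'   `alpha` and `scale_factor` (the divisor applied to reach unit mean rate).
#' @examples
#' q <- nuc_exchange_matrix(rep(1, 6))
#' m <- build_kcm_Q(q, q, q, codon_frequencies(mode = "EQUAL"), omega = 1, alpha = 1)
#' max(abs(rowSums(m$Q)))  # ~0
#' @export
build_kcm_Q <- function(q1, q2, q3, freqs, omega = 1, alpha = 1, code = NULL) {
  code <- get_code(code)
  if (!is.finite(omega) || omega <= 0) stop("omega must be positive")
  if (!alpha %in% c(0, 1)) stop("alpha must be 0 or 1")
  K <- kronecker_kernel(q1, q2, q3, code)
  finalize_generator(K, freqs, omega, alpha, code)
}

#' Build the M0 baseline generator
#'
#' The classical single-hit mechanistic codon model: substitutions changing
#' more than one nucleotide are forbidden; a single-nucleotide change i -> j
#' has rate pi_j times `kappa` if it is a transition (T<->C or A<->G), times
#' `omega` if nonsynonymous.  Equivalent to the Kronecker construction with
#' alpha = 0 and every position sharing one transition/transversion matrix.
#'
#' @inheritParams build_kcm_Q
#' @param kappa transition/transversion rate ratio (> 0).
#' @export
build_m0_Q <- function(kappa, omega, freqs, code = NULL) {
  code <- get_code(code)
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be positive")
  if (!is.finite(omega) || omega <= 0) stop("omega must be positive")
  K <- matrix(0, 61, 61, dimnames = dimnames(code$ndiff))
  K[code$ndiff == 1L] <- 1
  K[code$is_transition] <- kappa
  out <- finalize_generator(K, freqs, omega, alpha = 0, code = code)
  out$kappa <- kappa
  out
}

#' Expected fraction of multi-hit substitution events
#'
#' The flux-weighted proportion of substitution events that change two or
#' three nucleotides at once: sum of pi_i Q_ij over pairs differing at more
#' than one position, divided by the total off-diagonal flux.  Invariant
#' under global rescaling of the generator.
#'
#' @param Q a `codon_rate_matrix`.
#' @param code genetic code object.
#' @param weighted if `FALSE`, report instead the unweighted proportion of
#'   nonzero multi-hit entries among nonzero off-diagonal entries
#'   (a structural diagnostic, not an event rate).
#' @return a number in \[0, 1\].
#' @export
multi_hit_fraction <- function(Q, code = NULL, weighted = TRUE) {
  code <- get_code(code)
  M <- Q$Q
  diag(M) <- 0
  multi <- code$ndiff > 1L
  if (!weighted) {
    nz <- M > 0
    return(sum(nz & multi) / sum(nz))
  }
  flux <- Q$pi * M  # pi_i Q_ij
  sum(flux[multi]) / sum(flux)
}

#' Export / import rate matrices as whitespace-delimited text
#'
#' Writes the 61 x 61 generator (sense-codon order) or its 64 x 64 embedding
#' (canonical codon order, stop rows/columns zero) row-major, preceded by a
#' one-line `#` header naming the ordering convention.  `read_rate_matrix`
#' accepts either dimension; a 64 x 64 input is reduced to sense codons.
#'
#' @param Q a `codon_rate_matrix` (write) .
#' @param path file path.
#' @param dim one of 61 or 64.
#' @param code genetic code object.
#' @export
write_rate_matrix <- function(Q, path, dim = c(61, 64), code = NULL) {
  code <- get_code(code)
  dim <- match.arg(as.character(dim[1]), c("61", "64"))
  M <- Q$Q
  if (dim == "64") {
    full <- matrix(0, 64, 64, dimnames = list(code$codons, code$codons))
    full[code$sense, code$sense] <- M
    M <- full
    hdr <- "# 64x64 codon rate matrix, rows/cols in T,C,A,G order, third position fastest (TTT..GGG)"
  } else {
    hdr <- "# 61x61 sense-codon rate matrix, canonical T,C,A,G order, third position fastest, stops removed"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(M, digits = 17), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_matrix
#' @return `read_rate_matrix`: a numeric 61 x 61 matrix in sense-codon order.
#' @export
read_rate_matrix <- function(path, code = NULL) {
  code <- get_code(code)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  vals <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  n <- length(vals)
  if (!n %in% c(61L, 64L) || any(lengths(vals) != n))
    stop("rate matrix file must be square, 61x61 or 64x64; got ", n, " rows")
  M <- do.call(rbind, vals)
  if (any(!is.finite(M))) stop("non-numeric entries in rate matrix file")
  if (n == 64L) {
    dimnames(M) <- list(code$codons, code$codons)
    M <- M[code$sense, code$sense]
  } else {
    dimnames(M) <- list(code$sense, code$sense)
  }
  M
}
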