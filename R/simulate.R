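#' Random phylogeny with lognormal branch lengths
#'
#' Uniform random binary topology (via [ape::rtree()]) with every branch
#' length drawn independently from a lognormal distribution.  By default
#' `bl_mean` and `bl_sd` are the arithmetic mean and SD of the branch
#' lengths (default 0.41 and 0.34 expected substitutions per codon, about
#' 11.5 substitutions per codon of total tree length on 15 taxa); with
#' `log_params = TRUE` they are taken directly as the lognormal's
#' meanlog/sdlog, which gives much more divergent trees.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param bl_mean,bl_sd branch-length mean and SD (or meanlog/sdlog when
#'   `log_params = TRUE`).
#' @param log_params interpret `bl_mean`/`bl_sd` on the log scale.
#' @param seed optional integer seed; `NULL` leaves the RNG state alone.
#' @return an [ape::phylo] rooted binary tree with `2 n_taxa - 2` edges.
#' @export
random_tree <- function(n_taxa, bl_mean = 0.41, bl_sd = 0.34,
                        log_params = FALSE, seed = NULL) {
  if (n_taxa < 3) stop("n_taxa must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  p <- lnorm_params(bl_mean, bl_sd, log_params)
  ape::rtree(n_taxa, br = function(n) stats::rlnorm(n, p[1], p[2]))
}

# convert arithmetic mean/sd of a lognormal to meanlog/sdlog
lnorm_params <- function(m, s, log_params = FALSE) {
  if (log_params) return(c(m, s))
  if (m <= 0 || s <= 0) stop("branch-length mean and sd must be positive")
  sdlog <- sqrt(log(1 + (s / m)^2))
  c(log(m) - sdlog^2 / 2, sdlog)
}

#' Simulation scheme definitions
#'
#' A scheme describes how a generating codon rate matrix is built for the
#' simulation study:
#'
#' * `A` - the single-hit M0 generator itself (no multi-hit substitutions);
#' * `B`, `C`, `D` - the M0 generator augmented with one random
#'   double/triple exchangeability per multi-difference sense-codon pair,
#'   drawn as the absolute value of a Normal with scheme-specific mean and
#'   SD: B |N(0.0001, 0.03)|, C |N(0.001, 0.1)|, D |N(0.1, 0.1)|.  With the
#'   default base kappa these levels translate into roughly 11%, 30% and
#'   38% of substitution events being double or triple;
#' * `EXTERNAL` - a user-supplied 61 x 61 or 64 x 64 rate matrix loaded
#'   from `external_matrix` (see [read_rate_matrix()]).
#'
#' @param name scheme name.
#' @param base_kappa transition/transversion ratio of the M0 base matrix
#'   (default 1.4; see the methods vignette).
#' @param perturb_mean,perturb_sd override the scheme's Normal parameters.
#' @param external_matrix path to a rate-matrix file (EXTERNAL only).
#' @return a `simulation_scheme` list.
#' @export
simulation_scheme <- function(name = c("A", "B", "C", "D", "EXTERNAL"),
                              base_kappa = 1.4,
                              perturb_mean = NULL, perturb_sd = NULL,
                              external_matrix = NULL) {
  name <- match.arg(name)
  defaults <- list(A = c(NA, NA), B = c(1e-4, 0.03),
                   C = c(1e-3, 0.1), D = c(0.1, 0.1),
                   EXTERNAL = c(NA, NA))[[name]]
  if (name == "EXTERNAL" && is.null(external_matrix))
    stop("EXTERNAL scheme requires external_matrix")
  structure(list(name = name, base_kappa = base_kappa,
                 perturb_mean = if (is.null(perturb_mean)) defaults[1] else perturb_mean,
                 perturb_sd = if (is.null(perturb_sd)) defaults[2] else perturb_sd,
                 external_matrix = external_matrix),
            class = "simulation_scheme")
}

#' Build the generating rate matrix of a simulation scheme
#'
#' Scheme A is the M0 generator with the scheme's kappa and omega equal to
#' `omega_factor`.  Schemes B-D start from the raw M0 exchangeabilities
#' (kappa for transitions, 1 for transversions), install one folded-normal
#' draw per unordered multi-difference sense-codon pair as a symmetric
#' exchangeability, multiply every entry by the target codon frequency and
#' every nonsynonymous entry by `omega_factor`, then fix the diagonal and
#' scale to unit mean rate.  EXTERNAL loads a rate matrix from file,
#' multiplies every nonsynonymous entry by `omega_factor`, and re-applies
#' the diagonal fix and scaling with the matrix's stationary distribution.
#'
#' @param scheme scheme name or [simulation_scheme()] object.
#' @param omega_factor multiplier on all nonsynonymous rates.
#' @param freqs codon frequencies of the generator (default equal, 1/61).
#' @param code genetic code object.
#' @param seed optional seed for the perturbation draws.
#' @return a `codon_rate_matrix`.
#' @export
build_scheme_matrix <- function(scheme, omega_factor = 1, freqs = NULL,
                                code = NULL, seed = NULL) {
  code <- get_code(code)
  if (is.character(scheme)) scheme <- simulation_scheme(scheme)
  if (is.null(freqs)) freqs <- codon_frequencies(mode = "EQUAL", code = code)
  if (!is.null(seed)) set.seed(seed)

  if (scheme$name == "EXTERNAL") {
    M <- read_rate_matrix(scheme$external_matrix, code)
    diag(M) <- 0
    if (any(M < 0)) stop("external rate matrix has negative off-diagonal entries")
    M[!code$synonymous] <- M[!code$synonymous] * omega_factor
    pi <- stationary_distribution(M)
    total <- sum(pi * rowSums(M))
    if (total <= 0) stop("degenerate external matrix")
    Q <- M / total
    diag(Q) <- -rowSums(Q)
    db <- max(abs(pi * Q - t(pi * Q)))
    if (db > 1e-8)
      warning("external matrix violates detailed balance (max |pi_i Q_ij - pi_j Q_ji| = ",
              signif(db, 3), "); likelihood computations assume reversibility")
    return(structure(list(Q = Q, pi = pi,
                          freqs = codon_frequencies(pi, mode = "F61", code = code),
                          omega = omega_factor, alpha = 1, scale_factor = total),
                     class = "codon_rate_matrix"))
  }

  if (scheme$name == "A")
    return(build_m0_Q(scheme$base_kappa, omega_factor, freqs, code))

  # B/C/D: M0 exchangeabilities plus folded-normal multi-hit exchangeabilities
  S <- matrix(0, 61, 61, dimnames = dimnames(code$ndiff))
  S[code$ndiff == 1L] <- 1
  S[code$is_transition] <- scheme$base_kappa
  multi <- which(code$ndiff > 1L & upper.tri(S), arr.ind = TRUE)
  draws <- abs(stats::rnorm(nrow(multi), scheme$perturb_mean, scheme$perturb_sd))
  S[multi] <- draws
  S[multi[, c(2, 1)]] <- draws
  finalize_generator(S, freqs, omega = omega_factor, alpha = 1, code = code)
}

# stationary distribution of a generator given only off-diagonal rates
stationary_distribution <- function(M) {
  Q <- M
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  e <- eigen(t(Q))
  i <- which.min(abs(e$values))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Simulate a codon alignment along a tree
#'
#' Draws each site's root codon from the generator's stationary
#' distribution and evolves it down the tree.  The default method samples
#' each child state from the parent's row of P(t) = exp(Qt); the
#' `"gillespie"` method simulates the exact jump chain event by event and
#' additionally records how many nucleotides each substitution event
#' changed (attribute `"events"`: counts of single/double/triple hits),
#' which is what makes the multi-hit flux of a generator observable.
#'
#' @param tree an [ape::phylo] tree with branch lengths in expected
#'   substitutions per codon.
#' @param Q a `codon_rate_matrix`.
#' @param n_codons number of codon sites (>= 1).
#' @param seed optional integer seed.
#' @param method `"matrix"` (transition-probability sampling) or
#'   `"gillespie"` (exact event simulation).
#' @param code genetic code object.
#' @return a [codon_alignment()] of the tip sequences; for
#'   `method = "gillespie"` with attribute `events` = named counts of
#'   substitution events by hit multiplicity (1, 2, 3).
#' @export
simulate_alignment <- function(tree, Q, n_codons, seed = NULL,
                               method = c("matrix", "gillespie"),
                               code = NULL) {
  method <- match.arg(method)
  code <- get_code(code)
  if (n_codons < 1) stop("n_codons must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ns <- length(Q$pi)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- matrix(NA_integer_, ntip + tree$Nnode, n_codons)
  states[root, ] <- sample.int(ns, n_codons, replace = TRUE, prob = Q$pi)
  events <- c(`1` = 0L, `2` = 0L, `3` = 0L)

  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    t_e <- tree$edge.length[e]
    x <- states[par, ]
    if (method == "matrix") {
      P <- transition_matrix(Q, t_e)
      y <- integer(n_codons)
      for (s in unique(x)) {
        i <- which(x == s)
        y[i] <- sample.int(ns, length(i), replace = TRUE, prob = P[s, ])
      }
    } else {
      y <- x
      for (site in seq_len(n_codons)) {
        s <- y[site]; remaining <- t_e
        repeat {
          rate <- -Q$Q[s, s]
          if (rate <= 0) break
          dt <- stats::rexp(1, rate)
          if (dt > remaining) break
          remaining <- remaining - dt
          probs <- Q$Q[s, ]; probs[s] <- 0
          s_new <- sample.int(ns, 1L, prob = probs)
          nd <- code$ndiff[s, s_new]
          events[nd] <- events[nd] + 1L
          s <- s_new
        }
        y[site] <- s
      }
    }
    states[chi, ] <- y
  }
  aln <- codon_alignment(states[seq_len(ntip), , drop = FALSE],
                         taxa = tree$tip.label, code = code)
  if (method == "gillespie") attr(aln, "events") <- events
  aln
}
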