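#' Transition probability matrix of a reversible generator
#'
#' Computes P(t) = exp(Qt) through the symmetric eigendecomposition of
#' D^(1/2) Q D^(-1/2) (D = diag(pi)), which is valid because every generator
#' built by this package satisfies detailed balance.  Tiny negative entries
#' from rounding are clamped to zero.
#'
#' @param Q a `codon_rate_matrix` (or any list with `Q` and `pi`).
#' @param t branch length (>= 0), expected substitutions per codon.
#' @return a stochastic matrix of the generator's dimension.
#' @export
transition_matrix <- function(Q, t) {
  if (!is.finite(t) || t < 0) stop("t must be a nonnegative number")
  P <- cpp_transition_matrix(Q$Q, Q$pi, t)
  dimnames(P) <- dimnames(Q$Q)
  P
}

# -- internal tree plumbing ---------------------------------------------------

# Reorder an ape tree postorder and extract the pieces the C++ engine needs.
prep_tree <- function(tree, taxa) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  orphans <- setdiff(tree$tip.label, taxa)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(orphans) || length(missing))
    stop("tree/alignment taxon mismatch; in tree only: [",
         paste(orphans, collapse = ", "), "]; in alignment only: [",
         paste(missing, collapse = ", "), "]")
  tree <- ape::reorder.phylo(tree, "postorder")
  list(edge = tree$edge, edge_len = tree$edge.length,
       tip_order = tree$tip.label, n_node = tree$Nnode)
}

# Compress alignment columns (rows = taxa in tree tip order) into unique
# patterns with multiplicities.
compress_patterns <- function(states) {
  key <- apply(states, 2, paste0, collapse = "\r")
  first <- !duplicated(key)
  w <- as.numeric(table(key)[key[first]])
  list(pat = states[, first, drop = FALSE], w = w)
}

# generic engine shared by codon and nucleotide fits
engine_loglik <- function(Qmat, pi, prep, states) {
  cp <- compress_patterns(states)
  cpp_loglik(Qmat, pi, prep$edge, prep$edge_len, cp$pat, cp$w, prep$n_node)
}

#' Log-likelihood of a codon alignment on a tree
#'
#' Felsenstein pruning over compressed site patterns, with the stationary
#' distribution at the root and per-node rescaling for numerical stability.
#' Gaps and ambiguous codons contribute a partial likelihood of 1 over all
#' states.  For a reversible generator the result is invariant to root
#' placement, so rooted and unrooted trees give the same value.
#'
#' @param tree an [ape::phylo] tree with branch lengths in expected
#'   substitutions per codon.
#' @param aln a [codon_alignment()].
#' @param Q a `codon_rate_matrix` from [build_kcm_Q()] or [build_m0_Q()].
#' @return the log-likelihood (sum over sites).
#' @export
log_likelihood <- function(tree, aln, Q) {
  prep <- prep_tree(tree, aln$taxa)
  states <- aln$states[prep$tip_order, , drop = FALSE]
  ll <- engine_loglik(Q$Q, Q$pi, prep, states)
  if (!is.finite(ll))
    stop("non-finite log-likelihood (degenerate generator or underflow)")
  ll
}

# -- positional GTR -----------------------------------------------------------

gtr_generator <- function(rates, base_freq) {
  # rates: TC, TA, TG, CA, CG, AG with AG as reference handled by caller
  q <- nuc_exchange_matrix(rates)
  diag(q) <- 0
  Q <- q * rep(base_freq, each = 4)
  total <- sum(base_freq * rowSums(Q))
  Q <- Q / total
  diag(Q) <- -rowSums(Q)
  list(Q = Q, pi = base_freq)
}

#' Fit a 4-state GTR model to one codon position
#'
#' Extracts the nucleotide column at the given codon position of every site,
#' then fits a general time-reversible nucleotide model (five free relative
#' rates with the G-T rate as reference, empirical base frequencies, and a
#' single branch-length scale) by maximum likelihood with the same pruning
#' engine used for codon models.  This is the per-position partitioned
#' analysis against which the fitted per-position matrices of the codon
#' model can be compared.
#'
#' @param aln a [codon_alignment()].
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param position codon position, 1, 2 or 3.
#' @param code genetic code object.
#' @return list with `rates` (six relative rates, G-T = 1), `base_freq`,
#'   `branch_scale`, `lnL`, `converged`, `degenerate`.
#' @export
fit_positional_gtr <- function(aln, tree, position, code = NULL) {
  if (!position %in% 1:3) stop("position must be 1, 2 or 3")
  code <- get_code(code)
  nucs <- c("T", "C", "A", "G")
  pos_nuc <- substring(code$sense, position, position)
  nuc_idx <- match(pos_nuc, nucs)  # sense codon state -> nucleotide state
  states <- matrix(nuc_idx[aln$states], nrow(aln$states),
                   dimnames = list(aln$taxa, NULL))
  prep <- prep_tree(tree, aln$taxa)
  states <- states[prep$tip_order, , drop = FALSE]
  cnt <- tabulate(states[!is.na(states)], 4)
  degenerate <- sum(cnt > 0) < 2 ||
    all(apply(states, 2, function(col) length(unique(stats::na.omit(col))) <= 1))
  if (degenerate)
    warning("position ", position, ": alignment column set carries no substitution signal")
  cnt[cnt == 0] <- 0.5
  base_freq <- cnt / sum(cnt)

  obj <- function(par) {
    r <- exp(par[1:5])
    # free rates TC, TA, CA, CG, AG; the G-T rate is the fixed reference
    g <- gtr_generator(c(r[1], r[2], 1, r[3], r[4], r[5]), base_freq)
    prep2 <- prep
    prep2$edge_len <- prep$edge_len * exp(par[6])
    -engine_loglik(g$Q, g$pi, prep2, states)
  }
  fit <- stats::optim(c(rep(0, 5), 0), obj, method = "L-BFGS-B",
                      lower = c(rep(log(1e-6), 5), log(1e-4)),
                      upper = c(rep(log(1e4), 5), log(1e4)),
                      control = list(maxit = 500))
  r <- exp(fit$par[1:5])
  rates <- c(TC = r[1], TA = r[2], TG = 1, CA = r[3], CG = r[4], AG = r[5])
  list(rates = rates, base_freq = stats::setNames(base_freq, nucs),
       branch_scale = exp(fit$par[6]), lnL = -fit$value,
       converged = fit$convergence == 0, degenerate = degenerate)
}
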