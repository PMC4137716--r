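# shared fixtures, built in code at test time

code <- standard_genetic_code()

# brute-force Kronecker oracle: triple loop with explicit index arithmetic
# over the full 64 x 64 product, then stop-row/column deletion
oracle_kronecker <- function(q1, q2, q3) {
  nucs <- c("T", "C", "A", "G")
  full <- matrix(0, 64, 64)
  cods <- character(64)
  k <- 0L
  for (a in 1:4) for (b in 1:4) for (d in 1:4) {
    k <- k + 1L
    cods[k] <- paste0(nucs[a], nucs[b], nucs[d])
  }
  idx <- function(a, b, d) (a - 1L) * 16L + (b - 1L) * 4L + d
  for (a1 in 1:4) for (b1 in 1:4) for (d1 in 1:4)
    for (a2 in 1:4) for (b2 in 1:4) for (d2 in 1:4)
      full[idx(a1, b1, d1), idx(a2, b2, d2)] <-
        q1[a1, a2] * q2[b1, b2] * q3[d1, d2]
  dimnames(full) <- list(cods, cods)
  sense <- setdiff(cods, c("TAA", "TAG", "TGA"))
  full[sense, sense]
}

random_q <- function() nuc_exchange_matrix(stats::runif(6, 0.2, 3))

random_kcm_Q <- function(alpha = 1, omega = NULL, freqs = NULL) {
  if (is.null(omega)) omega <- stats::runif(1, 0.2, 2)
  if (is.null(freqs)) {
    p <- stats::rgamma(61, 5, 1)
    freqs <- codon_frequencies(p / sum(p), mode = "F61")
  }
  build_kcm_Q(random_q(), random_q(), random_q(), freqs, omega, alpha)
}

# small deterministic alignment used by several io/likelihood tests
toy_alignment <- function(n_taxa = 4, n_codons = 20, seed = 7) {
  set.seed(seed)
  tr <- random_tree(n_taxa, 0.5, 0.25)
  Q <- build_m0_Q(2, 0.5, codon_frequencies(mode = "EQUAL"))
  list(tree = tr, Q = Q, aln = simulate_alignment(tr, Q, n_codons))
}

# heavier simulation-and-refit studies shared between acceptance blocks are
# computed once per test run and cached here
.study_cache <- new.env(parent = emptyenv())

cached_study <- function(key, builder) {
  if (is.null(.study_cache[[key]])) .study_cache[[key]] <- builder()
  .study_cache[[key]]
}

# explicit marginalization over all internal-node state assignments;
# independent of the pruning engine
brute_force_loglik <- function(tree, aln, Q) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  ns <- length(Q$pi)
  Ps <- lapply(tree$edge.length, function(t) transition_matrix(Q, t))
  states <- aln$states[tree$tip.label, , drop = FALSE]
  root <- tree$edge[nrow(tree$edge), 1]
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), nn)))
  node_state <- function(node, assign, site) {
    if (node <= ntip) states[node, site] else assign[node - ntip]
  }
  ll <- 0
  for (site in seq_len(ncol(states))) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      assign <- grid[g, ]
      p <- Q$pi[[assign[root - ntip]]]
      for (e in seq_len(nrow(tree$edge)))
        p <- p * Ps[[e]][node_state(tree$edge[e, 1], assign, site),
                         node_state(tree$edge[e, 2], assign, site)]
      tot <- tot + p
    }
    ll <- ll + log(tot)
  }
  ll
}

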