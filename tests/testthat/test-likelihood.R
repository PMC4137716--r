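test_that("transition matrices match independent exponentiation oracles", {
  set.seed(20)
  Q <- random_kcm_Q()
  P0 <- transition_matrix(Q, 0)
  expect_equal(unname(P0), diag(61), tolerance = 1e-12)

  P <- transition_matrix(Q, 0.3)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  expect_gte(min(P), 0)
  skip_if_not_installed("Matrix")
  # scaling-and-squaring oracle
  Pexp <- as.matrix(Matrix::expm(Matrix::Matrix(Q$Q * 0.3)))
  expect_equal(unname(P), unname(Pexp), tolerance = 1e-9)
  # ergodic limit: every row converges to the stationary distribution
  Pinf <- transition_matrix(Q, 500)
  expect_lt(max(abs(sweep(Pinf, 2, Q$pi))), 1e-6)
})

test_that("Chapman-Kolmogorov holds on random generators", {
  set.seed(21)
  for (i in 1:3) {
    Q <- random_kcm_Q(alpha = i %% 2)
    s <- runif(1, 0.05, 1); t <- runif(1, 0.05, 1)
    expect_equal(transition_matrix(Q, s) %*% transition_matrix(Q, t),
                 transition_matrix(Q, s + t), tolerance = 1e-8)
  }
})

test_that("pruning equals brute-force marginalization on small trees", {
  set.seed(22)
  for (n_taxa in 3:4) {
    tr <- random_tree(n_taxa)
    Q <- random_kcm_Q(alpha = 1)
    aln <- simulate_alignment(tr, Q, 3)
    expect_equal(log_likelihood(tr, aln, Q), brute_force_loglik(tr, aln, Q),
                 tolerance = 1e-10)
  }
})

test_that("two-taxon single-site likelihood matches the closed form", {
  Q <- build_m0_Q(2, 0.5, codon_frequencies(mode = "EQUAL"))
  tr <- ape::read.tree(text = "(a:0.2,b:0.4);")
  cstate <- code$sense_index[["TTC"]]
  aln <- codon_alignment(matrix(cstate, 2, 1), taxa = c("a", "b"))
  P1 <- transition_matrix(Q, 0.2); P2 <- transition_matrix(Q, 0.4)
  closed <- log(sum(Q$pi * P1[, cstate] * P2[, cstate]))
  expect_equal(log_likelihood(tr, aln, Q), closed, tolerance = 1e-10)

  # at t = 0 the site likelihood is just the codon's frequency
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  expect_equal(log_likelihood(tr0, aln, Q), log(Q$pi[[cstate]]),
               tolerance = 1e-12)
})

test_that("pattern multiplicity, missing data and re-rooting behave", {
  fx <- toy_alignment(5, 30)
  ll <- log_likelihood(fx$tree, fx$aln, fx$Q)

  # duplicating every column doubles the log-likelihood exactly
  dup <- codon_alignment(cbind(fx$aln$states, fx$aln$states),
                         taxa = fx$aln$taxa)
  expect_equal(log_likelihood(fx$tree, dup, fx$Q), 2 * ll, tolerance = 1e-9)

  # an all-missing taxon contributes nothing beyond its branch integral;
  # likelihood stays finite and is bounded above by the complete-data case
  miss <- fx$aln
  miss$states[2, ] <- NA_integer_
  ll_miss <- log_likelihood(fx$tree, codon_alignment(miss$states, taxa = fx$aln$taxa), fx$Q)
  expect_true(is.finite(ll_miss))
  expect_gt(ll_miss, ll)

  # pulley principle: likelihood invariant to root placement (reversible Q)
  un <- ape::unroot(fx$tree)
  ll_un <- log_likelihood(un, fx$aln, fx$Q)
  expect_equal(ll_un, ll, tolerance = 1e-8)
  set.seed(23)
  internal <- length(un$tip.label) + seq_len(un$Nnode)
  for (nd in sample(internal[-1], min(4, length(internal) - 1)))
    expect_equal(log_likelihood(ape::root(un, node = nd, resolve.root = TRUE),
                                fx$aln, fx$Q),
                 ll, tolerance = 1e-8)

  # taxon mismatch is a hard input error
  bad <- fx$aln; bad$taxa[1] <- "zz"; rownames(bad$states)[1] <- "zz"
  expect_error(log_likelihood(fx$tree, bad, fx$Q), "mismatch")
})

test_that("the nucleotide engine agrees with an independent GTR implementation", {
  skip_if_not_installed("phangorn")
  set.seed(24)
  tr <- random_tree(6)
  Qc <- build_m0_Q(2, 1, codon_frequencies(mode = "EQUAL"))
  aln <- simulate_alignment(tr, Qc, 120)
  # first-position nucleotides as a 4-state data set
  nucs <- c("T", "C", "A", "G")
  pos1 <- matrix(match(substring(code$sense[aln$states], 1, 1), nucs),
                 nrow(aln$states), dimnames = list(aln$taxa, NULL))
  rates <- c(TC = 1.3, TA = 0.7, TG = 1, CA = 0.9, CG = 1.4, AG = 2.1)
  bf <- c(T = 0.2, C = 0.3, A = 0.4, G = 0.1)
  g <- kcm:::gtr_generator(rates, bf)
  prep <- kcm:::prep_tree(tr, aln$taxa)
  ours <- kcm:::engine_loglik(g$Q, g$pi, prep, pos1[prep$tip_order, ])

  chars <- matrix(tolower(nucs[pos1]), nrow(pos1), dimnames = dimnames(pos1))
  pd <- phangorn::phyDat(chars, type = "DNA")
  # phangorn's GTR rate order: AC, AG, AT, CG, CT, GT
  pml_fit <- phangorn::pml(tr, pd, bf = bf[c("A", "C", "G", "T")],
                           Q = c(rates[["CA"]], rates[["AG"]], rates[["TA"]],
                                 rates[["CG"]], rates[["TC"]], rates[["TG"]]))
  expect_equal(ours, pml_fit$logLik, tolerance = 1e-6)
})

test_that("positional GTR fitting recovers generating rates", {
  set.seed(25)
  tr <- random_tree(50, 0.15, 0.05)
  # build a codon generator whose third position follows known GTR rates
  truth <- c(TC = 2, TA = 1, TG = 1, CA = 1, CG = 2, AG = 1)
  q3 <- nuc_exchange_matrix(truth)
  qflat <- nuc_exchange_matrix(rep(1, 6))
  Q <- build_kcm_Q(qflat, qflat, q3, codon_frequencies(mode = "EQUAL"),
                   omega = 1, alpha = 0)
  aln <- simulate_alignment(tr, Q, 2000)
  fit <- fit_positional_gtr(aln, tr, position = 3)
  rel <- fit$rates / truth
  rel <- rel / rel[["TG"]]  # compare relative pattern with the TG reference
  expect_lt(max(abs(rel - 1)), 0.15)
  expect_error(fit_positional_gtr(aln, tr, position = 4), "position")
})

test_that("degenerate positional data triggers a warning, not an error", {
  states <- matrix(rep(code$sense_index[["TTT"]], 12), 3,
                   dimnames = list(paste0("t", 1:3), NULL))
  aln <- codon_alignment(states, taxa = paste0("t", 1:3))
  tr <- ape::read.tree(text = "(t1:0.1,t2:0.1,t3:0.1);")
  expect_warning(fit_positional_gtr(aln, tr, 1), "signal")
})
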