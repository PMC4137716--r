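test_that("AICc formula, monotonicity and large-n limit", {
  expect_equal(aicc(-100, 2, 150), 200 + 4 + 12 / 147, tolerance = 1e-12)
  expect_equal(aicc(0, 0, 10), 0)
  ks <- 1:10
  vals <- vapply(ks, function(k) aicc(-50, k, 150), 0)
  expect_true(all(diff(vals) > 0))
  # reduces to AIC as n grows
  expect_lt(abs(aicc(-50, 19, 1e9) - (100 + 38)), 1e-4)
  expect_error(aicc(-50, 19, 20), "n must exceed")
})

test_that("model variants carry the documented parameter accounting", {
  counts <- c(M0 = 2L, KCM7x = 7L, KCM7xM0 = 7L, KCM19x = 19L,
              KCM19xM0 = 19L, KCM19x_neutral = 18L)
  for (m in names(counts)) {
    sp <- model_spec(m)
    expect_identical(sp$k_free, counts[[m]])
  }
  expect_equal(model_spec("KCM7xM0")$alpha, 0)
  expect_equal(model_spec("KCM19x_neutral")$omega_fixed, 1)
})

test_that("delta AICc is antisymmetric and guards against mixed data", {
  fx <- toy_alignment(5, 40)
  f1 <- fit_codon_model(fx$aln, fx$tree, "M0", n_starts = 1)
  expect_equal(delta_aicc(f1, f1), 0)
  f2 <- fit_codon_model(fx$aln, fx$tree, "KCM7xM0", n_starts = 1)
  expect_equal(delta_aicc(f1, f2), -delta_aicc(f2, f1))
  f3 <- f2; f3$n_sites <- 99L
  expect_error(delta_aicc(f1, f3), "same alignment")
})

test_that("fitting the generating M0 model recovers kappa and omega", {
  set.seed(40)
  tr <- random_tree(15)
  Q <- build_m0_Q(2, 0.5, codon_frequencies(mode = "EQUAL"))
  aln <- simulate_alignment(tr, Q, 1000)
  fit <- fit_codon_model(aln, tr, "M0", n_starts = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$omega - 0.5), 0.1)          # ~3 SE at 1,000 codons
  expect_lt(abs(fit$params[["kappa"]] - 2) / 2, 0.2)
  # refitting from the optimum does not move the likelihood materially
  refit <- fit_codon_model(aln, tr, "M0", n_starts = 1,
                           init = list(rates = fit$params[["kappa"]],
                                       omega = fit$omega,
                                       branch_lengths = fit$branch_lengths))
  expect_lt(abs(refit$lnL - fit$lnL), 1e-3)
})

test_that("log-likelihoods respect the model nesting hierarchy", {
  set.seed(41)
  tr <- random_tree(8)
  Qgen <- build_scheme_matrix("B", omega_factor = 1)
  aln <- simulate_alignment(tr, Qgen, 200)
  fr <- estimate_frequencies(aln, "F3X4")

  f_m0 <- fit_codon_model(aln, tr, "M0", freqs = fr, n_starts = 1)
  k <- f_m0$params[["kappa"]]
  r6 <- c(TC = k, TA = 1, TG = 1, CA = 1, CG = 1, AG = k)
  # exact embedding of M0 into the tied single-hit variant
  f_7m0 <- fit_codon_model(aln, tr, "KCM7xM0", freqs = fr, n_starts = 1,
                           init = list(rates = r6, omega = f_m0$omega,
                                       branch_lengths = f_m0$branch_lengths))
  # near-exact embedding across the multi-hit switch: damped rates make the
  # double/triple flux negligible while singles renormalize back
  f_7 <- fit_codon_model(aln, tr, "KCM7x", freqs = fr, n_starts = 1,
                         init = list(rates = f_7m0$rates * 1e-3,
                                     omega = f_7m0$omega,
                                     branch_lengths = f_7m0$branch_lengths))
  f_19 <- fit_codon_model(aln, tr, "KCM19x", freqs = fr, n_starts = 1,
                          init = list(rates = rep(f_7$rates, 3),
                                      omega = f_7$omega,
                                      branch_lengths = f_7$branch_lengths))
  f_19m0 <- fit_codon_model(aln, tr, "KCM19xM0", freqs = fr, n_starts = 1,
                            init = list(rates = rep(f_7m0$rates, 3),
                                        omega = f_7m0$omega,
                                        branch_lengths = f_7m0$branch_lengths))
  expect_gte(f_7m0$lnL, f_m0$lnL - 1e-3)
  expect_gte(f_7$lnL, f_7m0$lnL - 0.01)
  expect_gte(f_19$lnL, f_7$lnL - 1e-3)
  expect_gte(f_19m0$lnL, f_7m0$lnL - 1e-3)
  expect_gte(f_19$lnL, f_19m0$lnL - 0.01)
})

test_that("replicate studies are byte-deterministic given a seed", {
  run <- function() replicate_study("A", factor = 1, n_reps = 2, n_taxa = 6,
                                    n_codons = 60, models = "M0", seed = 99)
  expect_identical(run()$summary, run()$summary)
  expect_identical(run()$replicates, run()$replicates)
})

test_that("compare_models returns a coherent AICc table", {
  fx <- toy_alignment(5, 60)
  cmp <- compare_models(fx$aln, fx$tree, c("M0", "KCM7xM0"), n_starts = 1)
  expect_identical(cmp$table$model, c("M0", "KCM7xM0"))
  expect_equal(cmp$table$AICc,
               vapply(cmp$fits, function(f) aicc(f$lnL, f$k, f$n_sites), 0),
               ignore_attr = TRUE)
  expect_equal(cmp$table$delta_AICc_vs_first[1], 0)
})
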